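# PCA m6A score, orientation, grouping, stemness index, score pipeline.

test_that("PCA score matches an independently coded eigendecomposition oracle", {
  set.seed(41)
  m <- matrix(rnorm(12, 5, 2), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  got <- compute_m6a_score(m, rownames(m))
  # oracle: z-score genes, eigen-decompose the sample covariance directly
  z <- t(scale(t(m)))
  S <- t(z)                                   # samples x genes, columns centered
  ev <- eigen(stats::cov(S) * (nrow(S) - 1) / nrow(S), symmetric = TRUE)
  # projections onto the first two eigenvectors, any sign combination
  pc1 <- S %*% ev$vectors[, 1]
  pc2 <- S %*% ev$vectors[, 2]
  combos <- list(pc1 + pc2, pc1 - pc2, -pc1 + pc2, -pc1 - pc2)
  matched <- any(vapply(combos, function(cb)
    isTRUE(all.equal(unname(got), as.numeric(cb), tolerance = 1e-8)),
    logical(1)))
  expect_true(matched)
})

test_that("degenerate and symmetric score inputs behave as documented", {
  m <- matrix(5, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_warning(sc <- compute_m6a_score(m, rownames(m)), "constant")
  expect_equal(unname(sc), rep(0, 4))

  m2 <- toy_expr(6, 4, seed = 50)
  dup <- cbind(m2, m2)
  colnames(dup) <- paste0("s", 1:8)
  sc2 <- compute_m6a_score(dup, rownames(dup))
  expect_equal(unname(sc2[1:4]), unname(sc2[5:8]), tolerance = 1e-8)

  # centering: adding a constant changes nothing
  sc3 <- compute_m6a_score(m2 + 7, rownames(m2))
  sc0 <- compute_m6a_score(m2, rownames(m2))
  expect_equal(sc3, sc0, tolerance = 1e-8)

  # gene and sample reordering: invariant up to overall sign
  perm_g <- sample(nrow(m2)); perm_s <- sample(ncol(m2))
  sc4 <- compute_m6a_score(m2[perm_g, perm_s], rownames(m2))
  agree <- max(abs(sc4[names(sc0)] - sc0), abs(sc4[names(sc0)] + sc0))
  expect_equal(min(max(abs(sc4[names(sc0)] - sc0)),
                   max(abs(sc4[names(sc0)] + sc0))), 0, tolerance = 1e-8)

  expect_error(compute_m6a_score(m2, c("G01", "G02")), "fewer than 3")
})

test_that("orientation flips anti-risk scores and is idempotent", {
  m <- toy_expr(8, 10, seed = 60)
  risk_mean <- colMeans(m[1:3, ])
  scores <- setNames(-risk_mean + rnorm(10, 0, 0.01), colnames(m))
  flipped <- orient_score(scores, rownames(m)[1:3], character(0), m)
  expect_gt(cor(flipped, risk_mean), 0)
  again <- orient_score(flipped, rownames(m)[1:3], character(0), m)
  expect_identical(again, flipped)
  expect_warning(un <- orient_score(scores, character(0), character(0), m),
                 "unoriented")
  expect_identical(un, scores)
})

test_that("score groups come from the optimal cutpoint and stratify risk", {
  co <- simulate_cohort(sim_config(n_samples = 200, n_background_genes = 40,
                                   n_immune_sets = 2, genes_per_set = 5,
                                   hazard_beta = 1, censor_rate = 0.2, seed = 71))
  scores <- co$truth$latent_score
  tab <- assign_score_groups(scores, co$clinical)
  expect_setequal(unique(tab$score_group), c("high", "low"))
  lr <- logrank_test(co$clinical$time, co$clinical$event, tab$score_group)
  expect_lt(lr$p, 0.05)
  km_hi <- km_curve(co$clinical$time[tab$score_group == "high"],
                    co$clinical$event[tab$score_group == "high"])
  km_lo <- km_curve(co$clinical$time[tab$score_group == "low"],
                    co$clinical$event[tab$score_group == "low"])
  expect_lt(min(km_hi$surv), min(km_lo$surv))     # worse survival up high
  tab2 <- assign_score_groups(scores, co$clinical)
  expect_identical(tab, tab2)                     # deterministic
  expect_error(assign_score_groups(setNames(rep(1, 200), names(scores)),
                                   co$clinical), "constant")
})

test_that("stemness index is a rescaled per-sample Spearman correlation", {
  m <- toy_expr(10, 5, seed = 81)
  w <- setNames(rnorm(8), rownames(m)[1:8])
  # plant one sample whose expression ranks equal the weight ranks
  m[names(w), 2] <- sort(w) [rank(w)] * 2 + 10    # strictly increasing in w
  msi <- stemness_index(m, w)
  expect_equal(unname(msi[2]), 1)                 # top of the cohort
  expect_equal(min(msi), 0)
  expect_equal(max(msi), 1)
  expect_true(all(msi >= 0 & msi <= 1))

  # raw correlations match the stats-core Spearman per sample
  raw <- vapply(colnames(m), function(s)
    spearman(m[names(w), s], unname(w))$rho, numeric(1))
  rescaled <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(unname(msi), unname(rescaled), tolerance = 1e-12)

  # rank invariance under a strictly monotone per-sample transform
  m3 <- m; m3[, 3] <- exp(m3[, 3] / 2)
  expect_equal(stemness_index(m3, w), msi, tolerance = 1e-12)
  expect_error(stemness_index(m, w[1:2]), "fewer than 3")
})

test_that("score pipeline runs end to end and links score to planted hazard", {
  co <- simulate_cohort(sim_config(n_samples = 88, n_background_genes = 200,
                                   n_immune_sets = 3, genes_per_set = 10,
                                   seed = 91))
  tab <- suppressWarnings(suppressMessages(
    run_score_pipeline(co$expr, co$clinical, co$truth$subtype_labels)))
  counts <- attr(tab, "stage_counts")
  expect_gt(counts$signature, 0)
  expect_gte(counts$signature, counts$prognostic)
  expect_gt(spearman(tab$m6a_score, co$truth$latent_score)$rho, 0)
  expect_gte(ari(tab$score_group, co$truth$subtype_labels), 0.2)
  tab2 <- suppressWarnings(suppressMessages(
    run_score_pipeline(co$expr, co$clinical, co$truth$subtype_labels)))
  expect_identical(tab$m6a_score, tab2$m6a_score)  # deterministic
})

test_that("a null cohort fails the pipeline at the signature stage, by name", {
  co <- simulate_null_cohort(sim_config(n_samples = 60, n_background_genes = 150,
                                        n_immune_sets = 2, genes_per_set = 5,
                                        seed = 92))
  expect_error(
    suppressWarnings(suppressMessages(
      run_score_pipeline(co$expr, co$clinical, co$truth$subtype_labels))),
    "phenotype_signature|screen_prognostic_genes")
})
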