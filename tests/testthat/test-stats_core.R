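# Statistical core: moderated t, BH, rank tests, correlation, ORA.

two_group_fixture <- function(n_genes = 60, na = 8, nb = 8, seed = 3,
                              shift_first = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (na + nb)), n_genes, na + nb,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(na + nb))))
  if (shift_first > 0) m[1:5, (na + 1):(na + nb)] <- m[1:5, (na + 1):(na + nb)] + shift_first
  list(expr = m, a = colnames(m)[1:na], b = colnames(m)[(na + 1):(na + nb)])
}

test_that("moderated t basics: zero logFC for identical groups, input checks", {
  fx <- two_group_fixture()
  fx$expr[1, ] <- rep(c(1, 2, 3, 4), 4)   # same values in both groups
  de <- suppressWarnings(moderated_t_test(fx$expr, fx$a, fx$b))
  expect_equal(de$log2FC[1], 0)
  expect_true(all(de$adjP >= 0 & de$adjP <= 1))
  expect_error(moderated_t_test(fx$expr, fx$a[1], fx$b), "at least 2")
  expect_error(moderated_t_test(fx$expr, fx$a, fx$a), "disjoint")
})

test_that("d0 -> Inf limit gives t = logFC / (s0 * sqrt(1/na + 1/nb))", {
  fx <- two_group_fixture()
  s02 <- 1.7
  de <- moderated_t_test(fx$expr, fx$a, fx$b, prior_df = Inf, prior_var = s02)
  expect_equal(de$t, de$log2FC / sqrt(s02 * (1 / 8 + 1 / 8)), tolerance = 1e-12)
})

test_that("d0 = 0 reduces to the ordinary pooled two-sample t-test", {
  fx <- two_group_fixture()
  de <- moderated_t_test(fx$expr, fx$a, fx$b, prior_df = 0, prior_var = 1)
  ref <- apply(fx$expr, 1, function(x)
    t.test(x[fx$b], x[fx$a], var.equal = TRUE)$statistic)
  expect_equal(de$t, unname(ref), tolerance = 1e-10)
})

test_that("null p-values are approximately uniform", {
  fx <- two_group_fixture(n_genes = 50, na = 10, nb = 10, seed = 9)
  de <- suppressWarnings(moderated_t_test(fx$expr, fx$a, fx$b))
  ks <- suppressWarnings(ks.test(de$p, "punif"))
  expect_lt(unname(ks$statistic), 0.2)
})

test_that("moderated t agrees with the limma oracle", {
  skip_if_not_installed("limma")
  fx <- two_group_fixture(n_genes = 200, seed = 21, shift_first = 2)
  # heteroscedastic genes so the variance prior is informative
  set.seed(22)
  fx$expr <- fx$expr * sqrt(rchisq(200, 4) / 4)
  design <- cbind(1, rep(c(0, 1), each = 8))
  lfit <- limma::eBayes(limma::lmFit(fx$expr, design))
  # route 1: same hyperparameters -> identical statistics
  de_fixed <- moderated_t_test(fx$expr, fx$a, fx$b,
                               prior_df = lfit$df.prior,
                               prior_var = lfit$s2.prior)
  expect_equal(de_fixed$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  # route 2: own trigamma moment estimation lands near limma's
  de <- moderated_t_test(fx$expr, fx$a, fx$b)
  expect_equal(attr(de, "prior_df"), lfit$df.prior, tolerance = 0.05)
  expect_equal(attr(de, "prior_var"), lfit$s2.prior, tolerance = 0.05)
  expect_gt(cor(de$t, unname(lfit$t[, 2])), 0.9999)
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(1)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))       # monotone in rank
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm])           # permutation-stable
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Wilcoxon rank-sum statistic and p behave as specified", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)         # minimum possible rank-sum
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))
  expect_gt(same$p, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("normal-approximation Wilcoxon p is close to exact enumeration at n=m=4", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(2.8, 6.3, 4.4, 7.0)
  obs <- wilcoxon_rank_sum(x, y)
  # brute force over all C(8,4)=70 assignments of ranks to group x
  r <- rank(c(x, y))
  combos <- combn(8, 4)
  sums <- colSums(matrix(r[combos], nrow = 4))
  obs_sum <- sum(r[1:4])
  exact_p <- mean(abs(sums - mean(sums)) >= abs(obs_sum - mean(sums)) - 1e-12)
  expect_lt(abs(obs$p - exact_p), 0.05)
})

test_that("Kruskal-Wallis is tie-safe and consistent with Wilcoxon for 2 groups", {
  g1 <- seq(1.1, 30.1, 1)
  g2 <- seq(2.3, 32.3, 1)
  kw <- kruskal_wallis(list(g1, g2))
  wx <- wilcoxon_rank_sum(g1, g2)
  expect_lt(abs(kw$p - wx$p), 0.01)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$statistic, 0)
  sep <- kruskal_wallis(list(1:5, 11:15, 21:25))
  expect_lt(sep$p, 0.01)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("Spearman correlation is monotone-invariant and matches hand ranks", {
  x <- c(0.3, 1.1, 2.7, 3.2, 4.9)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # one tie pair, hand-computed: Pearson on tie-averaged ranks
  xt <- c(1, 2, 2, 3, 4)
  yt <- c(5, 6, 9, 7, 8)
  expect_equal(spearman(xt, yt)$rho,
               cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("hypergeometric ORA matches closed forms and exhaustive enumeration", {
  universe <- sprintf("g%02d", 1:20)
  res <- hypergeometric_ora(universe[1:5], universe[1:5], universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5L)

  ident <- hypergeometric_ora(universe, universe, universe)
  expect_equal(ident$fold, 1)
  expect_equal(ident$p, 1)

  none <- hypergeometric_ora(universe[1:4], universe[10:12], universe[1:12])
  expect_equal(none$overlap, 0L)
  expect_equal(none$p, 1)

  # exhaustive enumeration oracle on a small universe
  uni <- letters[1:12]
  set <- letters[c(1, 3, 5, 7)]
  query <- letters[c(1, 2, 3, 8, 9)]
  obs <- hypergeometric_ora(query, set, uni)
  draws <- combn(12, 5)
  in_set <- match(set, uni)
  overlaps <- colSums(matrix(draws %in% in_set, nrow = 5))
  expect_equal(obs$p, mean(overlaps >= obs$overlap), tolerance = 1e-12)
  expect_error(hypergeometric_ora(c("zz"), set, uni), "contained")
})

test_that("DEG selection applies both thresholds; signatures intersect lists", {
  de <- data.frame(gene = sprintf("g%d", 1:10),
                   log2FC = c(1.5, 0.9, -1.2, 2.0, 0.2, 1.1, -0.5, 1.05, -3, 0),
                   adjP = c(0.01, 0.001, 0.04, 0.2, 0.01, 0.03, 0.01, 0.06, 0.001, 0.5))
  sel <- select_degs(de)
  expect_setequal(sel, c("g1", "g3", "g6", "g9"))
  expect_setequal(select_degs(de, one_sided = TRUE), c("g1", "g6"))

  expect_setequal(phenotype_signature(list(c("A", "B", "C"), c("B", "C", "D"))),
                  c("B", "C"))
  expect_identical(phenotype_signature(list("A")), "A")
  expect_warning(sig <- phenotype_signature(list("A", "B")), "no genes")
  expect_length(sig, 0L)
})
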