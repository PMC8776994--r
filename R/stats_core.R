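# Statistical core: empirical-Bayes moderated two-group differential
# expression, multiplicity control, rank tests, correlation, and
# hypergeometric over-representation.

#' Empirical-Bayes moderated two-group t-test
#'
#' Per-gene two-group comparison with variance moderation: residual
#' variances s_g^2 (pooled within groups, d_g = n_a + n_b - 2 df) are
#' shrunk towards a common prior. The prior degrees of freedom d0 and
#' prior variance s0^2 are estimated by moment-matching the scaled-F
#' distribution of s_g^2 on the log scale (trigamma inversion by Newton
#' iteration). The posterior variance is
#' `(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)` and the moderated t uses
#' d0 + d_g degrees of freedom. P-values are BH-adjusted.
#'
#' Log fold change is group_b minus group_a.
#'
#' @param expr Genes x samples expression matrix (log2 scale).
#' @param group_a,group_b Disjoint character vectors of sample ids, each of
#'   length >= 2.
#' @param prior_df,prior_var Optional overrides for d0 and s0^2 (e.g.
#'   `prior_df = Inf` for fully pooled variance, `prior_df = 0` for the
#'   ordinary t-test).
#' @return data.frame with columns `gene`, `log2FC`, `t`, `p`, `adjP`,
#'   `posterior_sd`; the estimated hyperparameters are in attributes
#'   `prior_df` and `prior_var`.
#' @export
moderated_t_test <- function(expr, group_a, group_b,
                             prior_df = NULL, prior_var = NULL) {
  validate_expression_matrix(expr)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint", call. = FALSE)
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing))
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)

  xa <- expr[, group_a, drop = FALSE]
  xb <- expr[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  dg <- na + nb - 2
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- mb - ma
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  s2 <- pmax((ssa + ssb) / dg, 1e-12)   # floor guards log(0) below

  if (is.null(prior_df) || is.null(prior_var)) {
    hyp <- fit_variance_prior(s2, dg)
    d0 <- prior_df %||% hyp$d0
    s02 <- prior_var %||% hyp$s02
  } else {
    d0 <- prior_df; s02 <- prior_var
  }

  if (is.infinite(d0)) {
    post_var <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    post_var <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  se <- sqrt(post_var * (1 / na + 1 / nb))
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  zero <- s2 <= 1e-12 & abs(lfc) < 1e-12
  if (any(zero)) {
    warning(sum(zero), " gene(s) constant in both groups; p set to 1",
            call. = FALSE)
    tstat[zero] <- 0
    p[zero] <- 1
  }

  out <- data.frame(gene = rownames(expr), log2FC = lfc, t = tstat, p = p,
                    adjP = bh_adjust(p), posterior_sd = sqrt(post_var),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

# Moment estimation of (d0, s0^2) from log residual variances:
# var(log s_g^2) = trigamma(dg/2) + trigamma(d0/2), solved for d0 by
# Newton inversion of the trigamma function; nonpositive excess variance
# falls back to d0 = Inf (fully pooled).
fit_variance_prior <- function(s2, dg) {
  z <- log(s2)
  evar <- stats::var(z)
  excess <- evar - trigamma(dg / 2)
  if (!is.finite(excess) || excess <= 0) {
    warning("no excess variance among gene variances; using pooled variance (d0 = Inf)",
            call. = FALSE)
    s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
    return(list(d0 = Inf, s02 = s02))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
               digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Solve trigamma(x) = y by Newton iteration, tolerance 1e-8.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:100) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    x_new <- x - delta
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < 1e-8) return(x_new)
    x <- x_new
  }
  x
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Wilcoxon rank-sum test (two-sided, normal approximation)
#'
#' Returns the rank-sum of `x` (W + n_x(n_x+1)/2 in Mann-Whitney terms)
#' and a two-sided p-value from the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @return list with `statistic` (rank-sum of x) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  ranksum <- unname(wt$statistic) + length(x) * (length(x) + 1) / 2
  p <- if (is.na(wt$p.value)) 1 else wt$p.value  # all-tied degenerate input
  list(statistic = ranksum, p = p)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 df.
#'
#' @param groups List of >= 2 nonempty numeric vectors.
#' @return list with `statistic` (H), `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("groups must be nonempty", call. = FALSE)
  k <- length(groups)
  if (length(unique(unlist(groups))) == 1L)   # all observations tied: H = 0
    return(list(statistic = 0, p = 1, df = k - 1L))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks; p-value from the asymptotic
#' t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realized overlap
#' between a query gene list and a gene set, within a fixed universe.
#' Fold enrichment is `(overlap/|query|) / (|set n universe|/|universe|)`.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param gene_set Character vector; intersected with `universe`.
#' @param universe Character vector of all assayed genes.
#' @return list with `overlap`, `fold`, `p`.
#' @export
hypergeometric_ora <- function(query, gene_set, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query))
    stop("query and universe must be nonempty", call. = FALSE)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe", call. = FALSE)
  set_u <- intersect(unique(gene_set), universe)
  k <- length(intersect(query, set_u))
  m <- length(set_u); n <- length(universe) - m; q <- length(query)
  p <- stats::phyper(k - 1, m, n, q, lower.tail = FALSE)
  fold <- if (m == 0) NA_real_ else (k / q) / (m / length(universe))
  list(overlap = k, fold = fold, p = p)
}

#' Threshold a differential-expression table into a DEG list
#'
#' Genes with `|log2FC| > lfc_threshold` and adjusted p below
#' `fdr_threshold`; `one_sided = TRUE` restricts to up-regulation
#' (log2FC > threshold).
#'
#' @param de Result of [moderated_t_test()].
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold Adjusted-p threshold (default 0.05).
#' @param one_sided Use signed rather than absolute fold change.
#' @return Character vector of selected genes.
#' @export
select_degs <- function(de, lfc_threshold = 1, fdr_threshold = 0.05,
                        one_sided = FALSE) {
  if (lfc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  fc_ok <- if (one_sided) de$log2FC > lfc_threshold else abs(de$log2FC) > lfc_threshold
  de$gene[fc_ok & de$adjP < fdr_threshold]
}

#' Intersect DEG lists into a phenotype signature
#'
#' The genes differentially expressed in every provided comparison; a
#' single list is returned unchanged.
#'
#' @param deg_lists List of character vectors (>= 1).
#' @return Character vector (possibly empty, with a warning).
#' @export
phenotype_signature <- function(deg_lists) {
  if (!is.list(deg_lists) || !length(deg_lists))
    stop("need at least one DEG list", call. = FALSE)
  sig <- Reduce(intersect, deg_lists)
  if (!length(sig))
    warning("DEG lists share no genes: empty phenotype signature", call. = FALSE)
  sig
}

#' Serialize a differential-expression table as TSV
#' @param de Result of [moderated_t_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene", "log2FC", "t", "p", "adjP")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
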