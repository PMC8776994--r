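# Single-sample gene-set enrichment (ssGSEA).
#
# Rank-based running-sum scores computed independently per sample: genes
# are ranked by expression (ties by average rank), in-set genes accumulate
# weight rank^alpha (normalized over in-set genes), out-of-set genes
# accumulate 1/(N - |set|), and the score is the sum over all ranked
# positions of the difference of the two cumulative distributions.

#' ssGSEA enrichment scores
#'
#' @param expr Genes x samples expression matrix.
#' @param sets Named list of character vectors (gene sets). Sets sharing no
#'   gene with `expr` are dropped with a warning.
#' @param alpha Rank-weighting exponent (>= 0; default 0.25, the canonical
#'   ssGSEA choice).
#' @param normalize Divide all scores by the global (max - min) across the
#'   whole score matrix (the common implementation default).
#' @return Sets x samples numeric matrix with attributes `alpha` and
#'   `normalized`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  validate_expression_matrix(expr)
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  if (!length(sets) || is.null(names(sets)))
    stop("sets must be a nonempty named list", call. = FALSE)
  sets <- lapply(sets, unique)
  keep <- vapply(sets, function(s) any(s %in% rownames(expr)), logical(1))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " gene set(s) with no gene in the matrix: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
    sets <- sets[keep]
  }
  if (!length(sets))
    stop("no gene set overlaps the expression matrix", call. = FALSE)

  n_genes <- nrow(expr)
  genes <- rownames(expr)
  inset_list <- lapply(sets, function(s) genes %in% s)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")      # N = highest expression
    ord <- order(x, decreasing = TRUE)          # walk top-down
    w <- r^alpha
    for (i in seq_along(sets)) {
      inset <- inset_list[[i]]
      m <- sum(inset)
      if (m == n_genes) { scores[i, j] <- 0; next }  # no out-of-set mass
      win <- ifelse(inset, w, 0)[ord]
      wout <- ifelse(inset, 0, 1)[ord]
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(wout) / (n_genes - m)
      scores[i, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}

#' Immune cell infiltration scores
#'
#' Relative abundance of immune cell types, one ssGSEA score per cell-type
#' marker set per sample.
#'
#' @param expr Genes x samples expression matrix.
#' @param signature Named list: one marker gene set per immune cell type.
#' @param ... Passed to [ssgsea_scores()].
#' @return Cell types x samples enrichment matrix.
#' @export
immune_infiltration <- function(expr, signature, ...) {
  ssgsea_scores(expr, signature, ...)
}

#' Stromal and immune ssGSEA scores
#'
#' ESTIMATE-style stromal/immune summaries computed as ssGSEA scores on two
#' user-supplied marker sets (an approximation: the published ESTIMATE gene
#' lists and purity transform are not reproduced).
#'
#' @param expr Genes x samples expression matrix.
#' @param stromal_set,immune_set Character vectors of marker genes.
#' @param ... Passed to [ssgsea_scores()].
#' @return 2 x samples matrix with rows `Stromal` and `Immune`.
#' @export
estimate_like_scores <- function(expr, stromal_set, immune_set, ...) {
  ssgsea_scores(expr, list(Stromal = stromal_set, Immune = immune_set), ...)
}

#' Genes correlated with a reference profile
#'
#' Pearson-correlation screen used to build proxy signatures (e.g. an EBV
#' expression proxy from genes correlated with viral gene expression when
#' the viral profile itself is unavailable).
#'
#' @param expr Genes x samples expression matrix.
#' @param reference_profile Numeric vector, one value per sample.
#' @param r_threshold Inclusion threshold on the correlation (default 0.3,
#'   strict inequality).
#' @return Character vector of genes with `cor > r_threshold`.
#' @export
build_correlated_set <- function(expr, reference_profile, r_threshold = 0.3) {
  validate_expression_matrix(expr)
  if (length(reference_profile) != ncol(expr))
    stop("reference profile length must equal the number of samples", call. = FALSE)
  if (stats::sd(reference_profile) == 0)
    stop("reference profile is constant; correlations undefined", call. = FALSE)
  r <- suppressWarnings(
    as.numeric(stats::cor(t(expr), reference_profile, method = "pearson")))
  rownames(expr)[!is.na(r) & r > r_threshold]
}

#' Proxy enrichment score from a correlated gene set
#'
#' Single-set ssGSEA score over a proxy signature (e.g. EBV-correlated
#' genes), returned as a per-sample vector.
#'
#' @param expr Genes x samples expression matrix.
#' @param correlated_genes Character vector of proxy genes.
#' @param ... Passed to [ssgsea_scores()].
#' @return Named numeric vector of per-sample scores.
#' @export
ebv_proxy_score <- function(expr, correlated_genes, ...) {
  s <- ssgsea_scores(expr, list(proxy = correlated_genes), ...)
  s["proxy", ]
}

#' Serialize an enrichment matrix as TSV
#' @param scores Sets x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(scores, path) {
  df <- data.frame(set = rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
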