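# The m6A score: a PCA-based per-sample risk score over prognostic
# signature genes (score = PC1 + PC2 of the sample scores), with sign
# orientation, optimal-cutpoint grouping, and the Spearman-based mRNA
# stemness index (mRNAsi).

#' PCA-based m6A score
#'
#' The expression matrix is restricted to the signature genes, each gene is
#' z-scored across samples (correlation PCA, so no single high-variance
#' gene dominates; zero-variance genes are dropped with a warning), and the
#' per-sample score is the sum of the first two principal-component sample
#' scores. The sign of each component is arbitrary; fix it with
#' [orient_score()].
#'
#' @param expr Genes x samples expression matrix.
#' @param signature_genes Character vector; >= 3 must be present in `expr`.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_m6a_score <- function(expr, signature_genes) {
  validate_expression_matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  present <- intersect(signature_genes, rownames(expr))
  if (length(present) < 3L)
    stop("fewer than 3 signature genes present in the expression matrix",
         call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (all(sds == 0)) {
    warning("all signature genes are constant; scores are all zero", call. = FALSE)
    return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  }
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant signature gene(s) dropped", call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) < 3L)
    stop("fewer than 3 usable (non-constant) signature genes", call. = FALSE)
  z <- (sub - rowMeans(sub)) / sds
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L] + if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0
  stats::setNames(as.numeric(scores), colnames(expr))
}

#' Orient a PCA score so high means risk
#'
#' PCA component signs are arbitrary. The score is flipped when its
#' correlation with the mean expression of the risk genes (minus the mean
#' of the protective genes, when given) is negative, so a high score is
#' reproducibly the risk-associated direction.
#'
#' @param scores Named per-sample scores.
#' @param risk_genes,protective_genes Character vectors (at least one
#'   nonempty; otherwise the scores are returned unflipped with a warning).
#' @param expr Genes x samples expression matrix.
#' @return Oriented scores.
#' @export
orient_score <- function(scores, risk_genes, protective_genes, expr) {
  risk <- intersect(risk_genes, rownames(expr))
  prot <- intersect(protective_genes, rownames(expr))
  if (!length(risk) && !length(prot)) {
    warning("no risk or protective genes available; score left unoriented",
            call. = FALSE)
    return(scores)
  }
  ref <- rep(0, ncol(expr))
  if (length(risk)) ref <- ref + colMeans(expr[risk, , drop = FALSE])
  if (length(prot)) ref <- ref - colMeans(expr[prot, , drop = FALSE])
  if (stats::sd(scores) == 0 || stats::sd(ref) == 0) return(scores)
  if (stats::cor(scores, ref) < 0) -scores else scores
}

#' Split samples into high/low score groups at the optimal cutpoint
#'
#' The cutpoint comes from [best_cutpoint()] (maximally selected rank
#' statistic) on the survival outcome; samples above it form the `high`
#' group.
#'
#' @param scores Named per-sample scores, aligned with `clinical`.
#' @param clinical Clinical data.frame with `time` and `event`.
#' @param minprop Passed to [best_cutpoint()].
#' @return data.frame (`ScoreTable`): sample_id, m6a_score, score_group;
#'   the cutpoint and its standardized statistic are kept as attributes.
#' @export
assign_score_groups <- function(scores, clinical, minprop = 0.1) {
  validate_clinical(clinical)
  if (!identical(names(scores), clinical$sample_id))
    stop("scores and clinical table are not sample-aligned", call. = FALSE)
  cut <- best_cutpoint(clinical$time, clinical$event, scores, minprop = minprop)
  out <- data.frame(sample_id = clinical$sample_id,
                    m6a_score = as.numeric(scores),
                    score_group = as.character(cut$groups),
                    stringsAsFactors = FALSE)
  attr(out, "cutpoint") <- cut$cutpoint
  attr(out, "statistic") <- cut$statistic
  out
}

#' mRNA stemness index (mRNAsi)
#'
#' Each sample is scored by the Spearman correlation between its expression
#' of the genes shared with the weight vector and the weights themselves;
#' the raw correlations are then linearly rescaled to `[0, 1]` across the
#' cohort (subtract the minimum, divide by the post-subtraction maximum).
#' Samples with constant expression over the shared genes get `NA` and are
#' excluded from the rescaling extremes.
#'
#' @param expr Genes x samples expression matrix.
#' @param weights Named numeric vector (gene -> weight); >= 3 genes must be
#'   shared with `expr`.
#' @return Named per-sample mRNAsi in `[0, 1]` (possibly `NA` for flagged
#'   samples).
#' @export
stemness_index <- function(expr, weights) {
  validate_expression_matrix(expr)
  shared <- intersect(names(weights), rownames(expr))
  if (length(shared) < 3L)
    stop("fewer than 3 genes shared between weights and expression matrix",
         call. = FALSE)
  w <- weights[shared]
  raw <- apply(expr[shared, , drop = FALSE], 2L, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, w, method = "spearman")
  })
  if (anyNA(raw))
    warning(sum(is.na(raw)), " sample(s) constant over the weight genes; mRNAsi NA",
            call. = FALSE)
  shifted <- raw - min(raw, na.rm = TRUE)
  mx <- max(shifted, na.rm = TRUE)
  if (mx == 0) return(stats::setNames(rep(0, length(raw)), names(raw)))
  shifted / mx
}

#' Read a stemness weight vector from a two-column TSV
#' @param path File with columns `gene` and `weight` (header required).
#' @return Named numeric vector.
#' @export
read_weights <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(df)))
    stop("weight file must have 'gene' and 'weight' columns", call. = FALSE)
  stats::setNames(as.numeric(df$weight), as.character(df$gene))
}

#' End-to-end m6A score pipeline
#'
#' Orchestrates, from an aligned cohort and subtype labels:
#' moderated differential expression of each subtype versus the rest ->
#' DEG selection (`|log2FC| > lfc`, adjusted p < `fdr`) -> intersection
#' into the phenotype signature -> univariate Cox screen (p < `cox_p`) ->
#' PCA m6A score -> risk orientation (risk = screened genes with HR > 1,
#' protective = HR < 1) -> optimal-cutpoint high/low grouping. Gene counts
#' at every stage are recorded.
#'
#' @param expr Genes x samples expression matrix.
#' @param clinical Sample-aligned clinical data.frame.
#' @param subtype_labels Named (by sample) labels with >= 2 distinct values.
#' @param lfc,fdr,cox_p,minprop Stage thresholds.
#' @return `ScoreTable` data.frame with columns sample_id, m6a_score,
#'   score_group, subtype; attributes `stage_counts`, `signature_genes`,
#'   `prognostic_genes`, `cutpoint`.
#' @export
run_score_pipeline <- function(expr, clinical, subtype_labels,
                               lfc = 1, fdr = 0.05, cox_p = 0.01,
                               minprop = 0.1) {
  validate_expression_matrix(expr)
  validate_clinical(clinical)
  if (is.null(names(subtype_labels)))
    names(subtype_labels) <- clinical$sample_id
  if (!identical(names(subtype_labels), clinical$sample_id) ||
      !identical(colnames(expr), clinical$sample_id))
    stop("expression, clinical and labels must be sample-aligned", call. = FALSE)
  lv <- sort(unique(subtype_labels))
  if (length(lv) < 2L) stop("need at least 2 subtype labels", call. = FALSE)

  deg_lists <- lapply(lv, function(l) {
    inside <- names(subtype_labels)[subtype_labels == l]
    outside <- setdiff(names(subtype_labels), inside)
    de <- moderated_t_test(expr, group_a = outside, group_b = inside)
    select_degs(de, lfc_threshold = lfc, fdr_threshold = fdr)
  })
  signature <- suppressWarnings(phenotype_signature(deg_lists))
  counts <- list(degs_per_subtype = lengths(deg_lists),
                 signature = length(signature))
  if (!length(signature))
    stop("score pipeline failed at stage 'phenotype_signature': ",
         "no overlapping differentially expressed genes", call. = FALSE)
  message("phenotype signature: ", length(signature), " genes")

  screen <- screen_prognostic_genes(expr[signature, , drop = FALSE],
                                    clinical, p_threshold = cox_p)
  counts$prognostic <- length(screen$genes)
  if (length(screen$genes) < 3L)
    stop("score pipeline failed at stage 'screen_prognostic_genes': ",
         length(screen$genes), " gene(s) with p < ", cox_p, call. = FALSE)
  message("prognostic genes (p < ", cox_p, "): ", length(screen$genes))

  scores <- compute_m6a_score(expr, screen$genes)
  tab <- screen$table[screen$table$gene %in% screen$genes, ]
  scores <- orient_score(scores,
                         risk_genes = tab$gene[tab$hr > 1],
                         protective_genes = tab$gene[tab$hr < 1],
                         expr = expr)
  out <- assign_score_groups(scores, clinical, minprop = minprop)
  out$subtype <- unname(subtype_labels)
  attr(out, "stage_counts") <- counts
  attr(out, "signature_genes") <- signature
  attr(out, "prognostic_genes") <- screen$genes
  out
}
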