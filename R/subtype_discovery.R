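# NMF consensus clustering for tumor subtype discovery.
#
# Expression of a gene panel (by default the m6A regulators) is factorized
# X ~ WH with multiplicative updates; repeated random restarts yield a
# consensus co-clustering matrix, final labels come from average-linkage
# hierarchical clustering of the consensus distances, and the number of
# clusters is chosen by silhouette width among values of k whose groups
# separate survival (log-rank p < 0.05).

#' Shift gene rows to be nonnegative
#'
#' NMF requires a nonnegative input; each gene row with a negative minimum
#' is shifted upward by that minimum so its new minimum is zero. Rows
#' already nonnegative are untouched.
#'
#' @param expr Genes x samples matrix.
#' @return Matrix of the same shape with all values >= 0.
#' @export
nonnegative_transform <- function(expr) {
  mins <- apply(expr, 1L, min)
  neg <- mins < 0
  if (any(neg)) expr[neg, ] <- expr[neg, , drop = FALSE] - mins[neg]
  expr
}

#' Standardized, folded NMF input for subtype discovery
#'
#' Prepares an expression panel for NMF clustering: each gene row is
#' z-scored across samples (constant rows are dropped with a warning) and
#' the signed matrix is folded into stacked positive and negative parts
#' (`rbind(pmax(Z, 0), pmax(-Z, 0))`), the standard construction for
#' factorizing signed expression data. Folding preserves both directions
#' of contrast, so a subtype marked only by uniformly elevated expression
#' still yields the two-block structure that argmax component labelling
#' requires.
#'
#' @param expr Genes x samples expression matrix (a gene panel, e.g. the
#'   m6A regulators).
#' @return Nonnegative `2g x samples` matrix, rows suffixed `_pos`/`_neg`.
#' @export
nmf_input <- function(expr) {
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene row(s) dropped from NMF input",
            call. = FALSE)
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(expr) < 2L) stop("fewer than 2 non-constant genes", call. = FALSE)
  z <- (expr - rowMeans(expr)) / sds
  out <- rbind(pmax(z, 0), pmax(-z, 0))
  rownames(out) <- c(paste0(rownames(z), "_pos"), paste0(rownames(z), "_neg"))
  out
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius loss `||X - WH||^2` with Lee-Seung
#' multiplicative updates from a seeded uniform random initialization,
#' stopping when the relative loss change drops below `tol` or after
#' `max_iter` iterations. A small epsilon (1e-10) guards denominators.
#'
#' @param X Nonnegative matrix (features x samples).
#' @param k Rank, `2 <= k < min(dim(X))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter,tol Stopping controls.
#' @return list with `W` (features x k), `H` (k x samples), `loss` (final
#'   Frobenius loss) and `loss_trace`.
#' @export
nmf_factorize <- function(X, k, seed, max_iter = 500L, tol = 1e-6) {
  if (any(X < 0)) stop("NMF input must be nonnegative", call. = FALSE)
  if (k < 2L || k >= min(dim(X)))
    stop("k must satisfy 2 <= k < min(dim(X))", call. = FALSE)
  eps <- 1e-10
  set.seed(seed)
  W <- matrix(stats::runif(nrow(X) * k), nrow(X), k)
  H <- matrix(stats::runif(k * ncol(X)), k, ncol(X))
  loss <- sum((X - W %*% H)^2)
  trace <- loss
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_loss <- sum((X - W %*% H)^2)
    trace <- c(trace, new_loss)
    if (abs(loss - new_loss) < tol * max(loss, eps)) {
      loss <- new_loss
      break
    }
    loss <- new_loss
  }
  list(W = W, H = H, loss = loss, loss_trace = trace)
}

#' Consensus NMF clustering
#'
#' Runs [nmf_factorize()] `n_runs` times from a seeded stream of random
#' initializations, assigns each sample per run to the argmax component of
#' its H column, and records the fraction of runs in which each sample
#' pair co-clusters. Final labels are obtained by average-linkage
#' hierarchical clustering of `1 - consensus` cut at `k`; cluster quality
#' is the average silhouette width on the consensus distances.
#'
#' @param X Nonnegative features x samples matrix.
#' @param k Number of clusters.
#' @param n_runs Number of NMF restarts (>= 2).
#' @param seed Master seed; per-run seeds are drawn from it.
#' @param run_seeds Optional explicit per-run seeds (overrides `seed`).
#' @return list with `k`, `labels` (named by sample), `consensus`
#'   (n x n), `average_silhouette`, `n_runs`, `seed`.
#' @export
consensus_cluster <- function(X, k, n_runs = 100L, seed = 1L,
                              run_seeds = NULL) {
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  n <- ncol(X)
  if (is.null(run_seeds)) {
    set.seed(seed)
    run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  }
  co <- matrix(0, n, n)
  for (s in run_seeds) {
    fit <- nmf_factorize(X, k, seed = s)
    lab <- apply(fit$H, 2L, which.max)
    co <- co + outer(lab, lab, "==")
  }
  consensus <- co / length(run_seeds)
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(X), colnames(X))
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- colnames(X)
  sil <- average_silhouette(1 - consensus, labels)
  list(k = k, labels = labels, consensus = consensus,
       average_silhouette = sil, n_runs = length(run_seeds), seed = seed)
}

#' Average silhouette width
#'
#' Mean of the per-sample silhouette `s(i) = (b - a) / max(a, b)` on a
#' distance matrix; samples in singleton clusters contribute 0.
#'
#' @param distance Symmetric n x n distance matrix with zero diagonal.
#' @param labels Integer cluster ids (>= 2 distinct values).
#' @return Average silhouette width in `[-1, 1]`.
#' @export
average_silhouette <- function(distance, labels) {
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dmatrix = as.matrix(distance))
  mean(sil[, "sil_width"])
}

#' Survival-guided selection of the number of clusters
#'
#' For every candidate `k`, consensus clustering is run and the resulting
#' groups are compared by log-rank test on the clinical survival data. The
#' chosen `k` maximizes average silhouette width among candidates whose
#' log-rank p-value is below 0.05; if no candidate separates survival, the
#' silhouette-best candidate is returned with a warning.
#'
#' @param X Nonnegative features x samples matrix (columns must match
#'   `clinical$sample_id` order).
#' @param clinical Clinical data.frame with `time` and `event`.
#' @param k_range Integer vector of candidate cluster numbers.
#' @param n_runs,seed Passed to [consensus_cluster()].
#' @return The winning [consensus_cluster()] result, augmented with
#'   `logrank_p` and a `selection` data.frame (k, silhouette, logrank_p).
#' @export
select_k <- function(X, clinical, k_range = 2:4, n_runs = 100L, seed = 1L) {
  validate_clinical(clinical)
  if (!identical(colnames(X), clinical$sample_id))
    stop("columns of X must match clinical sample order; use align_samples()",
         call. = FALSE)
  fits <- lapply(k_range, function(k) {
    fit <- consensus_cluster(X, k, n_runs = n_runs, seed = seed)
    fit$logrank_p <- logrank_test(clinical$time, clinical$event, fit$labels)$p
    fit
  })
  sel <- data.frame(
    k = k_range,
    silhouette = vapply(fits, `[[`, numeric(1), "average_silhouette"),
    logrank_p = vapply(fits, `[[`, numeric(1), "logrank_p"))
  pass <- sel$logrank_p < 0.05
  idx <- if (any(pass)) which(pass)[which.max(sel$silhouette[pass])] else {
    warning("no candidate k separates survival at p < 0.05; ",
            "falling back to the best silhouette", call. = FALSE)
    which.max(sel$silhouette)
  }
  out <- fits[[idx]]
  out$selection <- sel
  out
}
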