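# Survival machinery: Kaplan-Meier curves, log-rank tests, univariate Cox
# screening, and maximally selected rank statistics for optimal cutpoints.
# The product-limit estimator, log-rank test and Cox partial likelihood
# (Efron ties) are delegated to the survival package; the cutpoint search
# computes its own standardized log-rank statistic at every candidate split.

#' Kaplan-Meier product-limit curve
#'
#' @param time Nonnegative survival times.
#' @param event Event indicators (1 = progression/death, 0 = censored);
#'   at least one event required.
#' @return data.frame over distinct event times with columns `time`,
#'   `surv` (nonincreasing, starting below 1), and `n_risk`.
#' @export
km_curve <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ", call. = FALSE)
  if (!any(event == 1)) stop("Kaplan-Meier needs at least one event", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], surv = fit$surv[keep],
             n_risk = fit$n.risk[keep])
}

#' Log-rank test across groups
#'
#' Observed-minus-expected statistic with hypergeometric variance at each
#' event time, referred to chi-square with (groups - 1) df.
#'
#' @param time,event Survival outcome.
#' @param groups Group labels (>= 2 nonempty groups).
#' @return list with `chi2`, `p`, `df`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  if (!any(event == 1)) stop("log-rank test needs at least one event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       df = df)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling; a monotone likelihood
#' (e.g. perfect separation) is reported explicitly via `converged = FALSE`
#' rather than returned silently.
#'
#' @param time,event Survival outcome (>= 2 events).
#' @param covariate Per-sample numeric covariate, non-constant.
#' @return list with `beta`, `hr`, `se`, `p` (Wald), `ci_lower`,
#'   `ci_upper`, `n_events`, `score_chi2`, `converged`.
#' @export
cox_univariate <- function(time, event, covariate) {
  if (sum(event == 1) < 2L) stop("need at least 2 events", call. = FALSE)
  if (stats::sd(covariate) == 0)
    stop("covariate is constant; Cox coefficient undefined", call. = FALSE)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = "efron", control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1L]
  converged <- !monotone && is.finite(beta) && se < 1e3
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  list(beta = beta, hr = exp(beta), se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       ci_lower = exp(ci[1L]), ci_upper = exp(ci[2L]),
       n_events = sum(event == 1),
       score_chi2 = unname(fit$score),
       converged = converged)
}

#' Univariate Cox screen for prognostic genes
#'
#' Fits one univariate Cox model per gene on its (continuous) expression
#' and returns genes whose Wald p-value falls below the threshold.
#' Non-convergent genes are excluded with a warning.
#'
#' @param expr Genes x samples expression matrix, sample-aligned with
#'   `clinical` (see [align_samples()]).
#' @param clinical Clinical data.frame.
#' @param p_threshold Wald-p threshold (default 0.01).
#' @param dichotomize Split each gene at its median instead of using
#'   continuous expression.
#' @return list with `genes` (passing symbols) and `table` (per-gene
#'   data.frame: gene, beta, hr, se, p, converged).
#' @export
screen_prognostic_genes <- function(expr, clinical, p_threshold = 0.01,
                                    dichotomize = FALSE) {
  validate_expression_matrix(expr)
  validate_clinical(clinical)
  if (!identical(colnames(expr), clinical$sample_id))
    stop("expression and clinical samples not aligned; use align_samples()",
         call. = FALSE)
  rows <- lapply(rownames(expr), function(g) {
    x <- expr[g, ]
    if (dichotomize) x <- as.numeric(x > stats::median(x))
    if (stats::sd(x) == 0)
      return(data.frame(gene = g, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, p = NA_real_, converged = FALSE))
    fit <- tryCatch(cox_univariate(clinical$time, clinical$event, x),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(gene = g, beta = NA_real_, hr = NA_real_,
                        se = NA_real_, p = NA_real_, converged = FALSE))
    data.frame(gene = g, beta = fit$beta, hr = fit$hr, se = fit$se,
               p = fit$p, converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  bad <- !tab$converged
  if (any(bad))
    warning(sum(bad), " gene(s) excluded from the prognostic screen ",
            "(non-convergent or constant)", call. = FALSE)
  genes <- tab$gene[tab$converged & tab$p < p_threshold]
  list(genes = genes, table = tab)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Every candidate cutpoint leaving at least `minprop` of the samples on
#' each side is evaluated by the standardized log-rank statistic of the
#' induced two-group split; the cutpoint maximizing its absolute value is
#' returned (ties broken toward the lower cutpoint). The reported
#' `logrank_p` is the naive log-rank p-value at the chosen cut and is
#' selection-biased (flagged in the result); no maxstat adjustment is
#' applied.
#'
#' @param time,event Survival outcome.
#' @param score Per-sample numeric score, non-constant.
#' @param minprop Minimum fraction of samples on each side (default 0.1).
#' @return list with `cutpoint`, `statistic` (standardized log-rank at the
#'   cut), `groups` (factor `high`/`low`), `logrank_p`,
#'   `p_is_selection_biased = TRUE`.
#' @export
best_cutpoint <- function(time, event, score, minprop = 0.1) {
  if (stats::sd(score) == 0) stop("score is constant", call. = FALSE)
  if (minprop <= 0 || minprop >= 0.5)
    stop("minprop must lie in (0, 0.5)", call. = FALSE)
  n <- length(score)
  cand <- sort(unique(score))
  cand <- cand[-length(cand)]                 # split is score > c
  ok <- vapply(cand, function(c) {
    hi <- sum(score > c)
    hi >= minprop * n && (n - hi) >= minprop * n
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand))
    stop("no cutpoint satisfies the minprop constraint", call. = FALSE)
  stat <- vapply(cand, function(c)
    logrank_z(time, event, score > c), numeric(1))
  best <- which.max(abs(stat))                # which.max takes the first: lower cut
  cut <- cand[best]
  groups <- factor(ifelse(score > cut, "high", "low"), levels = c("low", "high"))
  p <- stats::pchisq(stat[best]^2, df = 1, lower.tail = FALSE)
  list(cutpoint = cut, statistic = stat[best], groups = groups,
       logrank_p = p, p_is_selection_biased = TRUE)
}

# Standardized two-group log-rank statistic (O - E)/sqrt(V) for the
# in-group defined by the logical vector `grp`.
logrank_z <- function(time, event, grp) {
  et <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in et) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    n1 <- sum(at_risk & grp)
    d1 <- sum(event == 1 & time == t & grp)
    U <- U + d1 - d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  if (V <= 0) return(0)
  U / sqrt(V)
}
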