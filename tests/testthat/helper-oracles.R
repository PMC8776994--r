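# Shared fixtures and independent oracles used across test files.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  if ((si + sj) / 2 - e == 0) return(1)
  (sij - e) / ((si + sj) / 2 - e)
}

# Literal scalar-loop running-sum single-sample enrichment score for one
# gene set (unnormalized), independent of the vectorized implementation.
ssgsea_oracle_one <- function(x, set, alpha) {
  stopifnot(!is.null(names(x)))
  N <- length(x)
  r <- rank(x, ties.method = "average")
  inset <- names(x) %in% set
  m <- sum(inset)
  denom <- sum(r[inset]^alpha)
  p_in <- 0
  p_out <- 0
  es <- 0
  for (i in order(x, decreasing = TRUE)) {
    if (inset[i]) {
      p_in <- p_in + r[i]^alpha / denom
    } else {
      p_out <- p_out + 1 / (N - m)
    }
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Small deterministic expression matrix fixture.
toy_expr <- function(n_genes = 10, n_samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 6, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# Random survival instance (no structure) for property tests.
random_surv <- function(n, seed) {
  set.seed(seed)
  list(time = round(rexp(n, 0.1), 2),
       event = rbinom(n, 1, 0.7),
       score = sample(seq_len(n)))  # ties possible via sampling below
}

# Brute-force maximally selected rank statistic oracle: evaluate every
# feasible split with survival::survdiff and take the first maximum.
cutpoint_oracle <- function(time, event, score, minprop = 0.1) {
  n <- length(score)
  cand <- sort(unique(score))
  cand <- cand[-length(cand)]
  cand <- cand[vapply(cand, function(cc) {
    hi <- sum(score > cc)
    hi >= minprop * n && (n - hi) >= minprop * n
  }, logical(1))]
  if (!length(cand)) stop("no feasible cut")
  chis <- vapply(cand, function(cc) {
    g <- factor(score > cc)
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }, numeric(1))
  list(cutpoint = cand[which.max(chis)], chi2 = max(chis))
}
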