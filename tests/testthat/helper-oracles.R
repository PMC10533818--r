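# Independent oracles and small fixture builders shared across test files.

# Brute-force Mann-Whitney AUC: mean concordance over all case-control
# pairs, ties counted 1/2.
auc_brute <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  grid <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}

# Exact HWE p by full enumeration with choose()-based probabilities
# (independent of the lgamma route in the implementation).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nm <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (nm == 0) return(1)
  h_all <- seq(nm %% 2, min(nm, 2 * n - nm), by = 2)
  p <- vapply(h_all, function(h) {
    naa <- (nm - h) / 2
    choose(n, naa) * choose(n - naa, h) * 2^h
  }, numeric(1))
  p <- p / sum(p)
  obs <- p[h_all == n_het]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Mid-p lower tail of the noncentral hypergeometric via dhyper tilting
# (independent of the lchoose route in the implementation).
midp_lower_oracle <- function(a, b, c, d, psi) {
  m1 <- a + b
  m2 <- c + d
  t <- a + c
  supp <- max(0, t - m2):min(m1, t)
  w <- stats::dhyper(supp, m1, m2, t) * psi^supp
  w <- w / sum(w)
  sum(w[supp < a]) + 0.5 * w[supp == a]
}

# Median-unbiased OR by successively refined grid search on log psi.
or_grid_oracle <- function(a, b, c, d, target = 0.5) {
  lo <- -25
  hi <- 25
  for (step in 1:5) {
    grid <- seq(lo, hi, length.out = 200)
    vals <- vapply(grid, function(lp) {
      midp_lower_oracle(a, b, c, d, exp(lp)) - target
    }, numeric(1))
    i <- which(diff(sign(vals)) != 0)[1]
    if (is.na(i)) return(if (vals[1] < 0) 0 else Inf)
    lo <- grid[i]
    hi <- grid[i + 1]
  }
  exp((lo + hi) / 2)
}

# Small cohort configuration for fast unit tests (not the acceptance
# study conditions).
tiny_config <- function(seed = 1, ...) {
  base <- list(
    n_train = 120, n_internal = 60, n_validation = 60,
    n_snps = 20, n_mqtl_cpgs = 40, n_multi_mqtl = 4,
    n_background_cpgs = 120, n_case_cpgs = 12, case_effect = 0.4,
    seed = seed
  )
  do.call(cohort_config, utils::modifyList(base, list(...)))
}

# Deterministic toy beta matrix builder.
toy_betas <- function(values, cpg_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cpg_ids %||% sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("S%03d", seq_len(ncol(m)))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x
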