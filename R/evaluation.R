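# Evaluation utilities: ROC/AUC with DeLong CIs, stratified AUC, paired
# reduction rates, covariate correlations, and two-group tests.

#' ROC AUC with a DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties count 1/2); the
#' CI uses the asymptotic variance of the placement values (DeLong). The
#' score direction is fixed — higher scores are assumed case-like — so a
#' worse-than-chance classifier yields AUC < 0.5 rather than being
#' flipped.
#'
#' @param scores Numeric scores.
#' @param labels Case status (0/1, logical, or two-level factor).
#' @param stratum Optional label recorded in the output.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `stratum`, `auc`, `ci_low`, `ci_high`, `n_case`,
#'   `n_control`.
#' @export
roc_auc <- function(scores, labels, stratum = "all", conf_level = 0.95) {
  y <- normalize_labels(labels)
  if (length(y) != length(scores)) abort("scores and labels must align")
  if (length(unique(y)) < 2) abort("both classes must be present")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(as.numeric(
      pROC::ci.auc(r, method = "delong", conf.level = conf_level)
    )),
    error = function(e) c(a, a, a)  # degenerate (e.g. all ties)
  )
  tibble(stratum = stratum, auc = a,
         ci_low = max(0, min(ci[1], a)), ci_high = min(1, max(ci[3], a)),
         n_case = sum(y == 1), n_control = sum(y == 0))
}

#' AUC per stratum
#'
#' Strata missing either class are skipped with a warning.
#'
#' @param scores,labels As in [roc_auc()].
#' @param strata Stratum label per subject.
#' @return Tibble with one [roc_auc()] row per usable stratum.
#' @export
stratified_auc <- function(scores, labels, strata) {
  if (length(strata) != length(scores)) abort("strata must align with scores")
  y <- normalize_labels(labels)
  purrr::map_dfr(unique(as.character(strata)), function(s) {
    idx <- which(strata == s)
    if (length(unique(y[idx])) < 2) {
      warn(sprintf("stratum '%s' lacks both classes; skipped", s))
      return(NULL)
    }
    roc_auc(scores[idx], y[idx], stratum = s)
  })
}

#' ROC curve points
#'
#' @param scores,labels As in [roc_auc()].
#' @return Tibble with `threshold`, `fpr`, `tpr` along the ROC curve.
#' @export
roc_points <- function(scores, labels) {
  y <- normalize_labels(labels)
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  tibble(threshold = r$thresholds, fpr = 1 - r$specificities,
         tpr = r$sensitivities)
}

#' Fraction of paired subjects whose score decreased
#'
#' Counts pairs with `after < before`; exact ties count as non-reduced.
#'
#' @param before,after Equal-length paired score vectors.
#' @return Tibble: `n_reduced`, `n_total`, `fraction`.
#' @export
paired_reduction_rate <- function(before, after) {
  if (length(before) != length(after)) {
    abort("before and after must have equal length")
  }
  n_red <- sum(after < before)
  tibble(n_reduced = n_red, n_total = length(before),
         fraction = if (length(before) > 0) n_red / length(before) else NA_real_)
}

#' Pearson correlation of scores with a covariate, per group
#'
#' @param scores,covariate Numeric vectors.
#' @param group_labels Optional grouping (e.g. case vs control); `NULL`
#'   computes a single overall correlation.
#' @return Tibble: `group`, `n`, `r`, `p` (two-sided t-distribution
#'   p-value).
#' @export
covariate_association <- function(scores, covariate, group_labels = NULL) {
  if (length(scores) != length(covariate)) {
    abort("scores and covariate must align")
  }
  if (is.null(group_labels)) group_labels <- rep("all", length(scores))
  purrr::map_dfr(unique(as.character(group_labels)), function(g) {
    idx <- which(group_labels == g)
    if (length(idx) < 3) {
      abort(sprintf("group '%s' has fewer than 3 paired observations", g))
    }
    if (sd(covariate[idx]) == 0) {
      abort(sprintf("covariate is constant within group '%s'", g))
    }
    ct <- cor.test(scores[idx], covariate[idx], method = "pearson")
    tibble(group = g, n = length(idx),
           r = unname(ct$estimate), p = ct$p.value)
  })
}

#' Two-group difference test
#'
#' Unpaired: Welch two-sample two-tailed t-test. Paired: Wilcoxon
#' signed-rank test, exact for n <= 25 pairs (normal approximation with
#' continuity correction above, or in the presence of ties).
#'
#' @param scores_a,scores_b Score vectors (equal length when paired).
#' @param paired Logical.
#' @return Two-sided p-value.
#' @export
group_difference_test <- function(scores_a, scores_b, paired = FALSE) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    abort("each group needs at least 2 observations")
  }
  if (paired) {
    if (length(scores_a) != length(scores_b)) {
      abort("paired vectors must have equal length")
    }
    diffs <- scores_a - scores_b
    if (all(diffs == 0)) abort("all paired differences are zero")
    diffs <- diffs[diffs != 0]
    if (length(diffs) <= 25) {
      exact_signrank_p(diffs)
    } else {
      suppressWarnings(
        wilcox.test(scores_a, scores_b, paired = TRUE, exact = FALSE,
                    correct = TRUE)$p.value
      )
    }
  } else {
    t.test(scores_a, scores_b, var.equal = FALSE)$p.value
  }
}

# Exact two-sided signed-rank p-value by enumerating the 2^n sign-flip
# distribution with dynamic programming. Handles tied |differences| via
# midranks (doubled to stay integer), which the stats::wilcox.test exact
# path refuses.
exact_signrank_p <- function(diffs) {
  r2 <- as.integer(round(2 * rank(abs(diffs))))  # doubled midranks
  v_obs <- sum(r2[diffs > 0])
  # distribution of the doubled positive-rank sum over all sign patterns
  dist <- c(1, rep(0, sum(r2)))
  for (r in r2) {
    shifted <- c(rep(0, r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  p_low <- sum(dist[seq_len(v_obs + 1)])           # P(V <= v_obs)
  p_high <- sum(dist[(v_obs + 1):length(dist)])    # P(V >= v_obs)
  min(1, 2 * min(p_low, p_high))
}
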