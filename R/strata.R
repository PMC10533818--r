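# Median-split risk groups and exact conditional 2x2 inference.
#
# Odds ratios are estimated by median-unbiased estimation under Fisher's
# noncentral hypergeometric distribution conditioned on the table margins,
# with mid-p corrections throughout: the estimate is the odds ratio psi at
# which the mid-p tail probability equals one half, the 95% CI inverts the
# mid-p tails at 0.025 per side, and the p-value is the two-sided mid-p at
# psi = 1.

#' Split scores at the median into low/high groups
#'
#' The median is computed across all provided subjects; a subject is
#' "high" iff their score is strictly above it ("low" = equal to or below).
#'
#' @param scores Numeric vector (>= 1 value).
#' @return Factor with levels `low`, `high`, same length as `scores`.
#' @export
median_split <- function(scores) {
  if (length(scores) == 0) abort("scores must be non-empty")
  m <- median(scores)
  factor(ifelse(scores > m, "high", "low"), levels = c("low", "high"))
}

#' Combine PRS and index high/low labels into four risk groups
#'
#' @param prs_labels,index_labels Factors from [median_split()], same
#'   subjects in the same order.
#' @return Factor with levels `low/low`, `high/low`, `low/high`,
#'   `high/high` (PRS first); `low/low` is the reference level.
#' @export
combine_groups <- function(prs_labels, index_labels) {
  if (length(prs_labels) != length(index_labels)) {
    abort("prs_labels and index_labels must cover the same subjects")
  }
  factor(paste(prs_labels, index_labels, sep = "/"),
         levels = c("low/low", "high/low", "low/high", "high/high"))
}

# log pmf of X = a (exposed cases) under the noncentral hypergeometric
# distribution with margins fixed; support and normalized probabilities.
nchg_dist <- function(m1, m2, t, log_psi) {
  supp <- max(0, t - m2):min(m1, t)
  lp <- lchoose(m1, supp) + lchoose(m2, t - supp) + supp * log_psi
  p <- exp(lp - max(lp))
  list(supp = supp, p = p / sum(p))
}

# Mid-p lower tail P(X < a) + 0.5 P(X = a); decreasing in psi.
midp_lower_tail <- function(a, m1, m2, t, log_psi) {
  d <- nchg_dist(m1, m2, t, log_psi)
  sum(d$p[d$supp < a]) + 0.5 * d$p[d$supp == a]
}

# Solve midp_lower_tail == target on the log-psi scale. Monotone
# decreasing, so bisection via uniroot; returns 0 / Inf when the target is
# unreachable (observed count at the edge of the support).
solve_psi <- function(a, m1, m2, t, target, bracket = 40) {
  g <- function(lp) midp_lower_tail(a, m1, m2, t, lp) - target
  lo <- -bracket
  hi <- bracket
  if (g(lo) <= 0) return(0)
  if (g(hi) >= 0) return(Inf)
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-10)$root)
}

#' Median-unbiased odds ratio with mid-p CI and p-value for a 2x2 table
#'
#' @param a,b Exposed cases and controls.
#' @param c,d Reference cases and controls.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `or_hat`, `ci_low`, `ci_high`, `p` (two-sided
#'   mid-p at odds ratio 1). Zero cells are allowed; the estimate or a CI
#'   limit may then be 0 or `Inf`.
#' @export
median_unbiased_or <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  if (a + c == 0 || b + d == 0 || a + b == 0 || c + d == 0) {
    abort("every margin of the 2x2 table must be positive")
  }
  m1 <- a + b
  m2 <- c + d
  t <- a + c
  alpha <- (1 - conf_level) / 2
  # mid-p upper and lower tails sum to 1 exactly, so the psi solving
  # lower tail = 0.5 is the unique median-unbiased estimate
  or_hat <- solve_psi(a, m1, m2, t, 0.5)
  ci_low <- solve_psi(a, m1, m2, t, 1 - alpha)
  ci_high <- solve_psi(a, m1, m2, t, alpha)
  ml <- midp_lower_tail(a, m1, m2, t, 0)
  p <- min(1, 2 * min(ml, 1 - ml))
  tibble(or_hat = or_hat, ci_low = ci_low, ci_high = ci_high, p = p)
}

#' 2x2 risk table with exact odds ratios against the reference group
#'
#' Counts cases and controls per risk group and computes the
#' median-unbiased odds ratio of each non-reference group versus the first
#' level (the reference, OR fixed at 1).
#'
#' @param groups Factor of group labels (first level = reference), e.g.
#'   from [combine_groups()].
#' @param case_status Case indicators aligned with `groups`.
#' @return Tibble of class `wid_risk_table`: `group`, `cases`, `controls`,
#'   `or_hat`, `ci_low`, `ci_high`, `p` (reference row has `or_hat` 1 and
#'   `NA` CI/p).
#' @export
risk_table <- function(groups, case_status) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) {
    abort("risk_table needs at least two non-empty groups")
  }
  y <- normalize_labels(case_status)
  if (length(y) != length(groups)) {
    abort("case_status must align with groups")
  }
  counts <- tibble(group = groups, case = y) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cases = sum(.data$case),
                     controls = sum(1 - .data$case), .groups = "drop")
  ref <- counts[1, ]
  if (ref$cases == 0 || ref$controls == 0) {
    abort("reference group must contain both cases and controls")
  }
  stats_tbl <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    if (i == 1) {
      tibble(or_hat = 1, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
    } else {
      median_unbiased_or(counts$cases[i], counts$controls[i],
                         ref$cases, ref$controls)
    }
  })
  out <- dplyr::bind_cols(counts, stats_tbl)
  class(out) <- c("wid_risk_table", class(out))
  out
}

#' Odds ratios across percentile categories of one or two risk scores
#'
#' Subjects are binned by percentiles of a single score or, when a second
#' score is supplied, of the combined score (sum of the two scores after
#' standardization). Each bin is compared with the bottom bin via
#' [median_unbiased_or()]; empty bins are omitted with a warning.
#'
#' @param scores_a Primary score vector.
#' @param scores_b Optional second score to combine with the first.
#' @param case_status Case indicators.
#' @param cut_points Strictly increasing percentiles within (0, 100),
#'   default quartile cuts `c(25, 50, 75)`.
#' @return Tibble of class `wid_risk_table`: one row per bin with counts
#'   and OR statistics (bottom bin is the reference).
#' @export
quantile_or_curve <- function(scores_a, scores_b = NULL, case_status,
                              cut_points = c(25, 50, 75)) {
  if (is.unsorted(cut_points, strictly = TRUE) ||
      any(cut_points <= 0) || any(cut_points >= 100)) {
    abort("cut_points must be strictly increasing percentiles in (0, 100)")
  }
  score <- if (is.null(scores_b)) {
    scores_a
  } else {
    if (length(scores_b) != length(scores_a)) {
      abort("scores_a and scores_b must align")
    }
    drop(scale(scores_a)) + drop(scale(scores_b))
  }
  breaks <- unique(c(-Inf, quantile(score, cut_points / 100, names = FALSE),
                     Inf))
  pct_labels <- sprintf("(%s,%s]", c("0", cut_points),
                        c(cut_points, "100"))[seq_len(length(breaks) - 1)]
  bin <- cut(score, breaks = breaks, labels = pct_labels)
  empty <- setdiff(pct_labels, unique(as.character(bin)))
  if (length(empty)) {
    warn(sprintf("omitting empty percentile bin(s): %s",
                 paste(empty, collapse = ", ")))
    bin <- droplevels(bin)
  }
  risk_table(bin, case_status)
}
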