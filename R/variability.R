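# Surrogate-tissue variability: per-CpG SDs, top-variable percentile sets,
# and immune-fraction-stratified summaries across tissues.

#' Per-CpG standard deviation of beta values
#'
#' @param betas CpGs x samples beta matrix (>= 2 samples).
#' @return Tibble with `cpg_id` and unbiased (n-1 denominator) `sd`,
#'   one row per CpG in input order.
#' @export
cpg_sd <- function(betas) {
  check_named_matrix(betas, "betas")
  if (ncol(betas) < 2) {
    abort("cpg_sd needs at least 2 samples")
  }
  n <- ncol(betas)
  dev <- betas - rowMeans(betas)
  tibble(cpg_id = rownames(betas),
         sd = unname(sqrt(rowSums(dev^2) / (n - 1))))
}

#' Top-variable CpGs at a percentile cut
#'
#' Returns the `ceiling(percentile/100 * n)` CpGs with the largest SD.
#' Ties in SD are broken by lexicographic `cpg_id` so the set is
#' deterministic.
#'
#' @param var_table Tibble from [cpg_sd()] (`cpg_id`, `sd`).
#' @param percentile Value in (0, 100].
#' @return Character vector of CpG ids.
#' @export
top_variable <- function(var_table, percentile) {
  if (nrow(var_table) == 0) abort("var_table is empty")
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile > 100) {
    abort("percentile must lie in (0, 100]")
  }
  k <- ceiling(percentile / 100 * nrow(var_table))
  ord <- order(-var_table$sd, var_table$cpg_id)
  var_table$cpg_id[ord][seq_len(k)]
}

#' Variability of a CpG set across tissues, stratified by immune fraction
#'
#' For every tissue and immune-fraction bin, computes the per-CpG SDs over
#' the samples in that bin and summarizes their distribution, both for the
#' supplied CpG set (`cpg_group = "selected"`) and for all CpGs
#' (`cpg_group = "all"`, the reference rows). Bins with fewer than two
#' samples are emitted with their `n` and `NA` summaries.
#'
#' @param betas_by_tissue Named list of CpGs x samples matrices.
#' @param cpg_set CpG ids to summarize (e.g. mQTL CpGs or a
#'   [top_variable()] set).
#' @param immune_fractions Either a named list of per-sample fractions
#'   aligned with each tissue's columns, or a tibble with `tissue`,
#'   `subject_id`, `immune_fraction` (as in a cohort bundle).
#' @param bins Increasing break points covering `[0, 1]`,
#'   default `c(0, 0.25, 0.75, 1)`.
#' @return Tibble: `tissue`, `bin`, `cpg_group`, `n` (samples in bin),
#'   `median_sd`, `iqr_low`, `iqr_high`.
#' @export
stratified_variability <- function(betas_by_tissue, cpg_set, immune_fractions,
                                   bins = c(0, 0.25, 0.75, 1)) {
  if (is.unsorted(bins, strictly = TRUE) || bins[1] > 0 ||
      bins[length(bins)] < 1) {
    abort("bins must be strictly increasing breaks covering [0, 1]")
  }
  frac_for <- function(tis, b) {
    if (is.data.frame(immune_fractions)) {
      sub <- immune_fractions[immune_fractions$tissue == tis, ]
      f <- sub$immune_fraction[match(colnames(b), sub$subject_id)]
    } else {
      f <- immune_fractions[[tis]]
    }
    if (is.null(f) || length(f) != ncol(b) || anyNA(f)) {
      abort(sprintf("immune fractions missing or misaligned for tissue '%s'", tis))
    }
    f
  }
  bin_labels <- sprintf("[%g,%g%s", bins[-length(bins)], bins[-1],
                        c(rep(")", length(bins) - 2), "]"))
  purrr::map_dfr(names(betas_by_tissue), function(tis) {
    b <- betas_by_tissue[[tis]]
    f <- frac_for(tis, b)
    idx <- cut(f, breaks = bins, labels = bin_labels,
               include.lowest = TRUE, right = FALSE)
    # the last bin is closed on the right
    idx[f >= bins[length(bins) - 1]] <- bin_labels[length(bin_labels)]
    sel <- intersect(cpg_set, rownames(b))
    purrr::map_dfr(c(bin_labels, "all"), function(lab) {
      cols <- if (lab == "all") seq_len(ncol(b)) else which(idx == lab)
      purrr::map_dfr(c("selected", "all"), function(grp) {
        rows <- if (grp == "selected") sel else rownames(b)
        if (length(cols) >= 2 && length(rows) >= 1) {
          sds <- cpg_sd(b[rows, cols, drop = FALSE])$sd
          q <- quantile(sds, c(0.25, 0.5, 0.75), names = FALSE)
          tibble(tissue = tis, bin = lab, cpg_group = grp,
                 n = length(cols), median_sd = q[2],
                 iqr_low = q[1], iqr_high = q[3])
        } else {
          tibble(tissue = tis, bin = lab, cpg_group = grp,
                 n = length(cols), median_sd = NA_real_,
                 iqr_low = NA_real_, iqr_high = NA_real_)
        }
      })
    })
  })
}
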