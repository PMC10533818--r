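# Genotype QC and the polygenic risk score PRS_j = sum_i beta_hat_i x_ij,
# where beta_hat_i is a published per-SNP log odds ratio and x_ij the
# effect-allele dosage.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditions on the observed allele counts and enumerates every
#' heterozygote count compatible with them; the two-sided p-value sums the
#' probabilities of all configurations no more likely than the observed one
#' (probability-mass ordering), the standard exact HWE test used in
#' genotype QC.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total
#'   >= 1).
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotyped subject is required")
  # allele count of the rarer allele
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)  # monomorphic: single configuration
  # support: heterozygote counts with the parity of the minor allele count
  h <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log P(het = h | n, n_minor) up to the common normalizer:
  # P proportional to n! 2^h / (n_aa! h! n_AA!) with
  # n_aa = (n_minor - h)/2, n_AA = n - h - n_aa
  n_aa <- (n_minor - h) / 2
  n_AA <- n - h - n_aa
  logp <- h * log(2) - lgamma(n_aa + 1) - lgamma(h + 1) - lgamma(n_AA + 1)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[h == n_het]
  if (length(obs) == 0) {
    abort("n_het is incompatible with the allele counts")
  }
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Default genotype QC thresholds
#'
#' Per-SNP: missing rate above 5%, minor allele frequency below 1%, or
#' Hardy-Weinberg exact p below 5e-6 excludes the SNP. Per-subject: call
#' rate below 95% excludes the subject (applied first).
#'
#' @param max_missing_rate,min_maf,hwe_alpha,min_subject_call_rate
#'   Thresholds, all in (0, 1).
#' @return Named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05, min_maf = 0.01,
                          hwe_alpha = 5e-6, min_subject_call_rate = 0.95) {
  th <- list(max_missing_rate = max_missing_rate, min_maf = min_maf,
             hwe_alpha = hwe_alpha,
             min_subject_call_rate = min_subject_call_rate)
  if (any(unlist(th) <= 0) || any(unlist(th) >= 1)) {
    abort("all thresholds must lie in (0, 1)")
  }
  structure(th, class = "qc_thresholds")
}

#' Filter a genotype matrix by subject call rate and SNP-level QC
#'
#' Subjects below the call-rate threshold are removed first; SNPs failing
#' the missing-rate, MAF, or HWE filters (evaluated in that order on the
#' retained subjects) are then removed. Each SNP is excluded for the first
#' filter it fails.
#'
#' @param genotypes Subjects x SNPs dosage matrix; `NA` marks missing
#'   calls.
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (filtered matrix) and `report`, a tibble
#'   of exclusions (`id`, `type` subject/snp, `reason`, `value`).
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  check_named_matrix(genotypes, "genotypes")
  stopifnot(inherits(thresholds, "qc_thresholds"))
  report <- tibble(id = character(), type = character(),
                   reason = character(), value = double())

  call_rate <- rowMeans(!is.na(genotypes))
  bad_sub <- which(call_rate < thresholds$min_subject_call_rate)
  if (length(bad_sub)) {
    report <- dplyr::bind_rows(report, tibble(
      id = rownames(genotypes)[bad_sub], type = "subject",
      reason = "call_rate", value = call_rate[bad_sub]
    ))
    genotypes <- genotypes[-bad_sub, , drop = FALSE]
  }

  drop_snp <- logical(ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    d <- genotypes[, j]
    miss <- mean(is.na(d))
    if (miss > thresholds$max_missing_rate) {
      report <- dplyr::bind_rows(report, tibble(
        id = colnames(genotypes)[j], type = "snp",
        reason = "missing_rate", value = miss))
      drop_snp[j] <- TRUE
      next
    }
    d <- d[!is.na(d)]
    if (length(d) == 0) {
      report <- dplyr::bind_rows(report, tibble(
        id = colnames(genotypes)[j], type = "snp",
        reason = "missing_rate", value = 1))
      drop_snp[j] <- TRUE
      next
    }
    af <- mean(d) / 2
    maf <- min(af, 1 - af)
    if (maf < thresholds$min_maf) {
      report <- dplyr::bind_rows(report, tibble(
        id = colnames(genotypes)[j], type = "snp",
        reason = "maf", value = maf))
      drop_snp[j] <- TRUE
      next
    }
    p_hwe <- hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
    if (p_hwe < thresholds$hwe_alpha) {
      report <- dplyr::bind_rows(report, tibble(
        id = colnames(genotypes)[j], type = "snp",
        reason = "hwe", value = p_hwe))
      drop_snp[j] <- TRUE
    }
  }
  list(genotypes = genotypes[, !drop_snp, drop = FALSE], report = report)
}

#' Compute the polygenic risk score
#'
#' `PRS_j = sum_i weight_i * dosage_ij` over the weight SNPs present in the
#' genotype matrix. Missing dosages are imputed as twice the cohort
#' effect-allele frequency of the SNP.
#'
#' @param genotypes Subjects x SNPs dosage matrix (`NA` = missing).
#' @param weights Tibble with `snp_id` and `prs_weight` (a per-SNP log odds
#'   ratio), e.g. the relevant columns of [snp_panel()].
#' @return Tibble with `subject_id` and `prs`; attribute `n_snps_used`
#'   records how many weight SNPs entered the score.
#' @export
compute_prs <- function(genotypes, weights) {
  check_named_matrix(genotypes, "genotypes")
  if (!all(c("snp_id", "prs_weight") %in% names(weights))) {
    abort("weights must have columns snp_id and prs_weight")
  }
  shared <- intersect(weights$snp_id, colnames(genotypes))
  if (length(shared) == 0) {
    abort("no weight SNPs overlap the genotype matrix")
  }
  g <- genotypes[, shared, drop = FALSE]
  if (anyNA(g)) {
    af <- colMeans(g, na.rm = TRUE) / 2
    for (j in seq_len(ncol(g))) {
      g[is.na(g[, j]), j] <- 2 * af[j]
    }
  }
  w <- weights$prs_weight[match(shared, weights$snp_id)]
  out <- tibble(subject_id = rownames(g), prs = unname(drop(g %*% w)))
  attr(out, "n_snps_used") <- length(shared)
  out
}
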