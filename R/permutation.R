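# Permutation null for index specificity: retrain the lasso on random
# non-mQTL CpG subsets and collect held-out validation AUCs.

#' Permutation null over random non-mQTL CpG subsets
#'
#' Each permutation samples `n_cpgs` CpGs without replacement from the
#' CpGs NOT in `mqtl_cpgs`, fits a cross-validated lasso on the training
#' split, scores the held-out validation split, and records the AUC.
#' CV folds are re-randomized per permutation from that permutation's
#' child seed, and the whole run is deterministic under `seed`.
#'
#' @param betas CpGs x samples beta matrix covering all subjects.
#' @param mqtl_cpgs CpG ids excluded from the sampling pool.
#' @param labels Case status for all subjects.
#' @param split List with `train` and `validation` character vectors of
#'   sample ids (columns of `betas`).
#' @param n_perm Number of permutations (>= 1).
#' @param n_cpgs CpGs sampled per permutation.
#' @param k_folds CV folds per fit.
#' @param seed Master seed.
#' @return Object of class `wid_perm`: `aucs`, `median_auc`, `band`
#'   (central 95% interval), `n_perm`, `n_cpgs`, `seed`.
#' @export
permutation_null <- function(betas, mqtl_cpgs, labels, split,
                             n_perm = 100, n_cpgs = 120, k_folds = 10,
                             seed = 1) {
  check_named_matrix(betas, "betas")
  if (n_perm < 1) abort("n_perm must be >= 1")
  pool <- setdiff(rownames(betas), mqtl_cpgs)
  if (length(pool) < n_cpgs) {
    abort(sprintf("non-mQTL pool (%d CpGs) is smaller than n_cpgs = %d",
                  length(pool), n_cpgs))
  }
  if (!all(c("train", "validation") %in% names(split))) {
    abort("split must name 'train' and 'validation' sample sets")
  }
  tr <- match(split$train, colnames(betas))
  va <- match(split$validation, colnames(betas))
  if (anyNA(tr) || anyNA(va)) abort("split ids must be columns of betas")
  y <- normalize_labels(labels)

  seeds <- child_seeds(seed, 2 * n_perm)
  aucs <- vapply(seq_len(n_perm), function(b) {
    cpgs <- withr::with_seed(seeds[2 * b - 1], sample(pool, n_cpgs))
    fit <- fit_penalized_classifier(
      betas[cpgs, tr, drop = FALSE], y[tr], penalty = "L1",
      k_folds = k_folds, seed = seeds[2 * b]
    )
    scores <- raw_index(betas[cpgs, va, drop = FALSE], fit$model)
    if (length(unique(scores)) == 1) return(0.5)  # nothing selected
    roc_auc(scores, y[va])$auc
  }, numeric(1))

  structure(
    list(aucs = aucs, median_auc = median(aucs),
         band = quantile(aucs, c(0.025, 0.975), names = FALSE),
         n_perm = n_perm, n_cpgs = n_cpgs, seed = seed),
    class = "wid_perm"
  )
}

#' @export
print.wid_perm <- function(x, ...) {
  cat(sprintf(
    "<wid_perm> %d permutations of %d CpGs: median AUC %.3f, 95%% band [%.3f, %.3f]\n",
    x$n_perm, x$n_cpgs, x$median_auc, x$band[1], x$band[2]
  ))
  invisible(x)
}

#' @export
#' @method tidy wid_perm
tidy.wid_perm <- function(x, ...) {
  tibble(permutation = seq_along(x$aucs), auc = x$aucs)
}

#' @export
#' @method glance wid_perm
glance.wid_perm <- function(x, ...) {
  tibble(n_perm = x$n_perm, n_cpgs = x$n_cpgs,
         median_auc = x$median_auc,
         band_low = x$band[1], band_high = x$band[2])
}
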