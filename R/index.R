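# The methylation risk index: penalized logistic training on mQTL CpGs,
# internal-validation model selection, finalization with discovery-set
# scaling, and scoring. The index for subject j is
#   score_j = (sum_i w_i beta_ij - mu) / sigma
# where mu and sigma are the mean and SD of sum_i w_i beta_ij over the
# discovery subjects, so the scored discovery set has mean 0 and SD 1.

#' Construct a risk-index model by hand
#'
#' Useful for loading published CpG/coefficient tables or for building tiny
#' fixtures; [finalize_index()] builds one from data.
#'
#' @param cpg_ids CpG identifiers.
#' @param weights Per-CpG weights on the beta scale (same length).
#' @param mu,sigma Scaling constants; `sigma` must be > 0.
#' @param intercept Logistic intercept (kept for probability prediction;
#'   not used in index scoring, where centring absorbs it).
#' @param penalty "L1" or "L2".
#' @param lambda Regularization strength used in fitting, if any.
#' @return Object of class `wid_index`.
#' @export
wid_index <- function(cpg_ids, weights, mu = 0, sigma = 1,
                      intercept = 0, penalty = NA_character_,
                      lambda = NA_real_) {
  if (length(cpg_ids) != length(weights)) {
    abort("cpg_ids and weights must have equal length")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) ||
      sigma <= 0) {
    abort("sigma must be a single positive number")
  }
  structure(
    list(cpg_ids = as.character(cpg_ids), weights = as.numeric(weights),
         mu = mu, sigma = sigma, intercept = intercept,
         penalty = penalty, lambda = lambda),
    class = "wid_index"
  )
}

#' @export
print.wid_index <- function(x, ...) {
  cat(sprintf("<wid_index> %d CpGs, penalty %s, lambda %.4g, mu %.4g, sigma %.4g\n",
              length(x$cpg_ids), x$penalty, x$lambda, x$mu, x$sigma))
  invisible(x)
}

# Class-stratified fold assignment, deterministic under seed.
stratified_folds <- function(labels, k_folds, seed) {
  foldid <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      foldid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  foldid
}

#' Fit a penalized logistic classifier on mQTL CpG betas
#'
#' Cross-validated lasso (L1) or ridge (L2) logistic regression over a
#' descending lambda path; the chosen lambda minimizes mean cross-validated
#' binomial deviance. Folds are stratified by case status and the fit is
#' deterministic under `seed`. Returned weights are on the beta scale
#' (predictors are standardized internally only).
#'
#' @param betas CpGs x samples beta matrix, no missing values.
#' @param labels Case status (0/1, logical, or two-level factor).
#' @param penalty "L1" (lasso) or "L2" (ridge).
#' @param k_folds Number of CV folds (>= 2, <= n).
#' @param seed Integer seed for fold assignment.
#' @param lambda Optional fixed lambda overriding the CV choice.
#' @return List with `model` (a [wid_index()] without scaling, i.e.
#'   mu = 0, sigma = 1; for L1 only the non-zero-weight CpGs are kept) and
#'   `report` (class `wid_train_report`: `cv_curve` tibble of lambda vs mean
#'   CV binomial deviance, `chosen_lambda`, `n_nonzero`,
#'   `internal_validation_auc` — `NA` until [select_model()]).
#' @export
fit_penalized_classifier <- function(betas, labels, penalty = c("L1", "L2"),
                                     k_folds = 10, seed = 1, lambda = NULL) {
  check_named_matrix(betas, "betas")
  penalty <- match.arg(penalty)
  if (anyNA(betas)) abort("betas must not contain missing values")
  y <- normalize_labels(labels)
  if (length(y) != ncol(betas)) abort("labels must match the number of samples")
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  if (k_folds < 2) abort("k_folds must be >= 2")
  if (k_folds > length(y)) abort("k_folds must not exceed the sample size")

  x <- t(betas)
  alpha <- if (penalty == "L1") 1 else 0
  foldid <- stratified_folds(y, k_folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          foldid = foldid, type.measure = "deviance",
                          standardize = TRUE)
  chosen <- if (is.null(lambda)) cv$lambda.min else lambda
  cf <- as.numeric(coef(cv$glmnet.fit, s = chosen, exact = FALSE))
  w <- setNames(cf[-1], rownames(betas))
  intercept <- cf[1]
  keep <- if (penalty == "L1") which(w != 0) else seq_along(w)
  model <- wid_index(names(w)[keep], unname(w[keep]), mu = 0, sigma = 1,
                     intercept = intercept, penalty = penalty,
                     lambda = chosen)
  report <- structure(
    list(cv_curve = tibble(lambda = cv$lambda, mean_deviance = cv$cvm),
         chosen_lambda = chosen, n_nonzero = sum(w != 0),
         penalty = penalty, internal_validation_auc = NA_real_),
    class = "wid_train_report"
  )
  list(model = model, report = report)
}

#' @export
print.wid_train_report <- function(x, ...) {
  cat(sprintf(
    "<wid_train_report> %s, lambda %.4g, %d non-zero weights, internal AUC %s\n",
    x$penalty, x$chosen_lambda, x$n_nonzero,
    ifelse(is.na(x$internal_validation_auc), "not evaluated",
           sprintf("%.3f", x$internal_validation_auc))
  ))
  invisible(x)
}

# Unscaled linear predictor sum_i w_i beta_ij for model CpGs.
raw_index <- function(betas, model) {
  missing <- setdiff(model$cpg_ids, rownames(betas))
  if (length(missing)) {
    abort(sprintf("betas lack model CpG(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (length(model$cpg_ids) == 0) {
    return(setNames(numeric(ncol(betas)), colnames(betas)))
  }
  drop(crossprod(betas[model$cpg_ids, , drop = FALSE], model$weights))
}

#' Select the best candidate model on internal-validation AUC
#'
#' Ties in AUC are broken toward the model with fewer non-zero weights.
#'
#' @param candidates List of `list(model, report)` pairs from
#'   [fit_penalized_classifier()].
#' @param internal_betas,internal_labels Internal-validation data.
#' @return List with the winning `model` and `report` (AUC filled in) and
#'   a `selection` tibble of all candidates.
#' @export
select_model <- function(candidates, internal_betas, internal_labels) {
  if (length(candidates) == 0) abort("candidates must be non-empty")
  aucs <- purrr::map_dbl(candidates, function(cand) {
    scores <- raw_index(internal_betas, cand$model)
    if (length(unique(scores)) == 1) 0.5
    else roc_auc(scores, internal_labels)$auc
  })
  nz <- purrr::map_int(candidates, function(cand) {
    as.integer(cand$report$n_nonzero)
  })
  selection <- tibble(
    candidate = seq_along(candidates),
    penalty = purrr::map_chr(candidates, function(cand) cand$model$penalty),
    internal_validation_auc = aucs,
    n_nonzero = nz
  )
  best <- order(-aucs, nz)[1]
  out <- candidates[[best]]
  out$report$internal_validation_auc <- aucs[best]
  out$selection <- selection
  out
}

#' Finalize the risk index on the full discovery set
#'
#' Refits the chosen penalty on the combined discovery data (training plus
#' internal validation), then sets the scaling constants mu and sigma to the
#' mean and SD of `sum_i w_i beta_ij` over the discovery subjects, so that
#' the scored discovery set has mean 0 and SD 1.
#'
#' @inheritParams fit_penalized_classifier
#' @param penalty Penalty of the selected model ("L1" by default).
#' @return A scaled [wid_index()].
#' @export
finalize_index <- function(betas, labels, penalty = "L1", k_folds = 10,
                           seed = 1, lambda = NULL) {
  fit <- fit_penalized_classifier(betas, labels, penalty = penalty,
                                  k_folds = k_folds, seed = seed,
                                  lambda = lambda)
  model <- fit$model
  if (length(model$cpg_ids) == 0 || all(model$weights == 0)) {
    abort("finalized model has no non-zero CpG weights; cannot scale")
  }
  raw <- raw_index(betas, model)
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    abort("raw index is constant over the discovery set (sigma = 0)")
  }
  model$mu <- mean(raw)
  model$sigma <- s
  model$report <- fit$report
  model
}

#' Score subjects with a finalized risk index
#'
#' `score_j = (sum_i w_i beta_ij - mu) / sigma`.
#'
#' @param betas CpGs x samples beta matrix containing every model CpG.
#' @param model A [wid_index()].
#' @return Tibble with `subject_id` and `score`.
#' @export
compute_index <- function(betas, model) {
  stopifnot(inherits(model, "wid_index"))
  raw <- raw_index(betas, model)
  tibble(subject_id = colnames(betas),
         score = unname((raw - model$mu) / model$sigma))
}

#' @export
#' @method tidy wid_index
tidy.wid_index <- function(x, ...) {
  tibble(cpg_id = x$cpg_ids, weight = x$weights)
}

#' @export
#' @method glance wid_index
glance.wid_index <- function(x, ...) {
  tibble(n_cpgs = length(x$cpg_ids), penalty = x$penalty,
         lambda = x$lambda, mu = x$mu, sigma = x$sigma,
         intercept = x$intercept)
}
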