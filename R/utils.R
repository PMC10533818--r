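# Internal helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Derive independent child seeds from one master seed
#'
#' Expands a single integer seed into `n` reproducible child seeds so that
#' pipeline stages (genotype sampling, methylation noise, fold assignment,
#' permutation draws, ...) consume independent random streams while the whole
#' run stays deterministic under the master seed.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(n), n >= 0)
  if (n == 0) return(integer(0))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Coerce case labels to 0/1 integer. Accepts 0/1 numeric, logical, or a
# two-level factor (second level = case).
normalize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) > 2) abort("labels must have at most two levels")
    return(as.integer(labels == levels(labels)[2]))
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  abort("labels must be 0/1, logical, or a two-level factor")
}

# Stop unless x is a numeric matrix with row and column names.
check_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("%s must have row and column names", what))
  }
  invisible(x)
}
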