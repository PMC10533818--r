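# ggplot2 helpers for the main result types.

#' @export
#' @method autoplot wid_perm
autoplot.wid_perm <- function(object, observed_auc = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$median_auc,
                        linetype = "dashed") +
    ggplot2::labs(x = "validation AUC (random CpG subsets)", y = "permutations",
                  title = sprintf("Permutation null (%d draws of %d CpGs)",
                                  object$n_perm, object$n_cpgs))
  if (!is.null(observed_auc)) {
    p <- p + ggplot2::geom_vline(xintercept = observed_auc,
                                 colour = "firebrick", linewidth = 1)
  }
  p
}

#' @export
#' @method autoplot wid_risk_table
autoplot.wid_risk_table <- function(object, ...) {
  df <- as_tibble(object)
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_hat, y = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2,
      na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (median-unbiased, 95% mid-p CI)",
                  y = NULL)
}

#' ROC curve plot
#'
#' @param scores,labels As in [roc_auc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  res <- roc_auc(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                                  res$auc, res$ci_low, res$ci_high))
}

#' Variability summary plot (median SD per tissue and immune-fraction bin)
#'
#' @param summary Tibble from [stratified_variability()].
#' @return A ggplot object.
#' @export
plot_variability <- function(summary) {
  df <- summary[!is.na(summary$median_sd), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$median_sd,
                                   fill = .data$cpg_group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$iqr_low, ymax = .data$iqr_high),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tissue)) +
    ggplot2::labs(x = "immune-fraction bin", y = "median per-CpG SD",
                  fill = "CpG set")
}
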