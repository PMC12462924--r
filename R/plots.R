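#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-curve plot
#'
#' @param object A `dti_model` with a non-empty training log.
#' @param ... Unused.
#' @return A ggplot of the logged quantities over epochs.
#' @export
autoplot.dti_model <- function(object, ...) {
  df <- tidy(object)
  if (!nrow(df)) rlang::abort("model has no training log to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-episode metric distribution
#'
#' @param object A `fewshot_eval`.
#' @param ... Unused.
#' @return A ggplot showing the spread of AUROC/AUPRC/ACC across episodes.
#' @export
autoplot.fewshot_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_episode, c("auroc", "auprc", "acc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "per-episode value") +
    ggplot2::theme_minimal()
}

#' Attention profile plot
#'
#' @param attention A tibble from [extract_attention()].
#' @param entity `"atom"` or `"residue"`.
#' @return A ggplot of attention mass by position, highlighted positions
#'   marked.
#' @export
plot_attention <- function(attention, entity = c("atom", "residue")) {
  entity <- match.arg(entity)
  df <- attention[attention$entity == entity, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~level, scales = "free", ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = "top fraction") +
    ggplot2::labs(x = paste(entity, "index"), y = "attention mass") +
    ggplot2::theme_minimal()
}
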