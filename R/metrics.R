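# Evaluation metrics and the virtual-screening score.

#' Classification metrics for scored pairs
#'
#' AUROC uses the rank (Mann-Whitney) formulation with ties counted half;
#' AUPRC integrates the precision-recall curve stepwise over distinct score
#' thresholds; accuracy thresholds the score at 0.5. With single-class labels
#' AUROC and AUPRC are reported as `NA` with a warning.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric vector of the same length.
#' @return A one-row tibble `auroc`, `auprc`, `acc`, `n`.
#' @export
compute_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), length(labels) >= 1L)
  if (any(!is.finite(scores))) rlang::abort("non-finite scores")
  labels <- as.integer(labels)
  acc <- mean((scores > 0.5) == (labels == 1L))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    rlang::warn("single-class labels: AUROC/AUPRC not defined")
    return(tibble::tibble(auroc = NA_real_, auprc = NA_real_, acc = acc,
                          n = length(labels)))
  }
  r <- rank(scores) # average ranks handle ties as half-wins
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores)
  ls <- labels[ord]
  ss <- scores[ord]
  grp_end <- which(c(ss[-1L] != ss[-length(ss)], TRUE))
  tp <- cumsum(ls)[grp_end]
  fp <- cumsum(1L - ls)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)

  tibble::tibble(auroc = auroc, auprc = auprc, acc = acc, n = length(labels))
}

#' Virtual-screening score
#'
#' Combines the interaction probability and predicted affinity as
#' `y_c^2 * y_r`: squaring the classifier output emphasizes the initial
#' binds/does-not-bind call before weighting by predicted binding strength.
#'
#' @param y_c Interaction probability in \[0, 1\].
#' @param y_r Predicted affinity (pK scale).
#' @return `y_c^2 * y_r`, vectorized.
#' @export
screening_score <- function(y_c, y_r) {
  if (any(y_c < 0 | y_c > 1)) rlang::abort("y_c must lie in [0, 1]")
  y_c^2 * y_r
}

#' Rank candidate pairs by the screening score
#'
#' Predicts `y_c` and `y_r` for every pair, ranks by `y_c^2 * y_r`, and, when
#' labels are available, reports the precision within the top fraction.
#'
#' @param model A trained `dti_model`.
#' @param pairs Tibble with `drug_id`, `protein_id` and optionally `label`.
#' @param features A [featurize_dataset()] result.
#' @param top_fraction Fraction of the ranking used for the precision report
#'   (default 0.1, i.e. the top 10 percent).
#' @return The scored tibble sorted by decreasing score, with attribute
#'   `top_precision` when labels are present.
#' @export
screen_pairs <- function(model, pairs, features, top_fraction = 0.1) {
  out <- predict_pairs(model, pairs, features, affinity = TRUE)
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  if ("label" %in% names(out)) {
    m <- ceiling(top_fraction * nrow(out))
    attr(out, "top_precision") <- mean(out$label[seq_len(m)] == 1L)
  }
  out
}
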