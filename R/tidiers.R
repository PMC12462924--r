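#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model's training log
#'
#' @param x A `dti_model`.
#' @param ... Unused.
#' @return The per-epoch log as a long tibble (`epoch`, `metric`, `value`).
#' @export
tidy.dti_model <- function(x, ...) {
  if (!nrow(x$log)) return(tibble::tibble(epoch = integer(), metric = character(),
                                          value = numeric()))
  tidyr::pivot_longer(x$log, -"epoch", names_to = "metric", values_to = "value")
}

#' One-row model summary
#'
#' @param x A `dti_model`.
#' @param ... Unused.
#' @return A tibble with the stage, parameter count, levels, fusion
#'   dimension, epochs trained and final validation AUROC (if logged).
#' @export
glance.dti_model <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    n_parameters = sum(vapply(x$params, function(p) length(p$v), 0)),
    n_levels = x$config$n_levels,
    fusion_dim = x$config$fusion_dim,
    epochs = if (nrow(x$log)) max(x$log$epoch) else 0L,
    val_auroc = if ("val_auroc" %in% names(x$log) && nrow(x$log)) {
      x$log$val_auroc[nrow(x$log)]
    } else NA_real_
  )
}

#' Per-episode few-shot metrics
#'
#' @param x A `fewshot_eval`.
#' @param ... Unused.
#' @return The per-episode metric tibble.
#' @export
tidy.fewshot_eval <- function(x, ...) x$per_episode

#' Aggregate few-shot metrics
#'
#' @param x A `fewshot_eval`.
#' @param ... Unused.
#' @return A one-row tibble of means and standard deviations.
#' @export
glance.fewshot_eval <- function(x, ...) {
  s <- x$summary
  out <- as.list(c(stats::setNames(s$mean, s$metric),
                   stats::setNames(s$sd, paste0(s$metric, "_sd"))))
  out$n_episodes <- nrow(x$per_episode)
  tibble::as_tibble(out)
}
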