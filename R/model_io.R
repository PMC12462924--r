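# Plain-text (JSON) model checkpoints with the configuration embedded.

#' Save a model checkpoint
#'
#' Serializes the configuration, stage, seed and all parameter matrices to a
#' single JSON file.
#'
#' @param model A `dti_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    package = "metadti",
    config = unclass(model$config),
    stage = model$stage,
    seed = model$seed,
    params = lapply(model$params, function(p) {
      list(dim = dim(p$v), data = as.numeric(p$v))
    }),
    log = model$log
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_model()].
#' @return A `dti_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- encoder_config(
    n_levels = cfg$n_levels, embed_dim = cfg$embed_dim,
    protein_channels = cfg$protein_channels,
    protein_kernel_sizes = cfg$protein_kernel_sizes,
    drug_hidden_dims = cfg$drug_hidden_dims, fusion_dim = cfg$fusion_dim,
    attention_rank = cfg$attention_rank, dropout = cfg$dropout,
    l_max = cfg$l_max, use_stem = cfg$use_stem, use_gates = cfg$use_gates,
    fs_on_gated_sum = cfg$fs_on_gated_sum, head_hidden = cfg$head_hidden,
    disc_hidden = cfg$disc_hidden, conditioning = cfg$conditioning
  )
  params <- lapply(obj$params, function(p) {
    tg_param(matrix(p$data, p$dim[1L], p$dim[2L]))
  })
  structure(list(
    config = config, params = params, stage = obj$stage,
    seed = as.integer(obj$seed),
    log = tibble::as_tibble(obj$log)
  ), class = "dti_model")
}
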