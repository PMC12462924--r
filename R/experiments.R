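# Reproducible desk-scale benchmark experiments: the synthetic planted-rule
# dataset, a shifted family split, stage-one adversarial pre-training and
# stage-two episodic meta-learning, wrapped so that scripts, tests and the
# vignette run the identical protocol.

#' Desk-scale encoder configuration
#'
#' The compact encoder used for the package's synthetic benchmark
#' experiments: level-1..3 kernels of width 9 (so a single convolution spans
#' a planted motif), 8 channels per branch, fusion dimension 16. Small enough
#' to train on one CPU core in minutes while leaving the architecture
#' unchanged.
#'
#' @param ... Overrides passed to [encoder_config()].
#' @return An `encoder_config`.
#' @export
desk_encoder_config <- function(...) {
  encoder_config(embed_dim = 8L, protein_channels = rep(8L, 3),
                 protein_kernel_sizes = rep(9L, 3),
                 drug_hidden_dims = rep(8L, 3), fusion_dim = 16L,
                 attention_rank = 4L, head_hidden = 8L, disc_hidden = 8L,
                 l_max = 200L, ...)
}

#' Prepare the shifted-domain benchmark
#'
#' Generates (or reuses) the default synthetic dataset, holds out
#' `n_target_families` protein families as the target domain and subsamples
#' the source interactions.
#'
#' @param seed Integer seed for the split and subsample.
#' @param n_source_pairs Number of labeled source pairs kept.
#' @param n_target_families Families held out as target domain.
#' @param dataset Optional pre-generated [generate_dataset()] result.
#' @return List with `source`, `target`, `features`, `ground_truth`,
#'   `dataset`.
#' @export
prepare_benchmark <- function(seed = 11L, n_source_pairs = 400L,
                              n_target_families = 2L, dataset = NULL) {
  ds <- dataset %||% generate_dataset(synthetic_config())
  sp <- make_shifted_split(ds, n_target_families = n_target_families,
                           seed = seed)
  src <- sp$source
  source_all <- src$interactions
  if (n_source_pairs < nrow(src$interactions)) {
    withr::with_seed(seed, {
      src$interactions <- src$interactions[
        sample(nrow(src$interactions), n_source_pairs), , drop = FALSE]
    })
  }
  features <- featurize_dataset(list(
    proteins = dplyr::bind_rows(sp$source$proteins, sp$target$proteins),
    drugs = ds$drugs
  ), l_max = 200L)
  list(source = src, source_all_interactions = source_all,
       target = sp$target, features = features,
       ground_truth = sp$ground_truth, dataset = ds,
       target_families = sp$target_families)
}

#' Stage-one benchmark run
#'
#' Trains the encoder for 30 epochs on the benchmark's labeled source pairs
#' (batch 8, Adam at 6e-3 with weight decay 1e-3, affinity auxiliary 0.1),
#' with or without the category-aware adversarial alignment, and evaluates
#' source-validation and target-domain zero-shot AUROC.
#'
#' @param bench A [prepare_benchmark()] result.
#' @param seed Integer seed (initialization + batching).
#' @param cada If `TRUE`, run the dual-discriminator adversarial alignment
#'   with the ramped lambda schedule; if `FALSE`, plain supervised training.
#' @param epochs Training epochs.
#' @param verbose Print per-epoch losses.
#' @return List with the trained `model`, `val_auroc` (final epoch),
#'   `target_auroc` and the training `log`.
#' @export
run_stage_one <- function(bench, seed = 11L, cada = TRUE, epochs = 30L,
                          verbose = FALSE) {
  model <- train_inductive(
    bench$source, bench$target, desk_encoder_config(),
    epochs = epochs, batch_size = 8L, lr = 6e-3,
    lambda = if (cada) 1 else 0,
    lambda_schedule = if (cada) "dann_ramp" else "constant",
    lr_decay = "constant", weight_decay = 1e-3, affinity_weight = 0.1,
    val_every = 5L, seed = seed, features = bench$features, verbose = verbose
  )
  target_auroc <- evaluate_zeroshot(model, bench$target$interactions,
                                    bench$features)$auroc
  list(model = model,
       val_auroc = if (nrow(model$log)) model$log$val_auroc[nrow(model$log)] else NA_real_,
       target_auroc = target_auroc, log = model$log)
}

#' Stage-two benchmark run
#'
#' Builds 2-way k-shot episodes from the source-domain protein clusters,
#' meta-trains from the stage-one checkpoint, and evaluates on episodes drawn
#' from the held-out target clusters (unseen-protein mode throughout).
#'
#' @param bench A [prepare_benchmark()] result.
#' @param model A stage-one `dti_model` checkpoint.
#' @param k Shots per class.
#' @param seed Integer seed (episodes + meta-training).
#' @param epochs Meta-training epochs.
#' @param n_tasks Training episodes per epoch pass.
#' @param n_eval_tasks Held-out evaluation episodes.
#' @param k_q Query pairs per episode.
#' @param use_attention Attention-weighted prototypes (`FALSE` = mean
#'   prototypes ablation).
#' @param lr Meta-stage Adam learning rate.
#' @param meta_batch Episodes per gradient step.
#' @param train_encoder Update the encoder during meta-training (see
#'   [train_meta()]).
#' @return List with the meta-trained `model`, the `fewshot_eval` result
#'   `eval`, and `auroc` (mean over evaluation episodes).
#' @export
run_stage_two <- function(bench, model, k = 5L, seed = 13L, epochs = 40L,
                          n_tasks = 12L, n_eval_tasks = 20L, k_q = 5L,
                          use_attention = TRUE, lr = 6e-3, meta_batch = 4L,
                          train_encoder = TRUE) {
  n_src_cl <- max(2L, 6L - length(bench$target_families))
  src_asn <- cluster_proteins(bench$source$proteins, n_clusters = n_src_cl,
                              seed = seed)
  tgt_asn <- cluster_proteins(bench$target$proteins,
                              n_clusters = max(2L, length(bench$target_families)),
                              seed = seed)
  train_eps <- build_episodes(bench$source_all_interactions, src_asn, k = k,
                              k_q = k_q, n_tasks = n_tasks,
                              mode = "unseen_protein", seed = seed)
  eval_eps <- build_episodes(bench$target$interactions, tgt_asn, k = k,
                             k_q = k_q, n_tasks = n_eval_tasks,
                             mode = "unseen_protein", seed = seed + 1L)
  meta <- train_meta(train_eps, model, bench$features,
                     focal = focal_params(alpha = 1, gamma = 2),
                     meta_batch = meta_batch, epochs = epochs, lr = lr,
                     seed = seed, use_attention = use_attention,
                     train_encoder = train_encoder)
  ev <- evaluate_fewshot(meta, eval_eps, bench$features,
                         use_attention = use_attention)
  list(model = meta, eval = ev,
       auroc = ev$summary$mean[ev$summary$metric == "auroc"])
}
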