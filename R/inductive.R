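# Stage one: supervised source-domain training plus category-aware
# domain-adversarial alignment (gradient reversal + one domain discriminator
# per interaction class) against unlabeled target-domain pairs.

#' Gradient reversal layer
#'
#' Identity in the forward pass; on the backward pass the gradient reaching
#' upstream layers is multiplied by `-lambda`. On plain numeric input the
#' function simply returns its input (there is no tape to reverse).
#'
#' @param x A numeric matrix/vector, or an internal tape tensor during
#'   training.
#' @param lambda Nonnegative reversal strength.
#' @return `x`, unchanged in value.
#' @export
grl <- function(x, lambda) {
  stopifnot(lambda >= 0)
  if (tg_is(x)) tg_grl(x, lambda) else x
}

# discriminator k in {0, 1}: two-layer MLP returning logits (n x 1)
disc_logits_core <- function(params, k, X) {
  H <- tg_relu(tg_add(tg_matmul(X, params[[paste0("Wdisc", k, "_1")]]),
                      params[[paste0("bdisc", k, "_1")]]))
  tg_add(tg_matmul(H, params[[paste0("wdisc", k, "_2")]]),
         params[[paste0("bdisc", k, "_2")]])
}

# Category-conditioned adversarial loss on (already reversed) features.
# feats: ((n_s+n_t) x fusion_dim) tensor; probs: numeric matrix with columns
# (p_class0, p_class1); domain: 0 = source, 1 = target.
cada_loss_core <- function(params, feats, probs, domain,
                           conditioning = "scalar") {
  d <- matrix(domain, ncol = 1L)
  terms <- vector("list", 2L)
  for (k in 0:1) {
    Xk <- if (conditioning == "concat") {
      tg_hstack(list(tg_mul(feats, tg_const(matrix(probs[, k + 1L], ncol = 1L))),
                     tg_const(probs)))
    } else {
      tg_mul(feats, tg_const(matrix(probs[, k + 1L], ncol = 1L)))
    }
    z <- disc_logits_core(params, k, Xk)
    terms[[k + 1L]] <- tg_mean(tg_bce_logits(z, d))
  }
  tg_scale(tg_add(terms[[1L]], terms[[2L]]), 0.5)
}

#' Category-aware adversarial domain loss
#'
#' For each interaction class k in {0, 1}, every feature row is scaled by its
#' predicted probability for class k and passed to that class's domain
#' discriminator; a binary cross-entropy against the domain label
#' (source = 0, target = 1) is averaged over all `2 * (n_s + n_t)` terms.
#'
#' @param source_features,target_features Numeric matrices (rows x
#'   fusion_dim).
#' @param class_probs Numeric matrix `(n_s + n_t) x 2`; rows must sum to 1
#'   (columns: probability of class 0, class 1), source rows first.
#' @param params Discriminator parameters (named list with
#'   `Wdisc{0,1}_1`, `bdisc{0,1}_1`, `wdisc{0,1}_2`, `bdisc{0,1}_2`).
#' @param conditioning `"scalar"` (default) or `"concat"`; see
#'   [encoder_config()].
#' @return The scalar loss L_d.
#' @export
category_adversarial_loss <- function(source_features, target_features,
                                      class_probs, params,
                                      conditioning = "scalar") {
  n_s <- nrow(source_features)
  n_t <- nrow(target_features)
  if (n_s < 1L || n_t < 1L) rlang::abort("need at least one row per domain")
  stopifnot(nrow(class_probs) == n_s + n_t, ncol(class_probs) == 2L)
  if (any(abs(rowSums(class_probs) - 1) > 1e-6)) {
    rlang::abort("class probability rows must sum to 1")
  }
  feats <- rbind(source_features, target_features)
  domain <- c(rep(0, n_s), rep(1, n_t))
  pt <- lapply(params, tg_const)
  out <- tg_no_grad(cada_loss_core(pt, tg_const(feats), class_probs, domain,
                                   conditioning))
  as.numeric(tg_v(out))
}

#' Combined stage-one objective
#'
#' `L = L_s + lambda * L_d`: the supervised source cross-entropy plus the
#' lambda-weighted adversarial term. During training the gradient reversal
#' layer makes the encoder ascend L_d while the discriminators descend it.
#'
#' @param L_s,L_d Finite scalars.
#' @param lambda Nonnegative weight.
#' @return The combined scalar objective.
#' @export
combined_objective <- function(L_s, L_d, lambda) {
  stopifnot(is.finite(L_s), is.finite(L_d), lambda >= 0)
  L_s + lambda * L_d
}

# lambda schedule over training progress p in [0, 1]
lambda_at <- function(schedule, lambda, p) {
  switch(schedule,
    constant = lambda,
    dann_ramp = lambda * (2 / (1 + exp(-10 * p)) - 1)
  )
}

# deep-copy a model so training never mutates its input
clone_model <- function(model) {
  model$params <- lapply(model$params, function(p) tg_param(p$v))
  model
}

encode_batch_features <- function(params, cfg, features, pairs) {
  up <- unique(pairs$protein_id)
  ud <- unique(pairs$drug_id)
  Pf <- lapply(up, function(id) enc_protein_core(params, cfg, features$tokens[[id]]))
  names(Pf) <- up
  Df <- lapply(ud, function(id) {
    enc_drug_core(params, cfg, features$graphs[[id]], features$adj[[id]])
  })
  names(Df) <- ud
  O_rows <- lapply(seq_len(nrow(pairs)), function(j) {
    fuse_pair_core(params, cfg, Pf[[pairs$protein_id[j]]],
                   Df[[pairs$drug_id[j]]])$O
  })
  tg_vstack(O_rows)
}

head_logits_core <- function(params, O) {
  H <- tg_relu(tg_add(tg_matmul(O, params$Wh1), params$bh1))
  tg_add(tg_matmul(H, params$wh2), params$bh2)
}

#' Stage-one inductive training with domain-adversarial alignment
#'
#' Trains the encoder and classification head on labeled source-domain pairs
#' while aligning source and target feature distributions per interaction
#' class: fused features pass through a gradient reversal layer and
#' class-probability-scaled copies feed two domain discriminators (one per
#' class). A single backward sweep therefore makes the discriminators
#' minimize their domain cross-entropy while the encoder maximizes it,
#' weighted by `lambda`. Rows of the source interaction table with an
#' `affinity` value additionally train the affinity head (squared error).
#'
#' @param source List with `proteins`, `drugs`, `interactions` (labeled).
#' @param target List with `proteins`, `drugs`, `interactions` (labels
#'   ignored). Source and target protein ids must be disjoint.
#' @param config An [encoder_config()]; ignored when `model` is supplied.
#' @param epochs Training epochs over the source pairs (0 = return the
#'   initialized model unchanged).
#' @param batch_size Mini-batch size (per domain).
#' @param lr Adam learning rate.
#' @param lambda Peak adversarial weight.
#' @param lambda_schedule `"dann_ramp"` ramps lambda with training progress p
#'   as `lambda * (2 / (1 + exp(-10 p)) - 1)`; `"constant"` keeps it fixed.
#' @param affinity_weight Weight of the affinity regression term relative to
#'   the classification loss.
#' @param weight_decay Decoupled weight decay applied by the optimizer.
#' @param lr_decay `"cosine"` anneals the learning rate to zero over
#'   training; `"constant"` keeps it fixed.
#' @param val_fraction Fraction of source pairs held out for validation
#'   metrics.
#' @param val_every Evaluate validation AUROC every this many epochs (always
#'   at the final epoch).
#' @param seed Integer seed covering initialization, batching and the
#'   validation split.
#' @param features Optional precomputed [featurize_dataset()] over the union
#'   of both domains.
#' @param model Optional initialized `dti_model` to continue from.
#' @param verbose Print per-epoch losses.
#' @return A trained `dti_model` (stage `"inductive"`) whose `log` holds one
#'   row per epoch: `epoch`, `L_s`, `L_d`, `lambda`, `val_auroc`.
#' @export
train_inductive <- function(source, target, config = encoder_config(),
                            epochs = 30L, batch_size = 32L, lr = 1e-3,
                            lambda = 1, lambda_schedule = c("dann_ramp", "constant"),
                            affinity_weight = 0.1, weight_decay = 1e-4,
                            lr_decay = c("cosine", "constant"),
                            val_fraction = 0.2, val_every = 1L, seed = 1L,
                            features = NULL, model = NULL, verbose = FALSE) {
  lambda_schedule <- match.arg(lambda_schedule)
  lr_decay <- match.arg(lr_decay)
  if (epochs < 0L) rlang::abort("epochs must be >= 0")
  overlap <- intersect(unique(source$interactions$protein_id),
                       unique(target$interactions$protein_id))
  if (length(overlap)) {
    rlang::abort(paste0("protein id in both domains: ", overlap[1L]))
  }
  if (is.null(model)) model <- init_encoder(config, seed = seed)
  model <- clone_model(model)
  cfg <- model$config
  if (is.null(features)) {
    features <- featurize_dataset(list(
      proteins = dplyr::bind_rows(source$proteins, target$proteins),
      drugs = dplyr::distinct(dplyr::bind_rows(source$drugs, target$drugs))
    ), l_max = cfg$l_max)
  }
  if (epochs == 0L) {
    model$stage <- "inductive"
    return(model)
  }

  params <- model$params
  opt <- adam_state(params)
  src <- source$interactions
  tgt <- target$interactions
  log_rows <- vector("list", epochs)

  withr::with_seed(seed + 1L, {
    n_val <- floor(val_fraction * nrow(src))
    val_idx <- if (n_val > 0L) sample(nrow(src), n_val) else integer(0)
    val <- src[val_idx, , drop = FALSE]
    trn <- if (n_val > 0L) src[-val_idx, , drop = FALSE] else src
    steps_per_epoch <- max(1L, ceiling(nrow(trn) / batch_size))
    total_steps <- epochs * steps_per_epoch
    step <- 0L
    has_aff <- any(!is.na(trn$affinity))
    # with lambda fixed at 0 the adversarial branch contributes no encoder
    # gradient; skip its forward pass (the target batch is still drawn so
    # the random stream is identical either way)
    adv <- !(lambda == 0 && lambda_schedule == "constant")

    for (ep in seq_len(epochs)) {
      idx <- sample(nrow(trn))
      ep_ls <- ep_ld <- 0
      for (b in seq_len(steps_per_epoch)) {
        rows <- idx[((b - 1L) * batch_size + 1L):min(b * batch_size, nrow(trn))]
        bs <- trn[rows, , drop = FALSE]
        bt <- tgt[sample(nrow(tgt), min(batch_size, nrow(tgt))), , drop = FALSE]
        lam <- lambda_at(lambda_schedule, lambda, step / max(1L, total_steps - 1L))

        O_s <- encode_batch_features(params, cfg, features, bs)
        O_t <- if (adv) encode_batch_features(params, cfg, features, bt)
        if (cfg$dropout > 0) {
          keep <- function(n, f) {
            matrix(stats::rbinom(n * f, 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
                   n, f)
          }
          O_s <- tg_mul(O_s, tg_const(keep(nrow(bs), cfg$fusion_dim)))
          O_t <- tg_mul(O_t, tg_const(keep(nrow(bt), cfg$fusion_dim)))
        }
        z_s <- head_logits_core(params, O_s)
        L_s <- tg_mean(tg_bce_logits(z_s, matrix(bs$label, ncol = 1L)))

        if (adv) {
          z_t <- head_logits_core(params, O_t)
          p1 <- 1 / (1 + exp(-rbind(tg_v(z_s), tg_v(z_t)))) # detached
          probs <- cbind(1 - p1, p1)
          R <- tg_grl(tg_vstack(list(O_s, O_t)), lam)
          L_d <- cada_loss_core(params, R, probs,
                                c(rep(0, nrow(bs)), rep(1, nrow(bt))),
                                cfg$conditioning)
          loss <- tg_add(L_s, L_d)
        } else {
          L_d <- tg_const(0)
          loss <- L_s
        }
        if (has_aff) {
          ar <- which(!is.na(bs$affinity))
          if (length(ar)) {
            yr <- affinity_core(params, tg_rows(O_s, ar))
            loss <- tg_add(loss, tg_scale(tg_mean(tg_sq(tg_sub(yr,
              matrix(bs$affinity[ar], ncol = 1L)))), affinity_weight))
          }
        }
        tg_backward(loss)
        lr_t <- if (lr_decay == "cosine") {
          lr * 0.5 * (1 + cos(pi * step / max(1L, total_steps - 1L)))
        } else {
          lr
        }
        opt <- adam_step(params, opt, lr = lr_t, weight_decay = weight_decay)
        tg_zero_grads(params)
        ep_ls <- ep_ls + tg_v(L_s)[1L]
        ep_ld <- ep_ld + tg_v(L_d)[1L]
        step <- step + 1L
      }
      val_auroc <- NA_real_
      if ((ep %% val_every == 0L || ep == epochs) &&
          nrow(val) > 1L && length(unique(val$label)) == 2L) {
        pv <- predict_pairs(model, val, features)
        val_auroc <- compute_metrics(val$label, pv$y_c)$auroc
      }
      log_rows[[ep]] <- tibble::tibble(
        epoch = ep, L_s = ep_ls / steps_per_epoch, L_d = ep_ld / steps_per_epoch,
        lambda = lambda_at(lambda_schedule, lambda,
                           (step - 1L) / max(1L, total_steps - 1L)),
        val_auroc = val_auroc
      )
      if (verbose) {
        message(sprintf("epoch %d: L_s=%.4f L_d=%.4f val_auroc=%s", ep,
                        ep_ls / steps_per_epoch, ep_ld / steps_per_epoch,
                        format(val_auroc, digits = 3)))
      }
    }
  })
  model$stage <- "inductive"
  model$log <- dplyr::bind_rows(log_rows)
  model$seed <- as.integer(seed)
  model
}

#' Zero-shot evaluation on labeled pairs
#'
#' @param model A trained `dti_model`.
#' @param interactions Labeled interaction tibble.
#' @param features A [featurize_dataset()] result covering the ids.
#' @return A one-row metric tibble (`auroc`, `auprc`, `acc`, `n`).
#' @export
evaluate_zeroshot <- function(model, interactions, features) {
  pv <- predict_pairs(model, interactions, features)
  compute_metrics(interactions$label, pv$y_c)
}
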