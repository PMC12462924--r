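# Stage two: cluster-based 2-way k-shot episodes, affine-attention dynamic
# prototypes, cosine classification and focal loss.

#' Focal loss parameters
#'
#' @param alpha Positive-class weight (> 0).
#' @param gamma Modulation exponent (>= 0); `gamma = 0` recovers plain
#'   cross-entropy.
#' @return A `focal_params` list.
#' @export
focal_params <- function(alpha = 1, gamma = 2) {
  stopifnot(alpha > 0, gamma >= 0)
  structure(list(alpha = alpha, gamma = gamma), class = "focal_params")
}

#' Build 2-way k-shot episodes from protein clusters
#'
#' Each episode draws its support and query pairs from a single protein
#' cluster: k positive and k negative support interactions plus `k_q` query
#' interactions. In `"unseen_protein"` mode the cluster's proteins are first
#' split so that no protein id is shared between support and query sets.
#' Clusters that cannot satisfy the requirements are skipped with a warning;
#' if none qualifies, an error is raised.
#'
#' @param interactions Interaction tibble.
#' @param assignment Cluster assignment from [cluster_proteins()].
#' @param k Shots per class.
#' @param k_q Query pairs per episode.
#' @param n_tasks Number of episodes to draw (cycled over qualifying
#'   clusters).
#' @param mode `"unseen_protein"` (default) or `"same_protein"`.
#' @param seed Integer seed; episodes are deterministic given the inputs.
#' @return A list of episodes, each a list with `support`, `query`
#'   (interaction tibbles), `cluster_id` and `mode`.
#' @export
build_episodes <- function(interactions, assignment, k = 5L, k_q = 10L,
                           n_tasks = 20L, mode = c("unseen_protein", "same_protein"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L, k_q >= 1L, n_tasks >= 1L)
  inter <- dplyr::mutate(interactions,
    cluster_id = assignment$cluster_id[match(.data$protein_id,
                                             assignment$protein_id)])
  if (any(is.na(inter$cluster_id))) rlang::abort("interaction protein missing from assignment")
  cluster_ids <- sort(unique(inter$cluster_id))

  withr::with_seed(seed, {
    make_one <- function(cid) {
      rows <- inter[inter$cluster_id == cid, , drop = FALSE]
      prots <- unique(rows$protein_id)
      for (attempt in seq_len(20L)) {
        if (mode == "unseen_protein") {
          if (length(prots) < 2L) return(NULL)
          ns <- sample(seq_len(length(prots) - 1L), 1L)
          sup_prots <- sample(prots, ns)
          sup_pool <- rows[rows$protein_id %in% sup_prots, , drop = FALSE]
          qry_pool <- rows[!rows$protein_id %in% sup_prots, , drop = FALSE]
        } else {
          sup_pool <- qry_pool <- rows
        }
        pos <- which(sup_pool$label == 1L)
        neg <- which(sup_pool$label == 0L)
        if (length(pos) < k || length(neg) < k || nrow(qry_pool) < k_q) next
        sup <- sup_pool[c(sample(pos, k), sample(neg, k)), , drop = FALSE]
        if (mode == "same_protein") {
          # queries must not reuse support rows
          key <- paste(qry_pool$drug_id, qry_pool$protein_id)
          skey <- paste(sup$drug_id, sup$protein_id)
          qry_pool <- qry_pool[!key %in% skey, , drop = FALSE]
          if (nrow(qry_pool) < k_q) next
        }
        # draw queries, preferring both classes when available
        qpos <- which(qry_pool$label == 1L)
        qneg <- which(qry_pool$label == 0L)
        qidx <- if (length(qpos) && length(qneg) && k_q >= 2L) {
          npos <- max(1L, min(length(qpos), round(k_q / 2)))
          nneg <- min(length(qneg), k_q - npos)
          npos <- k_q - nneg
          if (npos > length(qpos)) next
          c(sample(qpos, npos), sample(qneg, nneg))
        } else {
          sample(nrow(qry_pool), k_q)
        }
        qry <- qry_pool[qidx, , drop = FALSE]
        return(list(support = dplyr::select(sup, -"cluster_id"),
                    query = dplyr::select(qry, -"cluster_id"),
                    cluster_id = cid, mode = mode))
      }
      NULL
    }

    episodes <- list()
    skipped <- integer(0)
    live <- cluster_ids
    ci <- 0L
    tries <- 0L
    while (length(episodes) < n_tasks && length(live) &&
           tries < 10L * n_tasks + length(cluster_ids)) {
      ci <- ci %% length(live) + 1L
      ep <- make_one(live[ci])
      tries <- tries + 1L
      if (is.null(ep)) {
        skipped <- c(skipped, live[ci])
        live <- live[-ci]
        ci <- ci - 1L
      } else {
        episodes[[length(episodes) + 1L]] <- ep
      }
    }
    if (length(skipped)) {
      rlang::warn(paste0("skipped clusters without feasible episodes: ",
                         paste(unique(skipped), collapse = ", ")))
    }
    if (!length(episodes)) rlang::abort("no cluster supports the requested episode shape")
    episodes
  })
}

#' Expand-and-concatenate support and query features
#'
#' Replicates the support block across the query axis and places each query
#' vector at index 1 of the third axis:
#' `O_c[n, q, 1, ] = O_q[n, q, ]` and `O_c[n, q, 1 + i, ] = O_s[n, i, ]`.
#'
#' @param O_s Numeric array (N x 2k x d).
#' @param O_q Numeric array (N x k_q x d).
#' @return Numeric array (N x k_q x (2k + 1) x d).
#' @export
expand_concat <- function(O_s, O_q) {
  ds <- dim(O_s); dq <- dim(O_q)
  stopifnot(length(ds) == 3L, length(dq) == 3L, ds[1L] == dq[1L],
            ds[3L] == dq[3L])
  N <- ds[1L]; twok <- ds[2L]; d <- ds[3L]; kq <- dq[2L]
  O_c <- array(0, c(N, kq, twok + 1L, d))
  for (q in seq_len(kq)) {
    O_c[, q, 1L, ] <- O_q[, q, ]
    O_c[, q, 2L:(twok + 1L), ] <- O_s
  }
  O_c
}

silu <- function(x) x / (1 + exp(-x))

#' Affine attention over support features
#'
#' Shared projection `Z = silu(O_c W_I)` feeds two affine branches
#' `Q = Z * gamma1 + beta1` and `K = Z * gamma2 + beta2`; raw attention is
#' `relu(Q K^T)^2`, and the returned scores are the query row (index 1 of the
#' third axis) against each support row.
#'
#' @param O_c Array (N x k_q x (2k + 1) x d) from [expand_concat()].
#' @param params List with `W_I` (d x d) and vectors `gamma1`, `beta1`,
#'   `gamma2`, `beta2` (length d).
#' @return Nonnegative array A (N x k_q x 2k).
#' @export
affine_attention <- function(O_c, params) {
  dm <- dim(O_c)
  N <- dm[1L]; kq <- dm[2L]; rows <- dm[3L]; d <- dm[4L]
  A <- array(0, c(N, kq, rows - 1L))
  g1 <- matrix(params$gamma1, rows, d, byrow = TRUE)
  b1 <- matrix(params$beta1, rows, d, byrow = TRUE)
  g2 <- matrix(params$gamma2, rows, d, byrow = TRUE)
  b2 <- matrix(params$beta2, rows, d, byrow = TRUE)
  for (n in seq_len(N)) {
    for (q in seq_len(kq)) {
      X <- matrix(O_c[n, q, , ], rows, d)
      Z <- silu(X %*% params$W_I)
      Q <- Z * g1 + b1
      K <- Z * g2 + b2
      raw <- pmax(Q %*% t(K), 0)^2
      A[n, q, ] <- raw[1L, -1L]
    }
  }
  A
}

#' Attention-weighted dynamic prototypes
#'
#' For each class c, the prototype is the softmax-weighted (over that class's
#' support indices only) combination of support features:
#' `P[n,q,c] = sum_i softmax_c(A[n,q,.])[i] * O_s_expanded[n,q,i,]`.
#' By default the `1/|O_c|` prefactor is dropped, since the downstream cosine
#' classifier is scale-invariant; `prefactor = TRUE` restores it.
#'
#' @param O_s_expanded Array (N x k_q x 2k x d): supports replicated across
#'   queries (rows 2..2k+1 of [expand_concat()] output).
#' @param support_labels Vector (length 2k) or matrix (N x 2k) of 0/1 labels.
#' @param A Attention scores (N x k_q x 2k), nonnegative.
#' @param prefactor Multiply prototypes by `1 / (2k + 1)`.
#' @return Array P (N x k_q x 2 x d); index 1 of the class axis is class 0.
#' @export
dynamic_prototypes <- function(O_s_expanded, support_labels, A,
                               prefactor = FALSE) {
  dm <- dim(O_s_expanded)
  N <- dm[1L]; kq <- dm[2L]; twok <- dm[3L]; d <- dm[4L]
  if (is.null(dim(support_labels))) {
    support_labels <- matrix(support_labels, N, twok, byrow = TRUE)
  }
  P <- array(0, c(N, kq, 2L, d))
  for (n in seq_len(N)) {
    for (c in 0:1) {
      idx <- which(support_labels[n, ] == c)
      if (!length(idx)) rlang::abort("a support class is empty")
      for (q in seq_len(kq)) {
        a <- A[n, q, idx]
        w <- exp(a - max(a))
        w <- w / sum(w)
        S <- matrix(O_s_expanded[n, q, idx, ], length(idx), d)
        P[n, q, c + 1L, ] <- colSums(S * w)
      }
    }
  }
  if (prefactor) P <- P / (twok + 1L)
  P
}

cosine_eps <- 1e-8

#' Cosine classification and focal loss
#'
#' Scores each query against the two prototypes by cosine similarity,
#' softmaxes over the class axis and evaluates the focal loss
#' `L_f = -mean( alpha_eff * (1 - p_true)^gamma * log(p_true) )` where
#' `alpha_eff` is `alpha` for positive-label queries and 1 otherwise.
#'
#' @param P Prototype array (N x k_q x 2 x d).
#' @param O_q Query array (N x k_q x d).
#' @param Y_q Query labels, vector (length k_q) or matrix (N x k_q).
#' @param focal A [focal_params()].
#' @return List with `scores` (N x k_q x 2), `probs` (N x k_q, probability of
#'   the true class), `p_positive` (N x k_q, probability of class 1) and the
#'   scalar `loss`.
#' @export
classify_and_loss <- function(P, O_q, Y_q, focal = focal_params()) {
  dm <- dim(P)
  N <- dm[1L]; kq <- dm[2L]; d <- dm[4L]
  if (is.null(dim(Y_q))) Y_q <- matrix(Y_q, N, kq, byrow = TRUE)
  scores <- array(0, c(N, kq, 2L))
  probs <- matrix(0, N, kq)
  p_pos <- matrix(0, N, kq)
  terms <- numeric(0)
  for (n in seq_len(N)) {
    for (q in seq_len(kq)) {
      v <- O_q[n, q, ]
      nv <- sqrt(sum(v^2)) + cosine_eps
      s <- vapply(1:2, function(ci) {
        p <- P[n, q, ci, ]
        sum(p * v) / ((sqrt(sum(p^2)) + cosine_eps) * nv)
      }, 0)
      scores[n, q, ] <- s
      e <- exp(s - max(s))
      sm <- e / sum(e)
      p_pos[n, q] <- sm[2L]
      pt <- sm[Y_q[n, q] + 1L]
      probs[n, q] <- pt
      a_eff <- if (Y_q[n, q] == 1L) focal$alpha else 1
      terms <- c(terms, -a_eff * (1 - pt)^focal$gamma * log(pt))
    }
  }
  list(scores = scores, probs = probs, p_positive = p_pos,
       loss = mean(terms))
}

# ---- tensor path for training ---------------------------------------------

# O_rows: list over support rows of (1 x d) tensors; O_qrow: (1 x d) tensor.
# Returns list(loss term tensor (1x1), p_true numeric, p_pos numeric).
meta_query_core <- function(params, O_qrow, O_srows, sup_labels, y,
                            focal, use_attention = TRUE, prefactor = FALSE) {
  twok <- length(O_srows)
  protos <- vector("list", 2L)
  if (use_attention) {
    rows <- tg_vstack(c(list(O_qrow), O_srows))
    Z <- tg_silu(tg_matmul(rows, params$WI))
    Q1 <- tg_add(tg_mul(tg_rows(Z, 1L), params$gamma1), params$beta1)
    K <- tg_add(tg_mul(Z, params$gamma2), params$beta2)
    a <- tg_sq(tg_relu(tg_matmul(Q1, tg_t(K)))) # 1 x (2k+1)
    A <- tg_cols(a, 2L:(twok + 1L))
  }
  Sup <- tg_vstack(O_srows)
  for (c in 0:1) {
    idx <- which(sup_labels == c)
    if (use_attention) {
      w <- tg_softmax_rows(tg_cols(A, idx))
    } else {
      w <- tg_const(matrix(1 / length(idx), 1L, length(idx)))
    }
    proto <- tg_matmul(w, tg_rows(Sup, idx))
    if (prefactor) proto <- tg_scale(proto, 1 / (twok + 1L))
    protos[[c + 1L]] <- proto
  }
  # the tiny constant inside the square root keeps the norm gradient finite
  # for an exactly-zero vector (ReLU-dead fused features)
  safe_norm <- function(x) {
    tg_add(tg_sqrt(tg_add(tg_sum(tg_sq(x)), tg_const(1e-16))),
           tg_const(cosine_eps))
  }
  qn <- safe_norm(O_qrow)
  s <- lapply(protos, function(p) {
    tg_div(tg_sum(tg_mul(p, O_qrow)), tg_mul(safe_norm(p), qn))
  })
  sv <- tg_t(tg_vstack(s)) # 1 x 2
  sm <- tg_softmax_rows(sv)
  p_true <- tg_cols(sm, y + 1L)
  a_eff <- if (y == 1L) focal$alpha else 1
  term <- tg_scale(tg_mul(tg_pow(tg_sub(tg_const(1), p_true), focal$gamma),
                          tg_log(p_true)), -a_eff)
  list(term = term, p_true = tg_v(p_true)[1L], p_pos = tg_v(sm)[1L, 2L])
}

# Encode every pair of an episode once; returns list(sup_rows, qry_rows).
episode_features_core <- function(params, cfg, features, episode) {
  pairs <- dplyr::bind_rows(episode$support, episode$query)
  up <- unique(pairs$protein_id)
  ud <- unique(pairs$drug_id)
  Pf <- lapply(up, function(id) enc_protein_core(params, cfg, features$tokens[[id]]))
  names(Pf) <- up
  Df <- lapply(ud, function(id) {
    enc_drug_core(params, cfg, features$graphs[[id]], features$adj[[id]])
  })
  names(Df) <- ud
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    fuse_pair_core(params, cfg, Pf[[pairs$protein_id[j]]],
                   Df[[pairs$drug_id[j]]])$O
  })
  ns <- nrow(episode$support)
  list(sup = rows[seq_len(ns)], qry = rows[ns + seq_len(nrow(episode$query))])
}

episode_loss_core <- function(params, cfg, features, episode, focal,
                              use_attention = TRUE, prefactor = FALSE) {
  ef <- episode_features_core(params, cfg, features, episode)
  terms <- vector("list", length(ef$qry))
  p_pos <- numeric(length(ef$qry))
  for (q in seq_along(ef$qry)) {
    mq <- meta_query_core(params, ef$qry[[q]], ef$sup,
                          episode$support$label, episode$query$label[q],
                          focal, use_attention, prefactor)
    terms[[q]] <- mq$term
    p_pos[q] <- mq$p_pos
  }
  loss <- tg_scale(Reduce(tg_add, terms), 1 / length(terms))
  list(loss = loss, p_pos = p_pos)
}

#' Stage-two episodic meta-training
#'
#' Metric-based episodic training (no inner-loop adaptation): the encoder is
#' initialized from the stage-one checkpoint, and for every episode the query
#' features are classified against attention-weighted class prototypes built
#' from the support features; the focal loss over meta-batches of `meta_batch`
#' episodes drives plain gradient descent on the encoder and attention
#' parameters.
#'
#' @param episodes Episode list from [build_episodes()].
#' @param model The stage-one `dti_model` checkpoint.
#' @param features A [featurize_dataset()] result covering all episode ids.
#' @param focal A [focal_params()].
#' @param meta_batch Episodes per gradient step.
#' @param epochs Passes over the episode list (0 = return the checkpoint
#'   unchanged).
#' @param lr Adam learning rate.
#' @param seed Integer seed for episode shuffling.
#' @param use_attention If `FALSE`, prototypes are unweighted class means
#'   (the mean-prototype ablation).
#' @param train_encoder If `FALSE`, only the affine-attention parameters are
#'   updated and the encoder stays at the stage-one checkpoint.
#' @param prefactor Restore the `1/|O_c|` prototype prefactor.
#' @param verbose Print per-epoch loss.
#' @return A trained `dti_model` (stage `"meta"`).
#' @export
train_meta <- function(episodes, model, features, focal = focal_params(),
                       meta_batch = 4L, epochs = 40L, lr = 1e-3, seed = 1L,
                       use_attention = TRUE, prefactor = FALSE,
                       train_encoder = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "dti_model"))
  if (epochs < 0L) rlang::abort("epochs must be >= 0")
  model <- clone_model(model)
  if (epochs == 0L) return(model)
  cfg <- model$config
  params <- model$params
  upd <- if (train_encoder) {
    params[setdiff(names(params), model_param_names(model, "disc"))]
  } else {
    params[model_param_names(model, "meta")]
  }
  opt <- adam_state(upd)
  log_rows <- vector("list", epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(episodes))
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, length(ord), by = meta_batch)) {
        bidx <- ord[b0:min(b0 + meta_batch - 1L, length(ord))]
        losses <- lapply(episodes[bidx], function(epi) {
          episode_loss_core(params, cfg, features, epi, focal,
                            use_attention, prefactor)$loss
        })
        loss <- tg_scale(Reduce(tg_add, losses), 1 / length(losses))
        tg_backward(loss)
        opt <- adam_step(upd, opt, lr = lr)
        tg_zero_grads(params)
        ep_loss <- ep_loss + tg_v(loss)[1L]
        nb <- nb + 1L
      }
      log_rows[[ep]] <- tibble::tibble(epoch = ep, L_f = ep_loss / nb)
      if (verbose) message(sprintf("meta epoch %d: L_f=%.4f", ep, ep_loss / nb))
    }
  })
  model$stage <- "meta"
  model$log <- dplyr::bind_rows(log_rows)
  model
}

#' Few-shot predictions for one episode
#'
#' @param model A `dti_model`.
#' @param episode One episode from [build_episodes()].
#' @param features A [featurize_dataset()] result.
#' @param use_attention,prefactor See [train_meta()].
#' @return The episode's query tibble with a `p_positive` column.
#' @export
predict_episode <- function(model, episode, features, use_attention = TRUE,
                            prefactor = FALSE) {
  out <- tg_no_grad(
    episode_loss_core(model$params, model$config, features, episode,
                      focal_params(), use_attention, prefactor)
  )
  dplyr::mutate(episode$query, p_positive = out$p_pos)
}

#' Few-shot evaluation over episodes
#'
#' Pools query predictions within each episode, computes AUROC/AUPRC/ACC per
#' episode and aggregates as mean and standard deviation. Episodes whose
#' queries contain a single class are excluded from AUROC/AUPRC with a
#' warning.
#'
#' @inheritParams predict_episode
#' @param episodes Episode list.
#' @return A `fewshot_eval` object: list with `per_episode` tibble and
#'   `summary` tibble.
#' @export
evaluate_fewshot <- function(model, episodes, features, use_attention = TRUE,
                             prefactor = FALSE) {
  rows <- purrr::map_dfr(seq_along(episodes), function(i) {
    pe <- predict_episode(model, episodes[[i]], features, use_attention,
                          prefactor)
    m <- suppressWarnings(compute_metrics(pe$label, pe$p_positive))
    tibble::tibble(episode = i, cluster_id = episodes[[i]]$cluster_id,
                   n_query = nrow(pe), auroc = m$auroc, auprc = m$auprc,
                   acc = m$acc)
  })
  if (any(is.na(rows$auroc))) {
    rlang::warn(paste0(sum(is.na(rows$auroc)),
                       " single-class episode(s) excluded from AUROC/AUPRC"))
  }
  summ <- tibble::tibble(
    metric = c("auroc", "auprc", "acc"),
    mean = c(mean(rows$auroc, na.rm = TRUE), mean(rows$auprc, na.rm = TRUE),
             mean(rows$acc)),
    sd = c(stats::sd(rows$auroc, na.rm = TRUE),
           stats::sd(rows$auprc, na.rm = TRUE), stats::sd(rows$acc))
  )
  structure(list(per_episode = rows, summary = summ), class = "fewshot_eval")
}

#' @export
print.fewshot_eval <- function(x, ...) {
  cat("<fewshot_eval> ", nrow(x$per_episode), " episodes\n", sep = "")
  print(x$summary)
  invisible(x)
}
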