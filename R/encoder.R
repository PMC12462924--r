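# The multi-level interaction encoder: a convolutional protein branch and a
# graph-convolutional molecule branch, fused level-by-level with low-rank
# bilinear attention and consolidated across levels by a gated selection unit.

#' Encoder configuration
#'
#' @param n_levels Number of encoder stages (default 3).
#' @param embed_dim Residue embedding dimension.
#' @param protein_channels Integer vector, convolution channels per level.
#' @param protein_kernel_sizes Integer vector, convolution widths per level.
#' @param drug_hidden_dims Integer vector, graph-convolution widths per level.
#' @param fusion_dim Dimension of the fused interaction vector O.
#' @param attention_rank Rank of the bilinear attention map.
#' @param dropout Dropout probability on the fused vector during training.
#' @param l_max Maximum protein length kept (N-terminal prefix).
#' @param use_stem If `FALSE`, the first protein stage passes the embedding
#'   through unchanged (ablation switch; requires
#'   `protein_channels[1] == embed_dim`).
#' @param use_gates If `FALSE`, the gated selection unit is replaced by an
#'   unweighted sum across levels (ablation switch).
#' @param fs_on_gated_sum If `TRUE` (default) the selection layer f_s acts on
#'   the gate-weighted sum; if `FALSE`, on the plain sum.
#' @param head_hidden Hidden width of the classification head (default
#'   `max(16, fusion_dim / 2)`).
#' @param disc_hidden Hidden width of the domain discriminators.
#' @param conditioning How discriminator inputs are conditioned on the class
#'   probability: `"scalar"` scales the feature vector by the class
#'   probability; `"concat"` appends the two-class probability vector.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_levels = 3L,
                           embed_dim = 128L,
                           protein_channels = rep(128L, n_levels),
                           protein_kernel_sizes = c(3L, 6L, 9L),
                           drug_hidden_dims = rep(128L, n_levels),
                           fusion_dim = 256L,
                           attention_rank = 8L,
                           dropout = 0,
                           l_max = 1200L,
                           use_stem = TRUE,
                           use_gates = TRUE,
                           fs_on_gated_sum = TRUE,
                           head_hidden = NULL,
                           disc_hidden = 32L,
                           conditioning = c("scalar", "concat")) {
  conditioning <- match.arg(conditioning)
  stopifnot(
    n_levels >= 1L,
    length(protein_channels) == n_levels,
    length(protein_kernel_sizes) == n_levels,
    length(drug_hidden_dims) == n_levels,
    all(c(embed_dim, protein_channels, protein_kernel_sizes,
          drug_hidden_dims, fusion_dim, attention_rank) > 0),
    dropout >= 0, dropout < 1
  )
  if (!use_stem && protein_channels[1L] != embed_dim) {
    rlang::abort("use_stem = FALSE requires protein_channels[1] == embed_dim")
  }
  structure(list(
    n_levels = as.integer(n_levels),
    embed_dim = as.integer(embed_dim),
    protein_channels = as.integer(protein_channels),
    protein_kernel_sizes = as.integer(protein_kernel_sizes),
    drug_hidden_dims = as.integer(drug_hidden_dims),
    fusion_dim = as.integer(fusion_dim),
    attention_rank = as.integer(attention_rank),
    dropout = dropout,
    l_max = as.integer(l_max),
    use_stem = use_stem,
    use_gates = use_gates,
    fs_on_gated_sum = fs_on_gated_sum,
    head_hidden = as.integer(head_hidden %||% max(16L, fusion_dim %/% 2L)),
    disc_hidden = as.integer(disc_hidden),
    conditioning = conditioning
  ), class = "encoder_config")
}

#' Initialize an encoder model
#'
#' Creates all trainable parameters (Glorot-uniform weights, zero biases) for
#' the encoder, the classification and affinity heads, the domain
#' discriminators and the meta-stage affine-attention unit.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for the initialization.
#' @return A `dti_model` object.
#' @export
init_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  cfg <- config
  params <- withr::with_seed(seed, {
    p <- list(embed = glorot(26L, cfg$embed_dim))
    cin <- cfg$embed_dim
    for (i in seq_len(cfg$n_levels)) {
      k <- cfg$protein_kernel_sizes[i]
      cout <- cfg$protein_channels[i]
      if (i > 1L || cfg$use_stem) {
        p[[paste0("Wp", i)]] <- glorot(k * cin, cout)
        p[[paste0("bp", i)]] <- zeros(1L, cout)
      }
      cin <- cout
    }
    din <- atom_feature_dim()
    for (i in seq_len(cfg$n_levels)) {
      dout <- cfg$drug_hidden_dims[i]
      p[[paste0("Wd", i)]] <- glorot(din, dout)
      p[[paste0("bd", i)]] <- zeros(1L, dout)
      din <- dout
    }
    for (i in seq_len(cfg$n_levels)) {
      ci <- cfg$protein_channels[i]
      hi <- cfg$drug_hidden_dims[i]
      p[[paste0("U", i)]] <- glorot(ci, cfg$attention_rank)
      p[[paste0("V", i)]] <- glorot(hi, cfg$attention_rank)
      p[[paste0("Uf", i)]] <- glorot(ci, cfg$fusion_dim)
      p[[paste0("Vf", i)]] <- glorot(hi, cfg$fusion_dim)
    }
    p$Wg <- glorot(cfg$fusion_dim, cfg$n_levels)
    p$bg <- zeros(1L, cfg$n_levels)
    p$Ws <- glorot(cfg$fusion_dim, cfg$fusion_dim)
    p$bs <- zeros(1L, cfg$fusion_dim)
    p$Wh1 <- glorot(cfg$fusion_dim, cfg$head_hidden)
    p$bh1 <- zeros(1L, cfg$head_hidden)
    p$wh2 <- glorot(cfg$head_hidden, 1L)
    p$bh2 <- zeros(1L, 1L)
    p$wr <- glorot(cfg$fusion_dim, 1L)
    p$br <- zeros(1L, 1L)
    # domain discriminators, one per interaction class
    dfin <- if (cfg$conditioning == "concat") cfg$fusion_dim + 2L else cfg$fusion_dim
    for (k in 0:1) {
      p[[paste0("Wdisc", k, "_1")]] <- glorot(dfin, cfg$disc_hidden)
      p[[paste0("bdisc", k, "_1")]] <- zeros(1L, cfg$disc_hidden)
      p[[paste0("wdisc", k, "_2")]] <- glorot(cfg$disc_hidden, 1L)
      p[[paste0("bdisc", k, "_2")]] <- zeros(1L, 1L)
    }
    # meta-stage affine attention
    p$WI <- glorot(cfg$fusion_dim, cfg$fusion_dim)
    p$gamma1 <- matrix(1, 1L, cfg$fusion_dim)
    p$beta1 <- zeros(1L, cfg$fusion_dim)
    p$gamma2 <- matrix(1, 1L, cfg$fusion_dim)
    p$beta2 <- zeros(1L, cfg$fusion_dim)
    p
  })
  structure(list(
    config = cfg,
    params = lapply(params, tg_param),
    stage = "init",
    seed = as.integer(seed),
    log = tibble::tibble()
  ), class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$v), 0))
  cat("<dti_model> stage:", x$stage, "|", x$config$n_levels, "levels |",
      np, "parameters\n")
  invisible(x)
}

model_param_names <- function(model, set = c("encoder", "disc", "meta", "all")) {
  set <- match.arg(set)
  nms <- names(model$params)
  disc <- grepl("^[wWb]disc", nms)
  meta <- nms %in% c("WI", "gamma1", "beta1", "gamma2", "beta2")
  switch(set,
    all = nms,
    disc = nms[disc],
    meta = nms[meta],
    encoder = nms[!disc & !meta]
  )
}

# ---- tensor-level forward cores -------------------------------------------

# tokens: integer vector of unpadded residue tokens (values 1..26)
enc_protein_core <- function(params, cfg, tokens) {
  if (length(tokens) < 1L) rlang::abort("protein with length 0 after masking")
  X <- tg_rows(params$embed, tokens)
  feats <- vector("list", cfg$n_levels)
  for (i in seq_len(cfg$n_levels)) {
    if (i == 1L && !cfg$use_stem) {
      P <- X
    } else {
      U <- tg_unfold(X, cfg$protein_kernel_sizes[i])
      P <- tg_relu(tg_add(tg_matmul(U, params[[paste0("Wp", i)]]),
                          params[[paste0("bp", i)]]))
    }
    feats[[i]] <- P
    if (i < cfg$n_levels) X <- tg_maxpool2(P)
  }
  feats
}

# graph: molecular_graph; adj: precomputed normalized adjacency (constant)
enc_drug_core <- function(params, cfg, graph, adj = NULL) {
  if (graph$n_atoms < 1L) rlang::abort("empty molecular graph")
  if (is.null(adj)) adj <- graph_adjacency_norm(graph)
  H <- tg_const(graph$node_features)
  feats <- vector("list", cfg$n_levels)
  for (i in seq_len(cfg$n_levels)) {
    H <- tg_relu(tg_add(
      tg_matmul(tg_const(adj), tg_matmul(H, params[[paste0("Wd", i)]])),
      params[[paste0("bd", i)]]
    ))
    feats[[i]] <- H
  }
  feats
}

# Low-rank bilinear attention fusion of one level's feature pair.
# P: (positions x c), D: (atoms x h); U/V project into the shared rank space,
# Uf/Vf into the fused feature space. Returns the pooled interaction vector
# (1 x fusion_dim) and the nonnegative attention map (positions x atoms).
bilinear_core <- function(P, D, U, V, Uf, Vf) {
  vec <- tg_bilinear_pool(P, D, U, V, Uf, Vf)
  list(vector = vec, attention_map = vec$aux)
}

# Gated selection across levels. I_list: list of (1 x fusion_dim) tensors.
gated_core <- function(I_list, Wg, bg, Ws, bs, use_gates = TRUE,
                       fs_on_gated_sum = TRUE) {
  Istack <- tg_vstack(I_list)
  if (use_gates && fs_on_gated_sum) {
    S <- tg_gated_sum(Istack, Wg, bg, TRUE)
    gates <- S$aux
  } else {
    S <- tg_gated_sum(Istack, Wg, bg, FALSE) # plain sum into f_s
    gates <- if (use_gates) {
      z <- rowSums(tg_v(Istack) * t(tg_v(Wg))) + as.numeric(tg_v(bg))
      1 / (1 + exp(-z))
    } else {
      rep(1, length(I_list))
    }
  }
  O <- tg_relu(tg_add(tg_matmul(S, Ws), bs))
  # RMS normalization keeps the fused vector on a stable scale across
  # proteins/molecules of different sizes and through training
  nrm <- tg_sqrt(tg_add(tg_mean(tg_sq(O)), tg_const(1e-6)))
  list(O = tg_div(O, nrm), gates = gates)
}

head_core <- function(params, O) {
  H <- tg_relu(tg_add(tg_matmul(O, params$Wh1), params$bh1))
  tg_sigmoid(tg_add(tg_matmul(H, params$wh2), params$bh2))
}

affinity_core <- function(params, O) {
  tg_add(tg_matmul(O, params$wr), params$br)
}

# Full single-pair forward. Returns tensors plus the numeric attention maps.
pair_forward_core <- function(params, cfg, tokens, graph, adj = NULL) {
  Pfeats <- enc_protein_core(params, cfg, tokens)
  Dfeats <- enc_drug_core(params, cfg, graph, adj)
  fuse_pair_core(params, cfg, Pfeats, Dfeats)
}

fuse_pair_core <- function(params, cfg, Pfeats, Dfeats) {
  I_list <- vector("list", cfg$n_levels)
  maps <- vector("list", cfg$n_levels)
  for (i in seq_len(cfg$n_levels)) {
    bf <- bilinear_core(Pfeats[[i]], Dfeats[[i]],
                        params[[paste0("U", i)]], params[[paste0("V", i)]],
                        params[[paste0("Uf", i)]], params[[paste0("Vf", i)]])
    I_list[[i]] <- bf$vector
    maps[[i]] <- bf$attention_map
  }
  gf <- gated_core(I_list, params$Wg, params$bg, params$Ws, params$bs,
                   cfg$use_gates, cfg$fs_on_gated_sum)
  list(O = gf$O, gates = gf$gates, maps = maps,
       P = Pfeats, D = Dfeats, I = I_list)
}

# ---- public numeric wrappers ----------------------------------------------

as_tokens <- function(model, protein) {
  if (is.character(protein)) {
    active_tokens(tokenize_protein(protein, l_max = model$config$l_max, pad = FALSE))
  } else if (is.list(protein) && !is.null(protein$tokens)) {
    active_tokens(protein)
  } else {
    tk <- as.integer(protein)
    tk[tk != 0L] # drop padding
  }
}

as_graph <- function(drug) {
  if (inherits(drug, "molecular_graph")) drug else smiles_to_graph(drug)
}

#' Per-level protein features
#'
#' Runs the protein branch of the encoder: residue embedding, then one block
#' of (1-D convolution, ReLU) per level with stride-2 max-pooling between
#' levels, so position counts shrink by about half from level to level.
#'
#' @param model A `dti_model`.
#' @param protein A sequence string, a [tokenize_protein()] result, or an
#'   integer token vector (padding zeros are dropped).
#' @return List of `n_levels` numeric matrices (positions_i x channels_i).
#' @export
encode_protein <- function(model, protein) {
  tokens <- as_tokens(model, protein)
  tg_no_grad(lapply(enc_protein_core(model$params, model$config, tokens), tg_v))
}

#' Per-level drug features
#'
#' Runs the molecule branch: `n_levels` graph-convolution blocks with
#' symmetric-normalized adjacency (self-connections added), ReLU activations,
#' and no pooling (all atoms are kept at every level).
#'
#' @param model A `dti_model`.
#' @param drug A SMILES string or a `molecular_graph`.
#' @return List of `n_levels` numeric matrices (atoms x dim_i).
#' @export
encode_drug <- function(model, drug) {
  graph <- as_graph(drug)
  tg_no_grad(lapply(enc_drug_core(model$params, model$config, graph), tg_v))
}

#' Low-rank bilinear attention fusion
#'
#' Fuses one level's protein and drug feature matrices. The attention map is
#' `relu(P U) %*% t(relu(D V))` (nonnegative, positions x atoms); the fused
#' vector is the attention-weighted bilinear pooling over all
#' (residue, atom) pairs, scaled by `1 / sqrt(n_pairs)` so its magnitude is
#' stable across protein lengths and molecule sizes:
#' `vector_k = sum_{r,a} M[r,a] * (P U_f)[r,k] * (D V_f)[a,k] / sqrt(n_pairs)`.
#'
#' @param P Numeric matrix (positions x c).
#' @param D Numeric matrix (atoms x h).
#' @param params List with matrices `U` (c x rank), `V` (h x rank),
#'   `Uf` (c x fusion_dim), `Vf` (h x fusion_dim).
#' @return List with `vector` (length fusion_dim) and `attention_map`.
#' @export
bilinear_fuse <- function(P, D, params) {
  stopifnot(nrow(P) >= 1L, nrow(D) >= 1L, ncol(params$U) >= 1L)
  out <- tg_no_grad(bilinear_core(
    tg_const(P), tg_const(D),
    tg_const(params$U), tg_const(params$V),
    tg_const(params$Uf), tg_const(params$Vf)
  ))
  list(vector = as.numeric(tg_v(out$vector)),
       attention_map = tg_v(out$attention_map))
}

#' Gated fusion across levels
#'
#' Each level's interaction vector receives a logistic gate
#' `g_i = sigmoid(I_i . w_g_i + b_g_i)`; the selection layer f_s (one linear
#' layer + ReLU followed by an RMS normalization) acts on the gate-weighted
#' sum.
#'
#' @param interactions List of numeric vectors (one per level, equal length).
#' @param params List with `Wg` (fusion_dim x n_levels), `bg` (n_levels),
#'   `Ws` (fusion_dim x fusion_dim), `bs` (fusion_dim).
#' @param use_gates,fs_on_gated_sum See [encoder_config()].
#' @return List with `vector` (the fused O) and `gates`.
#' @export
gated_fuse <- function(interactions, params, use_gates = TRUE,
                       fs_on_gated_sum = TRUE) {
  d <- unique(vapply(interactions, length, 1L))
  if (length(d) != 1L) rlang::abort("mismatched fusion_dim across levels")
  out <- tg_no_grad(gated_core(
    lapply(interactions, function(v) tg_const(matrix(v, 1L))),
    tg_const(params$Wg), tg_const(matrix(params$bg, 1L)),
    tg_const(params$Ws), tg_const(matrix(params$bs, 1L)),
    use_gates, fs_on_gated_sum
  ))
  list(vector = as.numeric(tg_v(out$O)), gates = out$gates)
}

#' Forward pass for one drug-target pair
#'
#' @param model A `dti_model`.
#' @param protein Sequence, tokenized protein, or token vector.
#' @param drug SMILES string or `molecular_graph`.
#' @return List with `y_c` (interaction probability), `y_r` (affinity,
#'   pK scale), `O` (fused vector), `gates`, and per-level `attention_maps`.
#' @export
forward_pair <- function(model, protein, drug) {
  tokens <- as_tokens(model, protein)
  graph <- as_graph(drug)
  tg_no_grad({
    fw <- pair_forward_core(model$params, model$config, tokens, graph)
    y_c <- tg_v(head_core(model$params, fw$O))[1L]
    y_r <- tg_v(affinity_core(model$params, fw$O))[1L]
    list(y_c = y_c, y_r = y_r, O = as.numeric(tg_v(fw$O)),
         gates = fw$gates, attention_maps = fw$maps)
  })
}

#' Predict interaction probabilities for a table of pairs
#'
#' @param model A `dti_model`.
#' @param pairs Tibble with `drug_id` and `protein_id` columns.
#' @param features A `dti_features` object from [featurize_dataset()].
#' @param affinity If `TRUE`, also return the affinity head output and the
#'   screening score `y_c^2 * y_r`.
#' @return The input tibble with `y_c` (and optionally `y_r`, `score`) added.
#' @export
predict_pairs <- function(model, pairs, features, affinity = FALSE) {
  tg_no_grad({
    up <- unique(pairs$protein_id)
    ud <- unique(pairs$drug_id)
    Pf <- lapply(up, function(id) {
      enc_protein_core(model$params, model$config, features$tokens[[id]])
    })
    names(Pf) <- up
    Df <- lapply(ud, function(id) {
      enc_drug_core(model$params, model$config, features$graphs[[id]],
                    features$adj[[id]])
    })
    names(Df) <- ud
    n <- nrow(pairs)
    y_c <- numeric(n)
    y_r <- numeric(n)
    for (j in seq_len(n)) {
      fw <- fuse_pair_core(model$params, model$config,
                           Pf[[pairs$protein_id[j]]], Df[[pairs$drug_id[j]]])
      y_c[j] <- tg_v(head_core(model$params, fw$O))[1L]
      if (affinity) y_r[j] <- tg_v(affinity_core(model$params, fw$O))[1L]
    }
    out <- dplyr::mutate(tibble::as_tibble(pairs), y_c = y_c)
    if (affinity) {
      out$y_r <- y_r
      out$score <- screening_score(out$y_c, out$y_r)
    }
    out
  })
}

#' Affinity prediction from a fused interaction vector
#'
#' A single linear layer (no activation) on the fused vector O, on the pK
#' scale: `y_r = O . w_r + b_r`.
#'
#' @param O Numeric vector (fusion_dim) or matrix (n x fusion_dim).
#' @param params List with `wr` (fusion_dim) and `br` (scalar).
#' @return Numeric vector of predicted affinities.
#' @export
predict_affinity <- function(O, params) {
  O <- if (is.matrix(O)) O else matrix(O, 1L)
  as.numeric(O %*% matrix(params$wr, ncol = 1L) + params$br)
}

#' Top-attended atoms and residues
#'
#' Ranks atoms (and pooled residue positions) by their summed bilinear
#' attention mass at each level and flags the top fraction, ties broken by the
#' lower index. Residue indices are at the level's own (pooled) resolution:
#' a level-i position covers roughly `2^(i-1)` consecutive residues.
#'
#' @param model A `dti_model`.
#' @param protein,drug As in [forward_pair()].
#' @param top_fraction Fraction of positions to flag (default 0.2, the
#'   "top 20 percent" convention used for interaction maps).
#' @return A tibble `level`, `entity` ("atom"/"residue"), `index`, `score`,
#'   `rank`, `selected`.
#' @export
extract_attention <- function(model, protein, drug, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  fw <- forward_pair(model, protein, drug)
  purrr::map_dfr(seq_along(fw$attention_maps), function(i) {
    M <- fw$attention_maps[[i]]
    dplyr::bind_rows(
      dplyr::mutate(top_attended(rowSums(M), top_fraction),
                    level = i, entity = "residue", .before = 1L),
      dplyr::mutate(top_attended(colSums(M), top_fraction),
                    level = i, entity = "atom", .before = 1L)
    )
  })
}

# rank positions by attention mass; top ceil(fraction * n), ties to the
# lower index
top_attended <- function(score, top_fraction) {
  ord <- order(-score, seq_along(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  m <- ceiling(top_fraction * length(score))
  tibble::tibble(index = seq_along(score), score = score, rank = rank,
                 selected = rank <= m)
}
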