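test_that("protein branch pooling shrinks positions by ceiling halves", {
  model <- init_encoder(desk_config(), seed = 1)
  feats <- encode_protein(model, strrep("A", 10))
  expect_equal(vapply(feats, nrow, 1L), c(10L, 5L, 3L))
  expect_equal(vapply(feats, ncol, 1L), rep(8L, 3))
  expect_error(encode_protein(model, integer(0)), "length 0")
})

test_that("delta kernels on a constant sequence give constant feature maps", {
  cfg <- desk_config()
  model <- init_encoder(cfg, seed = 1)
  # embedding constant, each conv kernel an identity-like delta (center tap)
  model$params$embed$v <- matrix(0.5, 26, cfg$embed_dim)
  for (i in 1:3) {
    k <- cfg$protein_kernel_sizes[i]
    W <- matrix(0, k * 8, 8)
    center <- ((k - 1) %/% 2)
    W[center * 8 + seq_len(8), ] <- diag(8)
    model$params[[paste0("Wp", i)]]$v <- W
    model$params[[paste0("bp", i)]]$v <- matrix(0, 1, 8)
  }
  feats <- encode_protein(model, strrep("G", 16))
  for (P in feats) {
    expect_lt(max(abs(sweep(P, 2, P[1, ]))), 1e-12)
  }
  # hand evaluation: each level is relu of the previous constant row
  x <- rep(0.5, 8)
  for (i in 1:3) {
    x <- pmax(x, 0)
    expect_equal(unname(feats[[i]][1, ]), x, tolerance = 1e-12)
  }
})

test_that("drug branch reduces to a plain MLP on an isolated atom", {
  model <- init_encoder(desk_config(), seed = 2)
  g <- smiles_to_graph("C")
  expect_equal(g$n_atoms, 1L)
  feats <- encode_drug(model, g)
  h <- g$node_features
  for (i in 1:3) {
    h <- pmax(h %*% model$params[[paste0("Wd", i)]]$v +
                matrix(model$params[[paste0("bd", i)]]$v,
                       nrow(h), 8, byrow = TRUE), 0)
    expect_equal(feats[[i]], h, tolerance = 1e-12)
  }
})

test_that("drug features are permutation-equivariant and symmetric on stars", {
  model <- init_encoder(desk_config(), seed = 3)
  g <- smiles_to_graph("CC(C)(C)O") # neopentane-like star with one O leaf
  feats <- encode_drug(model, g)
  perm <- c(3, 1, 5, 2, 4)
  gp <- permute_graph(g, perm)
  featsp <- encode_drug(model, gp)
  for (i in 1:3) {
    expect_equal(featsp[[i]], feats[[i]][perm, , drop = FALSE], tolerance = 1e-10)
  }
  # identical carbon leaves of the star embed identically at every level
  star <- smiles_to_graph("C(C)(C)C")
  sf <- encode_drug(model, star)
  leaves <- which(star$node_features[, 1] == 1 &
                    star$node_features[, 10 + 1 + 1] == 1) # C atoms of degree 1
  expect_equal(length(leaves), 3L)
  for (i in 1:3) {
    expect_lt(max(abs(sweep(sf[[i]][leaves, ], 2, sf[[i]][leaves[1], ]))), 1e-12)
  }
})

test_that("bilinear fusion matches the explicit pair-loop oracle", {
  set.seed(21)
  for (rep in 1:20) {
    c <- sample(2:8, 1); h <- sample(2:8, 1); r <- sample(1:4, 1)
    f <- sample(2:8, 1)
    P <- rand_mat(sample(1:6, 1), c)
    D <- rand_mat(sample(1:5, 1), h)
    pars <- rand_params_bilinear(c, h, r, f)
    got <- bilinear_fuse(P, D, pars)
    want <- bilinear_loop(P, D, pars)
    expect_equal(got$vector, want$vector, tolerance = 1e-10)
    expect_equal(got$attention_map, want$attention_map, tolerance = 1e-10)
    expect_true(all(got$attention_map >= 0))
  }
})

test_that("bilinear attention is constant for constant inputs and reduces to one pair", {
  set.seed(22)
  pars <- rand_params_bilinear(4, 4, 3, 6)
  P <- matrix(rep(rnorm(4), each = 5), 5, 4) # identical residue rows
  D <- matrix(rep(rnorm(4), each = 3), 3, 4) # identical atom rows
  out <- bilinear_fuse(P, D, pars)
  expect_lt(diff(range(out$attention_map)), 1e-12)

  P1 <- P[1, , drop = FALSE]
  D1 <- D[1, , drop = FALSE]
  one <- bilinear_fuse(P1, D1, pars)
  want <- bilinear_loop(P1, D1, pars)
  expect_equal(one$vector, want$vector, tolerance = 1e-12)
})

test_that("gated fusion matches a hand-rolled gate computation", {
  set.seed(23)
  f <- 6
  pars <- list(Wg = rand_mat(f, 3), bg = rnorm(3), Ws = rand_mat(f, f),
               bs = rnorm(f))
  I_list <- lapply(1:3, function(i) rnorm(f))
  got <- gated_fuse(I_list, pars)
  want <- gated_loop(I_list, pars)
  expect_equal(got$vector, want$vector, tolerance = 1e-10)
  expect_equal(got$gates, want$gates, tolerance = 1e-10)

  # bias saturation forces a one-hot gate: O = f_s(I_1)
  pars2 <- pars
  pars2$Wg <- matrix(0, f, 3)
  pars2$bg <- c(60, -60, -60)
  oh <- gated_fuse(I_list, pars2)
  expect_equal(oh$gates, c(1, 0, 0), tolerance = 1e-12)
  fs1 <- pmax(as.numeric(I_list[[1]] %*% pars$Ws) + pars$bs, 0)
  expect_equal(oh$vector, fs1 / sqrt(mean(fs1^2) + 1e-6), tolerance = 1e-10)

  # zero interactions: gates = logistic(bg), O = f_s(0) (RMS-normalized)
  zl <- lapply(1:3, function(i) rep(0, f))
  z <- gated_fuse(zl, pars)
  expect_equal(z$gates, 1 / (1 + exp(-pars$bg)), tolerance = 1e-12)
  fs0 <- pmax(pars$bs, 0)
  expect_equal(z$vector, fs0 / sqrt(mean(fs0^2) + 1e-6), tolerance = 1e-12)

  expect_error(gated_fuse(list(rnorm(4), rnorm(5), rnorm(4)), pars),
               "mismatched")
})

test_that("forward is deterministic, in (0,1), and 0.5 under a zero head", {
  model <- init_encoder(desk_config(), seed = 4)
  seqs <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  out1 <- forward_pair(model, seqs, "CCOc1ccccc1")
  out2 <- forward_pair(model, seqs, "CCOc1ccccc1")
  expect_identical(out1$y_c, out2$y_c)
  expect_identical(out1$O, out2$O)
  expect_gt(out1$y_c, 0)
  expect_lt(out1$y_c, 1)

  zm <- init_encoder(desk_config(), seed = 4)
  zm$params$wh2$v <- matrix(0, nrow(zm$params$wh2$v), 1)
  zm$params$bh2$v <- matrix(0, 1, 1)
  for (sm in c("CCO", "c1ccncc1", "CC(=O)NC")) {
    expect_equal(forward_pair(zm, seqs, sm)$y_c, 0.5)
  }
})

test_that("y_c is invariant to atom relabeling and to appended padding", {
  model <- init_encoder(desk_config(), seed = 5)
  seqs <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  g <- smiles_to_graph("CC(=O)Nc1ccccc1")
  base <- forward_pair(model, seqs, g)
  perm <- rev(seq_len(g$n_atoms))
  pg <- permute_graph(g, perm)
  permuted <- forward_pair(model, seqs, pg)
  expect_equal(permuted$y_c, base$y_c, tolerance = 1e-10)
  # attention-map columns permute identically
  for (i in 1:3) {
    expect_equal(permuted$attention_maps[[i]],
                 base$attention_maps[[i]][, perm], tolerance = 1e-10)
  }
  # padding tokens never change the prediction
  tk <- tokenize_protein(seqs, l_max = 50, pad = FALSE)$tokens
  padded <- c(tk, rep(0L, 17))
  expect_identical(forward_pair(model, padded, g)$y_c,
                   forward_pair(model, tk, g)$y_c)
})

test_that("the affinity head is an exact linear readout", {
  set.seed(24)
  f <- 16
  O <- rnorm(f)
  pars <- list(wr = rep(0, f), br = 5)
  expect_equal(predict_affinity(O, pars), 5)
  pars2 <- list(wr = rnorm(f), br = 0.7)
  y1 <- predict_affinity(O, pars2)
  y2 <- predict_affinity(2 * O, pars2)
  expect_equal(y2 - pars2$br, 2 * (y1 - pars2$br), tolerance = 1e-12)
  expect_equal(y1, sum(O * pars2$wr) + 0.7, tolerance = 1e-12)
})

test_that("top-attention extraction obeys the tie-break and dominance rules", {
  uni <- top_attended(rep(1, 10), 0.2)
  expect_identical(uni$index[uni$selected], c(1L, 2L))

  dom <- c(0, 0, 9, 0)
  for (f in c(0.05, 0.25, 0.5, 1)) {
    expect_true(3L %in% top_attended(dom, f)$index[top_attended(dom, f)$selected])
  }

  set.seed(25)
  for (rep in 1:10) {
    sc <- sample(rnorm(8), 8)
    res <- top_attended(sc, 0.4)
    m <- ceiling(0.4 * 8)
    oracle <- order(-sc, seq_along(sc))[seq_len(m)]
    expect_setequal(res$index[res$selected], oracle)
  }

  model <- init_encoder(desk_config(), seed = 6)
  att <- extract_attention(model, "MKTAYIAKQRQISFVK", "CCOc1ccccc1", 0.2)
  expect_setequal(unique(att$entity), c("atom", "residue"))
  expect_equal(sum(att$selected[att$level == 1 & att$entity == "atom"]),
               ceiling(0.2 * smiles_to_graph("CCOc1ccccc1")$n_atoms))
})

test_that("checkpoints round-trip through JSON", {
  model <- init_encoder(desk_config(), seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$config, model$config)
  for (nm in names(model$params)) {
    expect_equal(back$params[[nm]]$v, model$params[[nm]]$v, tolerance = 1e-12)
  }
  out1 <- forward_pair(model, "MKTAYIAK", "CCO")
  out2 <- forward_pair(back, "MKTAYIAK", "CCO")
  expect_equal(out1$y_c, out2$y_c, tolerance = 1e-12)
})
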