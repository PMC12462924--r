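# Meta-stage core: tensor-expansion layout, affine attention, dynamic
# prototypes, cosine classification and focal loss.

test_that("expand_concat places the query first and replicates supports", {
  O_s <- array(c(1, 0, 0, 1), c(1, 2, 2)) # supports (1,0) and (0,1)
  O_q <- array(c(5, 5), c(1, 1, 2))
  O_c <- expand_concat(O_s, O_q)
  expect_equal(dim(O_c), c(1, 1, 3, 2))
  expect_equal(O_c[1, 1, , ], rbind(c(5, 5), c(1, 0), c(0, 1)))

  set.seed(41)
  inst <- rand_meta_instance()
  O_c <- expand_concat(inst$O_s, inst$O_q)
  for (n in seq_len(inst$N)) for (q in seq_len(inst$kq)) {
    expect_equal(O_c[n, q, 1, ], inst$O_q[n, q, ])
    for (i in seq_len(2 * inst$k)) {
      expect_equal(O_c[n, q, i + 1, ], inst$O_s[n, i, ])
    }
  }
})

test_that("affine attention matches the hand-unrolled evaluation", {
  set.seed(42)
  # fully hand-unrolled 1x1x1 instance with k = 1, d = 2
  inst <- rand_meta_instance(N = 1, kq = 1, k = 1, d = 2)
  O_c <- expand_concat(inst$O_s, inst$O_q)
  A <- affine_attention(O_c, inst$params)
  rows <- O_c[1, 1, , ]
  Z <- silu_ref(rows %*% inst$params$W_I)
  Q <- sweep(sweep(Z, 2, inst$params$gamma1, "*"), 2, inst$params$beta1, "+")
  K <- sweep(sweep(Z, 2, inst$params$gamma2, "*"), 2, inst$params$beta2, "+")
  raw <- pmax(Q %*% t(K), 0)^2
  expect_equal(A[1, 1, ], raw[1, -1], tolerance = 1e-12)

  # zero projections give identically zero attention; ReLU-square keeps A >= 0
  zp <- list(W_I = inst$params$W_I, gamma1 = rep(0, 2), beta1 = rep(0, 2),
             gamma2 = rep(0, 2), beta2 = rep(0, 2))
  expect_true(all(affine_attention(O_c, zp) == 0))
  for (rep in 1:5) {
    inst <- rand_meta_instance()
    A <- affine_attention(expand_concat(inst$O_s, inst$O_q), inst$params)
    expect_true(all(A >= 0))
  }
})

test_that("dynamic prototypes softmax within each class only", {
  set.seed(43)
  inst <- rand_meta_instance(N = 2, kq = 2, k = 3, d = 3)
  O_c <- expand_concat(inst$O_s, inst$O_q)
  A <- affine_attention(O_c, inst$params)
  P <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], inst$sup_labels, A)

  # zero attention = uniform softmax = unweighted class means
  A0 <- array(0, dim(A))
  P0 <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], inst$sup_labels, A0)
  for (n in 1:2) for (q in 1:2) for (cc in 0:1) {
    idx <- which(inst$sup_labels == cc)
    expect_equal(P0[n, q, cc + 1, ], colMeans(inst$O_s[n, idx, ]),
                 tolerance = 1e-12)
  }

  # k = 1: each prototype is its single support vector
  inst1 <- rand_meta_instance(k = 1)
  O_c1 <- expand_concat(inst1$O_s, inst1$O_q)
  A1 <- affine_attention(O_c1, inst1$params)
  P1 <- dynamic_prototypes(O_c1[, , -1, , drop = FALSE], inst1$sup_labels, A1)
  for (n in seq_len(inst1$N)) for (q in seq_len(inst1$kq)) {
    expect_equal(P1[n, q, 2, ], inst1$O_s[n, 1, ], tolerance = 1e-12)
    expect_equal(P1[n, q, 1, ], inst1$O_s[n, 2, ], tolerance = 1e-12)
  }

  # permuting supports within a class leaves prototypes unchanged
  perm <- c(2, 3, 1, 5, 4, 6) # permutes within label blocks (k = 3)
  Pp <- dynamic_prototypes(O_c[, , -1, , drop = FALSE][, , perm, , drop = FALSE],
                           inst$sup_labels[perm], A[, , perm, drop = FALSE])
  expect_equal(Pp, P, tolerance = 1e-12)

  expect_error(dynamic_prototypes(O_c[, , -1, , drop = FALSE],
                                  rep(1L, 6), A), "empty")
})

test_that("cosine classification and focal loss match closed forms", {
  # query equals the positive prototype, orthogonal to the negative one
  P <- array(0, c(1, 1, 2, 2))
  P[1, 1, 2, ] <- c(1, 0)
  P[1, 1, 1, ] <- c(0, 1)
  O_q <- array(c(1, 0), c(1, 1, 2))
  out <- classify_and_loss(P, O_q, 1L, focal_params(alpha = 1, gamma = 2))
  expect_equal(out$scores[1, 1, ], c(0, 1), tolerance = 1e-7)
  expect_equal(out$probs[1, 1], exp(1) / (exp(1) + 1), tolerance = 1e-7)

  # gamma = 0, alpha = 1 reduces the focal loss to cross-entropy
  set.seed(44)
  inst <- rand_meta_instance(N = 3, kq = 3, k = 2, d = 3)
  O_c <- expand_concat(inst$O_s, inst$O_q)
  A <- affine_attention(O_c, inst$params)
  P <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], inst$sup_labels, A)
  out <- classify_and_loss(P, inst$O_q, inst$qry_labels,
                           focal_params(alpha = 1, gamma = 0))
  expect_equal(out$loss, mean(-log(out$probs)), tolerance = 1e-7)

  # single query at p = 0.5, gamma = 2: L = 0.25 * ln 2
  Pq <- array(0, c(1, 1, 2, 2))
  Pq[1, 1, 1, ] <- c(1, 0)
  Pq[1, 1, 2, ] <- c(0, 1)
  Oq <- array(c(1, 1), c(1, 1, 2)) # equidistant from both prototypes
  half <- classify_and_loss(Pq, Oq, 1L, focal_params(1, 2))
  expect_equal(half$probs[1, 1], 0.5, tolerance = 1e-9)
  expect_equal(half$loss, 0.25 * log(2), tolerance = 1e-9)
})

test_that("the meta core matches the nested-loop oracle on random instances", {
  set.seed(45)
  for (rep in 1:30) {
    inst <- rand_meta_instance()
    alpha <- runif(1, 0.5, 2)
    gamma <- sample(c(0, 1, 2), 1)
    O_c <- expand_concat(inst$O_s, inst$O_q)
    A <- affine_attention(O_c, inst$params)
    P <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], inst$sup_labels, A)
    out <- classify_and_loss(P, inst$O_q, inst$qry_labels,
                             focal_params(alpha, gamma))
    want <- meta_loop(inst$O_s, inst$O_q, inst$sup_labels, inst$qry_labels,
                      inst$params, alpha, gamma)
    expect_equal(O_c, want$O_c, tolerance = 1e-9)
    expect_equal(A, want$A, tolerance = 1e-9)
    expect_equal(P, want$P, tolerance = 1e-9)
    expect_equal(out$scores, want$scores, tolerance = 1e-9)
    expect_equal(out$loss, want$loss, tolerance = 1e-9)
  }
})

test_that("prototype scaling leaves scores, probabilities and loss unchanged", {
  set.seed(46)
  inst <- rand_meta_instance(N = 2, kq = 3, k = 2, d = 4)
  O_c <- expand_concat(inst$O_s, inst$O_q)
  A <- affine_attention(O_c, inst$params)
  P <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], inst$sup_labels, A)
  base <- classify_and_loss(P, inst$O_q, inst$qry_labels, focal_params())
  for (cscale in c(0.1, 3, 250)) {
    sc <- classify_and_loss(P * cscale, inst$O_q, inst$qry_labels, focal_params())
    expect_equal(sc$scores, base$scores, tolerance = 1e-6)
    expect_equal(sc$loss, base$loss, tolerance = 1e-6)
  }
  # the restored 1/|O_c| prefactor is exactly such a rescaling
  Ppre <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], inst$sup_labels, A,
                             prefactor = TRUE)
  pre <- classify_and_loss(Ppre, inst$O_q, inst$qry_labels, focal_params())
  expect_equal(pre$loss, base$loss, tolerance = 1e-6)
})

test_that("training-path meta loss equals the public numeric path", {
  set.seed(47)
  model <- init_encoder(desk_config(), seed = 8)
  d <- model$config$fusion_dim
  k <- 2; kq <- 3
  O_s <- array(rnorm(2 * k * d), c(1, 2 * k, d))
  O_q <- array(rnorm(kq * d), c(1, kq, d))
  sup_labels <- rep(c(1L, 0L), each = k)
  qry_labels <- c(1L, 0L, 1L)
  params <- model$params
  mp <- list(W_I = params$WI$v, gamma1 = as.numeric(params$gamma1$v),
             beta1 = as.numeric(params$beta1$v),
             gamma2 = as.numeric(params$gamma2$v),
             beta2 = as.numeric(params$beta2$v))
  O_c <- expand_concat(O_s, O_q)
  A <- affine_attention(O_c, mp)
  P <- dynamic_prototypes(O_c[, , -1, , drop = FALSE], sup_labels, A)
  want <- classify_and_loss(P, O_q, qry_labels, focal_params())

  terms <- vapply(seq_len(kq), function(q) {
    out <- metadti:::meta_query_core(
      params, metadti:::tg_const(matrix(O_q[1, q, ], 1)),
      lapply(seq_len(2 * k), function(i) metadti:::tg_const(matrix(O_s[1, i, ], 1))),
      sup_labels, qry_labels[q], focal_params()
    )
    metadti:::tg_v(out$term)[1]
  }, 0)
  expect_equal(mean(terms), want$loss, tolerance = 1e-8)
})

test_that("episodes respect size, feasibility and determinism contracts", {
  ds <- generate_dataset(synthetic_config(seed = 7))
  asn <- cluster_proteins(ds$proteins, n_clusters = 6, seed = 7)
  eps <- build_episodes(ds$interactions, asn, k = 3, k_q = 5, n_tasks = 12,
                        seed = 5)
  expect_length(eps, 12L)
  for (ep in eps) {
    expect_equal(nrow(ep$support), 6L)
    expect_equal(nrow(ep$query), 5L)
    expect_equal(sum(ep$support$label), 3L)
    # unseen-protein guard
    expect_length(intersect(ep$support$protein_id, ep$query$protein_id), 0L)
    # all pairs come from one cluster
    cl <- asn$cluster_id[match(c(ep$support$protein_id, ep$query$protein_id),
                               asn$protein_id)]
    expect_equal(unique(cl), ep$cluster_id)
  }
  eps2 <- build_episodes(ds$interactions, asn, k = 3, k_q = 5, n_tasks = 12,
                         seed = 5)
  expect_identical(eps, eps2)

  # a single-protein cluster cannot host unseen-protein episodes
  tiny <- tibble::tibble(
    drug_id = sprintf("D%03d", 1:10),
    protein_id = "P001", label = rep(c(0L, 1L), 5), affinity = NA_real_
  )
  asn1 <- tibble::tibble(protein_id = "P001", cluster_id = 0L)
  expect_error(suppressWarnings(
    build_episodes(tiny, asn1, k = 2, k_q = 2, n_tasks = 3, seed = 1)
  ), "no cluster")
  expect_warning(
    try(build_episodes(tiny, asn1, k = 2, k_q = 2, n_tasks = 3, seed = 1),
        silent = TRUE),
    "skipped"
  )
})

test_that("few-shot evaluation recovers hand-computable metrics", {
  ds <- generate_dataset(synthetic_config(seed = 7))
  feats <- featurize_dataset(ds, l_max = 150)
  asn <- cluster_proteins(ds$proteins, n_clusters = 6, seed = 7)
  eps <- build_episodes(ds$interactions, asn, k = 2, k_q = 4, n_tasks = 4,
                        seed = 9)
  # an all-zero encoder scores every query 0.5: chance AUROC by tie convention
  zm <- init_encoder(desk_config(), seed = 1)
  for (nm in names(zm$params)) zm$params[[nm]]$v <- zm$params[[nm]]$v * 0
  ev <- evaluate_fewshot(zm, eps, feats)
  expect_true(all(abs(ev$per_episode$auroc - 0.5) < 1e-12))

  # hand-built episode scores: AUROC 0.75 from 3 concordant pairs of 4
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2))
  expect_equal(m$auroc, 0.75)
})
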