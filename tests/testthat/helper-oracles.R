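# Independent oracles used across the suite. These deliberately use naive
# nested loops / direct formulas, not the package's vectorized paths.

# central finite-difference gradient of scalar f at matrix x
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# O(n^2) pairwise AUROC with half-credit for ties
auroc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# explicit double loop over (residue, atom) pairs for bilinear fusion
bilinear_loop <- function(P, D, params) {
  Ap <- pmax(P %*% params$U, 0)
  Ad <- pmax(D %*% params$V, 0)
  Pf <- P %*% params$Uf
  Df <- D %*% params$Vf
  f <- ncol(Pf)
  M <- matrix(0, nrow(P), nrow(D))
  vec <- numeric(f)
  for (r in seq_len(nrow(P))) {
    for (a in seq_len(nrow(D))) {
      M[r, a] <- sum(Ap[r, ] * Ad[a, ])
      vec <- vec + M[r, a] * Pf[r, ] * Df[a, ]
    }
  }
  list(vector = vec / sqrt(nrow(P) * nrow(D)), attention_map = M)
}

# explicit gate computation for the level-selection unit (including the
# selection layer's RMS normalization)
gated_loop <- function(I_list, params, fs_on_gated_sum = TRUE) {
  f <- length(I_list[[1]])
  S <- numeric(f)
  gates <- numeric(length(I_list))
  for (i in seq_along(I_list)) {
    gates[i] <- 1 / (1 + exp(-(sum(I_list[[i]] * params$Wg[, i]) + params$bg[i])))
    S <- S + if (fs_on_gated_sum) gates[i] * I_list[[i]] else I_list[[i]]
  }
  v <- pmax(as.numeric(S %*% params$Ws) + params$bs, 0)
  list(vector = v / sqrt(mean(v^2) + 1e-6), gates = gates)
}

silu_ref <- function(x) x / (1 + exp(-x))

# fully nested-loop evaluation of the meta stage (expand, attention,
# prototypes, cosine scores, focal loss) for one instance
meta_loop <- function(O_s, O_q, sup_labels, qry_labels, params, alpha = 1,
                      gamma = 2, prefactor = FALSE) {
  N <- dim(O_s)[1]; twok <- dim(O_s)[2]; d <- dim(O_s)[3]; kq <- dim(O_q)[2]
  if (is.null(dim(sup_labels))) sup_labels <- matrix(sup_labels, N, twok, byrow = TRUE)
  if (is.null(dim(qry_labels))) qry_labels <- matrix(qry_labels, N, kq, byrow = TRUE)
  O_c <- array(0, c(N, kq, twok + 1, d))
  A <- array(0, c(N, kq, twok))
  P <- array(0, c(N, kq, 2, d))
  scores <- array(0, c(N, kq, 2))
  probs <- matrix(0, N, kq)
  terms <- c()
  for (n in 1:N) for (q in 1:kq) {
    O_c[n, q, 1, ] <- O_q[n, q, ]
    for (i in 1:twok) O_c[n, q, i + 1, ] <- O_s[n, i, ]
    rows <- matrix(O_c[n, q, , ], twok + 1, d)
    Z <- silu_ref(rows %*% params$W_I)
    Q <- sweep(sweep(Z, 2, params$gamma1, "*"), 2, params$beta1, "+")
    K <- sweep(sweep(Z, 2, params$gamma2, "*"), 2, params$beta2, "+")
    raw <- pmax(Q %*% t(K), 0)^2
    A[n, q, ] <- raw[1, -1]
    for (cc in 0:1) {
      idx <- which(sup_labels[n, ] == cc)
      a <- A[n, q, idx]
      w <- exp(a) / sum(exp(a))
      pr <- numeric(d)
      for (j in seq_along(idx)) pr <- pr + w[j] * O_s[n, idx[j], ]
      if (prefactor) pr <- pr / (twok + 1)
      P[n, q, cc + 1, ] <- pr
      v <- O_q[n, q, ]
      scores[n, q, cc + 1] <- sum(pr * v) /
        ((sqrt(sum(pr^2)) + 1e-8) * (sqrt(sum(v^2)) + 1e-8))
    }
    e <- exp(scores[n, q, ])
    sm <- e / sum(e)
    pt <- sm[qry_labels[n, q] + 1]
    probs[n, q] <- pt
    a_eff <- if (qry_labels[n, q] == 1) alpha else 1
    terms <- c(terms, -a_eff * (1 - pt)^gamma * log(pt))
  }
  list(O_c = O_c, A = A, P = P, scores = scores, probs = probs,
       loss = mean(terms))
}

rand_mat <- function(nr, nc, sd = 0.5) matrix(rnorm(nr * nc, sd = sd), nr, nc)

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  (sij - expected) / (mx - expected)
}

# random small meta-stage instance (N, k_q, k, d <= 4)
rand_meta_instance <- function(N = NULL, kq = NULL, k = NULL, d = NULL) {
  N <- N %||% sample(1:4, 1)
  kq <- kq %||% sample(1:4, 1)
  k <- k %||% sample(1:4, 1)
  d <- d %||% sample(2:4, 1)
  list(
    N = N, kq = kq, k = k, d = d,
    O_s = array(rnorm(N * 2 * k * d), c(N, 2 * k, d)),
    O_q = array(rnorm(N * kq * d), c(N, kq, d)),
    sup_labels = rep(c(1L, 0L), each = k),
    qry_labels = sample(0:1, kq, replace = TRUE),
    params = list(W_I = rand_mat(d, d), gamma1 = rnorm(d), beta1 = rnorm(d),
                  gamma2 = rnorm(d), beta2 = rnorm(d))
  )
}

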