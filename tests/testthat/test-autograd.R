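# The reverse-mode engine underpins every trainable module; each op is
# checked against central finite differences on random instances.

expect_grad_matches <- function(build, x0, tol = 1e-5) {
  # build(tensor) must return a scalar tensor
  p <- tg_param(x0)
  loss <- build(p)
  tg_backward(loss)
  expect_false(is.null(p$grad))
  fd <- fd_grad(function(x) tg_v(build(tg_const(x)))[1], x0)
  expect_lt(max(abs(p$grad - fd)), tol * max(1, max(abs(fd))))
}

test_that("elementwise and broadcast ops backpropagate correctly", {
  set.seed(1)
  x <- rand_mat(3, 4)
  b_row <- rand_mat(1, 4)
  b_col <- rand_mat(3, 1)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_add(p, tg_const(b_row)))), x)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_mul(p, tg_const(b_col)))), x)
  expect_grad_matches(function(p) tg_sum(tg_div(tg_const(abs(x) + 1), tg_add(tg_sq(p), tg_const(1)))), x)
  expect_grad_matches(function(p) tg_mean(tg_sub(tg_mul(p, p), tg_scale(p, 0.3))), x)
  # gradient onto a broadcast operand accumulates over the expanded axis
  pb <- tg_param(b_row)
  loss <- tg_sum(tg_sq(tg_add(tg_const(x), pb)))
  tg_backward(loss)
  fd <- fd_grad(function(v) sum((x + matrix(v, 3, 4, byrow = TRUE))^2), b_row)
  expect_lt(max(abs(pb$grad - fd)), 1e-5)
})

test_that("matmul, transpose, stacking and indexing backpropagate correctly", {
  set.seed(2)
  x <- rand_mat(4, 3)
  W <- rand_mat(3, 5)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_matmul(p, tg_const(W)))), x)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_matmul(tg_const(t(W)), tg_t(p)))), x)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_rows(p, c(1, 3, 3)))), x)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_cols(p, c(2, 2, 1)))), x)
  expect_grad_matches(function(p) {
    tg_sum(tg_sq(tg_vstack(list(tg_rows(p, 1:2), tg_rows(p, 3:4)))))
  }, x)
  expect_grad_matches(function(p) {
    tg_sum(tg_sq(tg_hstack(list(p, tg_sq(p)))))
  }, x)
})

test_that("nonlinearities and reductions backpropagate correctly", {
  set.seed(3)
  x <- rand_mat(3, 3)
  expect_grad_matches(function(p) tg_sum(tg_relu(p)), x, tol = 1e-4)
  expect_grad_matches(function(p) tg_sum(tg_sigmoid(p)), x)
  expect_grad_matches(function(p) tg_sum(tg_silu(p)), x)
  expect_grad_matches(function(p) tg_sum(tg_exp(p)), x)
  expect_grad_matches(function(p) tg_sum(tg_log(tg_add(tg_sq(p), tg_const(1)))), x)
  expect_grad_matches(function(p) tg_sum(tg_sqrt(tg_add(tg_sq(p), tg_const(1)))), x)
  expect_grad_matches(function(p) tg_sum(tg_pow(tg_add(tg_sq(p), tg_const(0.5)), 2.7)), x)
  expect_grad_matches(function(p) tg_mean(tg_sq(tg_rowsums(p))), x)
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_softmax_rows(p))), x)
})

test_that("convolution unfolding and max-pooling backpropagate correctly", {
  set.seed(4)
  for (k in c(3, 4, 6)) {
    x <- rand_mat(7, 2)
    W <- rand_mat(k * 2, 3)
    expect_grad_matches(function(p) {
      tg_sum(tg_sq(tg_matmul(tg_unfold(p, k), tg_const(W))))
    }, x)
  }
  x <- rand_mat(5, 3) # odd row count exercises the pass-through tail
  expect_grad_matches(function(p) tg_sum(tg_sq(tg_maxpool2(p))), x, tol = 1e-4)
})

test_that("fused bilinear pooling matches finite differences in every input", {
  set.seed(7)
  P <- rand_mat(4, 3); D <- rand_mat(3, 2)
  U <- rand_mat(3, 2); V <- rand_mat(2, 2)
  Uf <- rand_mat(3, 5); Vf <- rand_mat(2, 5)
  ins <- list(P = P, D = D, U = U, V = V, Uf = Uf, Vf = Vf)
  w <- rand_mat(1, 5) # random linear functional makes the loss scalar
  for (nm in names(ins)) {
    p <- tg_param(ins[[nm]])
    args <- lapply(names(ins), function(x) if (x == nm) p else tg_const(ins[[x]]))
    loss <- tg_sum(tg_mul(do.call(tg_bilinear_pool, args), tg_const(w)))
    tg_backward(loss)
    fd <- fd_grad(function(v) {
      args2 <- lapply(names(ins), function(x) {
        tg_const(if (x == nm) v else ins[[x]])
      })
      sum(tg_v(do.call(tg_bilinear_pool, args2)) * w)
    }, ins[[nm]])
    expect_lt(max(abs(p$grad - fd)), 1e-5 * max(1, max(abs(fd))))
  }
})

test_that("fused gated sum matches finite differences in every input", {
  set.seed(8)
  Istack <- rand_mat(3, 4)
  Wg <- rand_mat(4, 3)
  bg <- rand_mat(1, 3)
  w <- rand_mat(1, 4)
  ins <- list(Istack = Istack, Wg = Wg, bg = bg)
  for (nm in names(ins)) {
    p <- tg_param(ins[[nm]])
    args <- lapply(names(ins), function(x) if (x == nm) p else tg_const(ins[[x]]))
    loss <- tg_sum(tg_mul(do.call(tg_gated_sum, args), tg_const(w)))
    tg_backward(loss)
    fd <- fd_grad(function(v) {
      args2 <- lapply(names(ins), function(x) {
        tg_const(if (x == nm) v else ins[[x]])
      })
      sum(tg_v(do.call(tg_gated_sum, args2)) * w)
    }, ins[[nm]])
    expect_lt(max(abs(p$grad - fd)), 1e-5 * max(1, max(abs(fd))))
  }
  # ungated variant is the plain column sum
  s <- tg_gated_sum(tg_const(Istack), tg_const(Wg), tg_const(bg), use_gates = FALSE)
  expect_equal(as.numeric(tg_v(s)), colSums(Istack), tolerance = 1e-12)
})

test_that("stable BCE-with-logits matches its naive form and gradient", {
  set.seed(5)
  z <- rand_mat(6, 1, sd = 3)
  y <- matrix(rbinom(6, 1, 0.5), ncol = 1)
  naive <- -(y * log(1 / (1 + exp(-z))) + (1 - y) * log(1 - 1 / (1 + exp(-z))))
  expect_equal(tg_v(tg_bce_logits(tg_const(z), y)), naive, tolerance = 1e-10)
  expect_grad_matches(function(p) tg_mean(tg_bce_logits(p, y)), z)
})

test_that("gradients accumulate across reuse of the same node", {
  x <- matrix(2)
  p <- tg_param(x)
  # f(x) = x^2 + 3x uses p twice
  loss <- tg_add(tg_mul(p, p), tg_scale(p, 3))
  tg_backward(loss)
  expect_equal(p$grad[1], 2 * 2 + 3)
})

test_that("gradient reversal is an exact identity forward and scales by -lambda backward", {
  set.seed(6)
  x <- rand_mat(4, 3)
  out <- grl(x, 2.5)
  expect_identical(out, x) # bit-for-bit on plain numerics
  p <- tg_param(x)
  o <- tg_grl(p, 2.5)
  expect_identical(tg_v(o), x)
  tg_backward(tg_sum(tg_sq(o)))
  expect_equal(p$grad, -2.5 * 2 * x, tolerance = 1e-12)

  # composed-function contract: f(grl(x, 1)) with f(u) = u^2 at x = 3
  p <- tg_param(matrix(3))
  tg_backward(tg_sq(tg_grl(p, 1)))
  expect_equal(p$grad[1], -6)
  # finite-difference of the composition without reversal, scaled by -lambda
  fd <- fd_grad(function(v) v[1]^2, matrix(3))
  expect_equal(p$grad[1], -1 * fd[1], tolerance = 1e-4)

  # lambda = 0 blocks the upstream gradient entirely
  p <- tg_param(matrix(3))
  tg_backward(tg_sq(tg_grl(p, 0)))
  expect_equal(p$grad[1], 0)
})

test_that("no-grad mode skips tape recording", {
  p <- tg_param(rand_mat(2, 2))
  out <- tg_no_grad(tg_sum(tg_sq(p)))
  expect_false(out$track)
  expect_null(out$backward)
})
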