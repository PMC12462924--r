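# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1, vectors 1xd).
# A node is an environment holding the value `v`, an accumulated gradient
# `grad`, its tracked `parents` and a `backward` closure that maps the node's
# upstream gradient to a list of parent gradients. Gradients are only recorded
# for nodes downstream of a parameter, and recording can be switched off
# globally for inference (`tg_no_grad()`).

.tape <- new.env(parent = emptyenv())
.tape$n <- 0
.tape$grad_on <- TRUE

tg_is <- function(x) is.environment(x)

#' @noRd
tg_tensor <- function(v, parents = NULL, backward = NULL, track = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$track <- track
  .tape$n <- .tape$n + 1
  e$id <- .tape$n
  class(e) <- "tg_tensor"
  e
}

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, nrow = 1)
}

tg_param <- function(v) tg_tensor(as_mat(v), track = TRUE)
tg_const <- function(v) tg_tensor(as_mat(v), track = FALSE)

# value of a tensor or plain numeric
tg_v <- function(x) if (tg_is(x)) x$v else as_mat(x)

tg_no_grad <- function(expr) {
  old <- .tape$grad_on
  .tape$grad_on <- FALSE
  on.exit(.tape$grad_on <- old)
  expr
}

# Record an op. `ins` is the list of input tensors (plain numerics allowed and
# treated as constants); `backward(g)` must return a list of gradients aligned
# with `ins` (NULL entries for constants).
tg_op <- function(v, ins, backward) {
  if (.tape$grad_on) {
    for (i in ins) {
      if (is.environment(i) && i$track) {
        return(tg_tensor(v, parents = ins, backward = backward, track = TRUE))
      }
    }
  }
  tg_tensor(v)
}

# ---- elementwise arithmetic with limited broadcasting ----------------------
# Shapes allowed for the second operand: same as a, 1 x ncol(a) (row
# broadcast), nrow(a) x 1 (column broadcast), or 1 x 1 (scalar).

bcast <- function(va, vb) {
  if (all(dim(vb) == dim(va))) return(vb)
  if (nrow(vb) == 1L && ncol(vb) == 1L) return(matrix(vb[1L], nrow(va), ncol(va)))
  if (nrow(vb) == 1L && ncol(vb) == ncol(va)) {
    return(matrix(vb, nrow(va), ncol(va), byrow = TRUE))
  }
  if (ncol(vb) == 1L && nrow(vb) == nrow(va)) return(matrix(vb, nrow(va), ncol(va)))
  stop("incompatible shapes: ", paste(dim(va), collapse = "x"), " vs ",
       paste(dim(vb), collapse = "x"))
}

# reduce a full-shaped gradient back onto the (possibly broadcast) shape of vb
unbcast <- function(g, vb) {
  if (all(dim(g) == dim(vb))) return(g)
  if (nrow(vb) == 1L && ncol(vb) == 1L) return(matrix(sum(g), 1L, 1L))
  if (nrow(vb) == 1L) return(matrix(colSums(g), 1L))
  matrix(rowSums(g), ncol = 1L)
}

tg_add <- function(a, b) {
  va <- tg_v(a); vb <- tg_v(b)
  tg_op(va + bcast(va, vb), list(a, b),
        function(g) list(g, unbcast(g, vb)))
}

tg_sub <- function(a, b) {
  va <- tg_v(a); vb <- tg_v(b)
  tg_op(va - bcast(va, vb), list(a, b),
        function(g) list(g, -unbcast(g, vb)))
}

tg_mul <- function(a, b) {
  va <- tg_v(a); vb <- tg_v(b)
  vbb <- bcast(va, vb)
  tg_op(va * vbb, list(a, b),
        function(g) list(g * vbb, unbcast(g * va, vb)))
}

tg_div <- function(a, b) {
  va <- tg_v(a); vb <- tg_v(b)
  vbb <- bcast(va, vb)
  tg_op(va / vbb, list(a, b),
        function(g) list(g / vbb, unbcast(-g * va / vbb^2, vb)))
}

tg_scale <- function(a, s) {
  va <- tg_v(a)
  tg_op(va * s, list(a), function(g) list(g * s))
}

# ---- linear algebra --------------------------------------------------------

tg_matmul <- function(a, b) {
  va <- tg_v(a); vb <- tg_v(b)
  tg_op(va %*% vb, list(a, b),
        function(g) list(tcrossprod(g, vb), crossprod(va, g)))
}

tg_t <- function(a) {
  tg_op(t(tg_v(a)), list(a), function(g) list(t(g)))
}

# ---- nonlinearities --------------------------------------------------------

tg_relu <- function(a) {
  va <- tg_v(a)
  m <- va > 0
  tg_op(va * m, list(a), function(g) list(g * m))
}

tg_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-tg_v(a)))
  tg_op(s, list(a), function(g) list(g * s * (1 - s)))
}

tg_silu <- function(a) {
  va <- tg_v(a)
  s <- 1 / (1 + exp(-va))
  tg_op(va * s, list(a), function(g) list(g * s * (1 + va * (1 - s))))
}

tg_exp <- function(a) {
  ev <- exp(tg_v(a))
  tg_op(ev, list(a), function(g) list(g * ev))
}

tg_log <- function(a) {
  va <- tg_v(a)
  tg_op(log(va), list(a), function(g) list(g / va))
}

tg_sq <- function(a) {
  va <- tg_v(a)
  tg_op(va^2, list(a), function(g) list(2 * g * va))
}

tg_sqrt <- function(a) {
  s <- sqrt(tg_v(a))
  tg_op(s, list(a), function(g) list(g / (2 * s)))
}

# ---- reductions ------------------------------------------------------------

tg_sum <- function(a) {
  va <- tg_v(a)
  tg_op(matrix(sum(va), 1L, 1L), list(a),
        function(g) list(matrix(g[1L], nrow(va), ncol(va))))
}

tg_mean <- function(a) {
  va <- tg_v(a)
  n <- length(va)
  tg_op(matrix(mean(va), 1L, 1L), list(a),
        function(g) list(matrix(g[1L] / n, nrow(va), ncol(va))))
}

tg_rowsums <- function(a) {
  va <- tg_v(a)
  tg_op(matrix(rowSums(va), ncol = 1L), list(a),
        function(g) list(matrix(g, nrow(va), ncol(va))))
}

# ---- structural ops --------------------------------------------------------

tg_rows <- function(a, idx) {
  va <- tg_v(a)
  idx <- as.integer(idx)
  tg_op(va[idx, , drop = FALSE], list(a), function(g) {
    gz <- matrix(0, nrow(va), ncol(va))
    rs <- rowsum(g, group = idx)
    gz[as.integer(rownames(rs)), ] <- rs
    list(gz)
  })
}

tg_cols <- function(a, idx) {
  va <- tg_v(a)
  idx <- as.integer(idx)
  tg_op(va[, idx, drop = FALSE], list(a), function(g) {
    gz <- matrix(0, nrow(va), ncol(va))
    cs <- rowsum(t(g), group = idx)
    gz[, as.integer(rownames(cs))] <- t(cs)
    list(gz)
  })
}

tg_vstack <- function(lst) {
  vals <- lapply(lst, tg_v)
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  tg_op(do.call(rbind, vals), lst, function(g) {
    lapply(seq_along(lst), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# 'same'-padded sliding windows for a 1-D convolution over the rows of a
# (positions x channels) matrix; output row t holds rows t-hl .. t+hr with
# hl = floor((k-1)/2), zero-padded at the boundary, laid out as k blocks of
# `channels` columns.
tg_unfold <- function(a, k) {
  va <- tg_v(a)
  L <- nrow(va); C <- ncol(va)
  hl <- (k - 1L) %/% 2L; hr <- k - 1L - hl
  ap <- rbind(matrix(0, hl, C), va, matrix(0, hr, C))
  rowsel <- outer(seq_len(L), 0:(k - 1L), "+") # indices into padded rows
  out <- do.call(cbind, lapply(seq_len(k), function(j) {
    ap[rowsel[, j], , drop = FALSE]
  }))
  tg_op(out, list(a), function(g) {
    gp <- matrix(0, L + k - 1L, C)
    for (j in seq_len(k)) {
      rows <- rowsel[, j]
      gp[rows, ] <- gp[rows, ] + g[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    }
    list(gp[(hl + 1L):(hl + L), , drop = FALSE])
  })
}

# non-overlapping max-pool over row pairs; odd trailing row passes through
tg_maxpool2 <- function(a) {
  va <- tg_v(a)
  L <- nrow(va); C <- ncol(va)
  if (L == 1L) return(tg_op(va, list(a), function(g) list(g)))
  odd <- L %% 2L == 1L
  vp <- if (odd) rbind(va, matrix(-Inf, 1L, C)) else va
  i1 <- seq(1L, nrow(vp), by = 2L)
  a1 <- vp[i1, , drop = FALSE]
  a2 <- vp[i1 + 1L, , drop = FALSE]
  first <- a1 >= a2 # ties keep the earlier position
  tg_op(pmax(a1, a2), list(a), function(g) {
    gz <- matrix(0, L + as.integer(odd), C)
    gz[i1, ] <- g * first
    gz[i1 + 1L, ] <- g * (!first)
    list(gz[seq_len(L), , drop = FALSE])
  })
}

tg_softmax_rows <- function(a) {
  va <- tg_v(a)
  ex <- exp(va - apply(va, 1L, max))
  sm <- ex / rowSums(ex)
  tg_op(sm, list(a), function(g) {
    list(sm * (g - rowSums(g * sm)))
  })
}

tg_hstack <- function(lst) {
  vals <- lapply(lst, tg_v)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  tg_op(do.call(cbind, vals), lst, function(g) {
    lapply(seq_along(lst), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# elementwise a^p for a >= 0 and fixed numeric exponent p
tg_pow <- function(a, p) {
  va <- tg_v(a)
  tg_op(va^p, list(a), function(g) list(g * p * va^(p - 1)))
}

# Numerically stable binary cross-entropy with logits, elementwise:
# l = softplus(z) - y*z, with d l / d z = sigmoid(z) - y.
tg_bce_logits <- function(z, y) {
  vz <- tg_v(z)
  vy <- bcast(vz, as_mat(y))
  l <- pmax(vz, 0) - vy * vz + log1p(exp(-abs(vz)))
  tg_op(l, list(z), function(g) list(g * (1 / (1 + exp(-vz)) - vy)))
}

# Gradient reversal: identity forward, gradient scaled by -lambda backward.
tg_grl <- function(a, lambda) {
  tg_op(tg_v(a), list(a), function(g) list(-lambda * g))
}

# ---- fused blocks ----------------------------------------------------------
# The two most-repeated per-pair blocks are fused into single tape nodes with
# hand-derived backward passes (checked against finite differences in the
# test suite) to keep the tape small.

# Low-rank bilinear attention pooling:
#   Ap = relu(P U), Ad = relu(D V), M = Ap Ad^T,
#   vec_k = (1 / sqrt(nP * nD)) * sum_{r,a} M[r,a] * (P Uf)[r,k] * (D Vf)[a,k]
# Returns the (1 x f) pooled vector; the attention map M is stored on the
# node as `aux`.
tg_bilinear_pool <- function(P, D, U, V, Uf, Vf) {
  vP <- tg_v(P); vD <- tg_v(D)
  vU <- tg_v(U); vV <- tg_v(V); vUf <- tg_v(Uf); vVf <- tg_v(Vf)
  PU <- vP %*% vU
  DV <- vD %*% vV
  Ap <- pmax(PU, 0)
  Ad <- pmax(DV, 0)
  M <- Ap %*% t(Ad)
  Pf <- vP %*% vUf
  Df <- vD %*% vVf
  s <- 1 / sqrt(nrow(vP) * nrow(vD))
  vec <- matrix(s * rowSums((t(Pf) %*% M) * t(Df)), 1L)
  node <- tg_op(vec, list(P, D, U, V, Uf, Vf), function(g) {
    gk <- as.numeric(g) # 1 x f
    gPf <- s * (M %*% Df) * matrix(gk, nrow(vP), length(gk), byrow = TRUE)
    gDf <- s * (t(M) %*% Pf) * matrix(gk, nrow(vD), length(gk), byrow = TRUE)
    gM <- s * (Pf * matrix(gk, nrow(vP), length(gk), byrow = TRUE)) %*% t(Df)
    gAp <- gM %*% Ad
    gAd <- t(gM) %*% Ap
    gPU <- gAp * (PU > 0)
    gDV <- gAd * (DV > 0)
    list(
      gPU %*% t(vU) + gPf %*% t(vUf),
      gDV %*% t(vV) + gDf %*% t(vVf),
      t(vP) %*% gPU,
      t(vD) %*% gDV,
      t(vP) %*% gPf,
      t(vD) %*% gDf
    )
  })
  node$aux <- M
  node
}

# Gated sum across levels: rows of Istack are the level vectors I_i,
#   g_i = sigmoid(I_i . Wg[, i] + bg[i]),  S = sum_i g_i * I_i  (1 x f).
# With use_gates = FALSE the gates are fixed at 1. Gates stored as `aux`.
tg_gated_sum <- function(Istack, Wg, bg, use_gates = TRUE) {
  vI <- tg_v(Istack)
  l <- nrow(vI)
  if (!use_gates) {
    node <- tg_op(matrix(colSums(vI), 1L), list(Istack, Wg, bg), function(g) {
      list(matrix(g, l, ncol(vI), byrow = TRUE), NULL, NULL)
    })
    node$aux <- rep(1, l)
    return(node)
  }
  vW <- tg_v(Wg); vb <- tg_v(bg)
  z <- rowSums(vI * t(vW)) + as.numeric(vb)
  gate <- 1 / (1 + exp(-z))
  S <- matrix(colSums(vI * gate), 1L)
  node <- tg_op(S, list(Istack, Wg, bg), function(g) {
    gs <- as.numeric(g)
    dgate <- as.numeric(vI %*% gs)            # dL/dg_i
    dz <- dgate * gate * (1 - gate)
    gI <- outer(gate, gs) + dz * t(vW)
    gW <- t(vI * dz)
    list(gI, gW, matrix(dz, 1L))
  })
  node$aux <- gate
  node
}

# ---- backward driver -------------------------------------------------------

#' @noRd
tg_backward <- function(root) {
  stopifnot(tg_is(root), length(root$v) == 1L)
  if (!root$track) return(invisible(NULL))
  # collect the tracked subgraph, marking visited nodes with a per-sweep stamp
  stamp <- .tape$stamp <- (.tape$stamp %||% 0) + 1
  nodes <- vector("list", 4096L)
  nn <- 0L
  stack <- vector("list", 4096L)
  sp <- 1L
  stack[[1L]] <- root
  while (sp > 0L) {
    nd <- stack[[sp]]
    sp <- sp - 1L
    if (identical(nd$stamp, stamp)) next
    nd$stamp <- stamp
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) {
      if (is.environment(p) && p$track && !identical(p$stamp, stamp)) {
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, 0), decreasing = TRUE)
  root$grad <- matrix(1, 1L, 1L)
  for (nd in nodes[ord]) {
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (is.environment(p) && p$track && !is.null(gs[[i]])) {
        p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
      }
    }
  }
  invisible(NULL)
}

tg_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
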