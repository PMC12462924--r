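# Adam optimizer over a flat named list of tg_param tensors.

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) p$v * 0),
    u = lapply(params, function(p) p$v * 0),
    t = 0L
  )
}

adam_step <- function(params, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$u[[nm]] <- beta2 * state$u[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    uhat <- state$u[[nm]] / bc2
    p$v <- p$v - lr * (mhat / (sqrt(uhat) + eps) + weight_decay * p$v)
  }
  state
}

# Glorot-uniform initialization for a (fan_in x fan_out) weight matrix.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros <- function(nr, nc = 1L) matrix(0, nr, nc)
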