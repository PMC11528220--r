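# Recurrent-network primitives for the sequential variational autoencoder:
# GRU cells with hand-derived backpropagation-through-time, parameter
# flattening utilities, and an Adam optimizer. Gradients are validated
# against a central-difference oracle in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# GRU parameters; column blocks of Wx/Wh are [reset | update | candidate]
gru_init <- function(n_in, n_hidden) {
  list(Wx = matrix(stats::rnorm(n_in * 3 * n_hidden,
                                sd = if (n_in > 0) 1 / sqrt(n_in) else 0),
                   n_in, 3 * n_hidden),
       Wh = matrix(stats::rnorm(n_hidden * 3 * n_hidden,
                                sd = 1 / sqrt(n_hidden)),
                   n_hidden, 3 * n_hidden),
       b = rep(0, 3 * n_hidden))
}

# One GRU step. X: B x n_in (may have zero columns), Hprev: B x H.
gru_step <- function(p, X, Hprev) {
  H <- ncol(Hprev)
  A <- X %*% p$Wx + matrix(p$b, nrow(X), 3 * H, byrow = TRUE)
  Ah <- Hprev %*% p$Wh
  i1 <- seq_len(H); i2 <- i1 + H; i3 <- i2 + H
  r <- sigmoid(A[, i1, drop = FALSE] + Ah[, i1, drop = FALSE])
  z <- sigmoid(A[, i2, drop = FALSE] + Ah[, i2, drop = FALSE])
  Ahn <- Ah[, i3, drop = FALSE]
  n <- tanh(A[, i3, drop = FALSE] + r * Ahn)
  Hnew <- (1 - z) * n + z * Hprev
  list(H = Hnew, cache = list(X = X, Hprev = Hprev, r = r, z = z, n = n,
                              Ahn = Ahn))
}

# Backward through one GRU step; accumulates into the grad list `g`
# (same shape as p) and returns list(dX, dHprev, g).
gru_step_backward <- function(p, cache, dH, g) {
  r <- cache$r; z <- cache$z; n <- cache$n
  dz <- dH * (cache$Hprev - n)
  dn <- dH * (1 - z)
  dHprev <- dH * z
  dpre_n <- dn * (1 - n^2)
  dr <- dpre_n * cache$Ahn
  dAh_n <- dpre_n * r
  dpre_r <- dr * r * (1 - r)
  dpre_z <- dz * z * (1 - z)
  dA <- cbind(dpre_r, dpre_z, dpre_n)
  dAh <- cbind(dpre_r, dpre_z, dAh_n)
  g$Wx <- g$Wx + crossprod(cache$X, dA)
  g$b <- g$b + colSums(dA)
  g$Wh <- g$Wh + crossprod(cache$Hprev, dAh)
  dX <- dA %*% t(p$Wx)
  dHprev <- dHprev + dAh %*% t(p$Wh)
  list(dX = dX, dHprev = dHprev, g = g)
}

zero_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  utils::relist(flat, skeleton)
}

adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, theta, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + state$eps), state = state)
}

clip_global_norm <- function(grad, max_norm) {
  nrm <- sqrt(sum(grad^2))
  if (is.finite(max_norm) && nrm > max_norm) grad * (max_norm / nrm) else grad
}
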