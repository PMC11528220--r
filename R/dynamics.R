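# Sequential variational autoencoder for neural population dynamics with
# Poisson emissions. The input stream is LFP band power p(t) (or binned
# spike counts s(t)); the objective is always Poisson reconstruction of the
# spike counts, so an LFP-input model learns to estimate the firing rates
# underlying simultaneously recorded spiking. A bidirectional GRU encoder
# posits a Gaussian posterior over the generator's initial condition; an
# optional controller GRU posits per-step Gaussian inferred inputs u(t); the
# generator GRU evolves autonomously from the initial condition driven by
# u(t); factors are a linear readout of the generator state and per-channel
# rates are exponentiated linear readouts of the factors.

LOGVAR_CLAMP <- 8
LOGRATE_CLAMP <- 12

#' Dynamics model configuration
#'
#' Desk-scale defaults (encoder 48, generator 48, controller 24, 24-d
#' initial condition, 2 inferred inputs, 8 factors) are sized so that a
#' synthetic session trains on one CPU in minutes; larger architectures are
#' accepted via the same fields. The KL weights apply to a per-segment
#' summed Poisson NLL, hence their small scale: heavier weights collapse
#' the posteriors toward the prior on desk-scale data.
#'
#' @param input_kind `"lfp_power"` or `"spikes"`: what the encoder consumes.
#' @param n_in Input channel count.
#' @param n_out Spiking channel count (the reconstruction target).
#' @param encoder_dim,generator_dim,controller_dim GRU hidden sizes.
#' @param ic_dim Initial-condition latent dimensionality.
#' @param co_dim Inferred-input dimensionality per step; 0 disables the
#'   controller entirely (purely autonomous generator).
#' @param factor_dim Factor dimensionality (`<= generator_dim`).
#' @param kl_weight_ic,kl_weight_co Final KL weights; both ramp linearly
#'   from 0 over `kl_warmup_steps` training steps.
#' @param kl_warmup_steps Linear KL warm-up length in steps.
#' @param l2_gen,l2_con L2 penalties on the recurrent (hidden-to-hidden)
#'   weights of the generator and controller.
#' @param dropout Input dropout probability during training.
#' @param learning_rate,lr_decay Adam learning rate and per-epoch decay.
#' @param batch_size,max_epochs Minibatch size and training length.
#' @param valid_frac Fraction of segments held out for validation (seeded
#'   shuffle); best-validation weights are returned.
#' @param jitter_bins Spike-jitter augmentation range (spikes input only):
#'   each input spike is independently displaced by an integer offset
#'   uniform in `[-jitter_bins, jitter_bins]` on every training step.
#' @param clip_norm Global gradient-norm clip.
#' @param cell Recurrent cell type; `"gru"` (the only implemented cell,
#'   matching the model family this architecture descends from).
#' @param seed Seed for initialization, data split, and training noise.
#' @return A `model_config` list.
#' @export
model_config <- function(input_kind = c("lfp_power", "spikes"),
                         n_in, n_out,
                         encoder_dim = 48, generator_dim = 48,
                         controller_dim = 24, ic_dim = 24, co_dim = 2,
                         factor_dim = 8,
                         kl_weight_ic = 0.05, kl_weight_co = 0.05,
                         kl_warmup_steps = 100,
                         l2_gen = 1e-4, l2_con = 1e-4,
                         dropout = 0.05,
                         learning_rate = 1e-2, lr_decay = 0.999,
                         batch_size = 64, max_epochs = 150,
                         valid_frac = 0.2, jitter_bins = 2,
                         clip_norm = 200, cell = "gru", seed = 0) {
  input_kind <- match.arg(input_kind)
  cell <- match.arg(cell, "gru")
  cfg <- as.list(environment())
  dims <- c(n_in = n_in, n_out = n_out, encoder_dim = encoder_dim,
            generator_dim = generator_dim, ic_dim = ic_dim,
            factor_dim = factor_dim)
  if (any(dims <= 0)) {
    stop("model_config: dimensions must be positive (",
         paste(names(dims)[dims <= 0], collapse = ", "), ")")
  }
  if (co_dim < 0) stop("model_config: co_dim must be >= 0")
  if (co_dim > 0 && controller_dim <= 0) {
    stop("model_config: controller_dim must be positive when co_dim > 0")
  }
  if (factor_dim > generator_dim) {
    stop("model_config: factor_dim must be <= generator_dim")
  }
  if (dropout < 0 || dropout >= 1) stop("model_config: dropout in [0, 1)")
  structure(cfg, class = "model_config")
}

#' Build an untrained dynamics model
#'
#' Allocates and seeds all parameters: bidirectional encoder GRUs, linear
#' readouts to the initial-condition posterior, the optional controller GRU
#' with its inferred-input posterior readouts, the generator GRU, the factor
#' readout, and the exponential rate readout. With `co_dim = 0` no
#' controller parameters exist.
#'
#' @param cfg A [model_config()].
#' @return A `dynamics_model` (config + parameters).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  E <- cfg$encoder_dim; G <- cfg$generator_dim; Fd <- cfg$factor_dim
  cc <- cfg$co_dim
  with_local_seed(cfg$seed, {
    p <- list(
      enc_f = gru_init(cfg$n_in, E),
      enc_b = gru_init(cfg$n_in, E),
      W_icm = matrix(stats::rnorm(2 * E * cfg$ic_dim, sd = 1 / sqrt(2 * E)),
                     2 * E, cfg$ic_dim),
      b_icm = rep(0, cfg$ic_dim),
      W_icv = matrix(stats::rnorm(2 * E * cfg$ic_dim, sd = 1 / sqrt(2 * E)),
                     2 * E, cfg$ic_dim),
      b_icv = rep(-3, cfg$ic_dim),
      W_g0 = matrix(stats::rnorm(cfg$ic_dim * G, sd = 1 / sqrt(cfg$ic_dim)),
                    cfg$ic_dim, G),
      b_g0 = rep(0, G),
      gen = gru_init(cc, G),
      W_fac = matrix(stats::rnorm(G * Fd, sd = 1 / sqrt(G)), G, Fd),
      W_rate = matrix(stats::rnorm(Fd * cfg$n_out, sd = 1 / sqrt(Fd)),
                      Fd, cfg$n_out),
      b_rate = rep(0, cfg$n_out))
    if (cc > 0) {
      Cd <- cfg$controller_dim
      p$con <- gru_init(2 * E + Fd, Cd)
      p$W_com <- matrix(stats::rnorm(Cd * cc, sd = 1 / sqrt(Cd)), Cd, cc)
      p$b_com <- rep(0, cc)
      p$W_cov <- matrix(stats::rnorm(Cd * cc, sd = 1 / sqrt(Cd)), Cd, cc)
      p$b_cov <- rep(-3, cc)
    }
    structure(list(cfg = cfg, params = p, trained = FALSE, history = NULL),
              class = "dynamics_model")
  })
}

#' @export
print.dynamics_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<dynamics_model:%s> in %d ch -> out %d ch | enc %d, ",
                     "gen %d, ic %d, co %d, factors %d | %s\n"),
              cfg$input_kind, cfg$n_in, cfg$n_out, cfg$encoder_dim,
              cfg$generator_dim, cfg$ic_dim, cfg$co_dim, cfg$factor_dim,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

slice_t <- function(X, t) {
  matrix(X[, , t], dim(X)[1], dim(X)[2])
}

clamp_cached <- function(x, lim) {
  v <- pmin(pmax(x, -lim), lim)
  list(v = v, mask = (x > -lim & x < lim) * 1)
}

#' Poisson negative log likelihood
#'
#' `sum(lambda - s * log(lambda) + log(s!))` over all entries, so the value
#' is a true negative log likelihood (minimized at `lambda = s`).
#'
#' @param rates Positive matrix/array of rates (spikes/bin), or a
#'   [binned_features()] of kind `rates`.
#' @param counts Non-negative integer matrix/array of the same shape, or a
#'   [binned_features()] of kind `spike_counts`.
#' @return Scalar loss.
#' @export
poisson_nll <- function(rates, counts) {
  if (inherits(rates, "binned_features")) rates <- rates$values
  if (inherits(counts, "binned_features")) counts <- counts$values
  if (!identical(dim(rates), dim(counts)) &&
      length(rates) != length(counts)) {
    stop("poisson_nll: shape mismatch")
  }
  if (any(rates <= 0)) stop("poisson_nll: rates must be strictly positive")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("poisson_nll: counts must be non-negative integers")
  }
  sum(rates - counts * log(rates) + lgamma(counts + 1))
}

# ---- segmentation ----------------------------------------------------------

#' Segment a continuous session into overlapping training windows
#'
#' Windows of `window_ms` start at the session origin and step by
#' `window_ms - overlap_ms`; a final partial window is dropped. Input and
#' target (when given) are segmented identically.
#'
#' @param x Input [binned_features()].
#' @param target Optional target [binned_features()] (spike counts) on the
#'   same clock and bin count.
#' @param window_ms Window length (default 1000 ms).
#' @param overlap_ms Overlap between consecutive windows (200 ms for
#'   center-out-style sessions, 350 ms for less structured ones).
#' @return A `segment_set`: arrays `input` (and `target`) of shape
#'   segment x channel x bin, plus start bins and window geometry.
#' @export
segment_continuous <- function(x, target = NULL, window_ms = 1000,
                               overlap_ms = 200) {
  stopifnot(inherits(x, "binned_features"))
  if (overlap_ms >= window_ms) {
    stop("segment_continuous: overlap must be smaller than the window")
  }
  wb <- round(window_ms / x$bin_ms)
  step <- round((window_ms - overlap_ms) / x$bin_ms)
  nb <- ncol(x$values)
  if (nb < wb) stop("segment_continuous: session shorter than one window")
  starts <- seq(0L, nb - wb, by = step) # 0-based start bins
  n_seg <- length(starts)
  seg_of <- function(values) {
    arr <- array(0, dim = c(n_seg, nrow(values), wb))
    for (s in seq_len(n_seg)) {
      arr[s, , ] <- values[, (starts[s] + 1L):(starts[s] + wb), drop = FALSE]
    }
    arr
  }
  tgt <- NULL
  if (!is.null(target)) {
    stopifnot(inherits(target, "binned_features"))
    if (ncol(target$values) != nb || target$bin_ms != x$bin_ms) {
      stop("segment_continuous: target must share the input's bin clock")
    }
    tgt <- seg_of(target$values)
  }
  structure(list(input = seg_of(x$values), target = tgt,
                 starts_bin = starts, window_bins = wb, step_bins = step,
                 bin_ms = x$bin_ms, t0_ms = x$t0_ms,
                 input_kind = x$kind,
                 target_channel_ids = if (!is.null(target))
                   target$channel_ids else NULL),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d ch x %d bins (step %d bins%s)\n",
              dim(x$input)[1], dim(x$input)[2], x$window_bins, x$step_bins,
              if (!is.null(x$target)) ", with target" else ""))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# Full forward pass over one batch.
# X: B x n_in x T input array; S: B x n_out x T counts (or NULL).
# sample: draw posterior samples (training) vs posterior means (inference).
# Returns loss components, per-step outputs and (optionally) the cache
# needed by model_backward.
model_forward <- function(p, cfg, X, S = NULL, sample = FALSE,
                          kl_ic_w = cfg$kl_weight_ic,
                          kl_co_w = cfg$kl_weight_co,
                          need_cache = FALSE) {
  B <- dim(X)[1]; T <- dim(X)[3]
  E <- cfg$encoder_dim; G <- cfg$generator_dim; Fd <- cfg$factor_dim
  cc <- cfg$co_dim
  i1E <- seq_len(E); i2E <- i1E + E

  hf <- vector("list", T); hb <- vector("list", T)
  cache_f <- vector("list", T); cache_b <- vector("list", T)
  h <- matrix(0, B, E)
  for (t in seq_len(T)) {
    st <- gru_step(p$enc_f, slice_t(X, t), h)
    h <- st$H; hf[[t]] <- h; cache_f[[t]] <- st$cache
  }
  h <- matrix(0, B, E)
  for (t in rev(seq_len(T))) {
    st <- gru_step(p$enc_b, slice_t(X, t), h)
    h <- st$H; hb[[t]] <- h; cache_b[[t]] <- st$cache
  }

  icin <- cbind(hf[[T]], hb[[1]])
  ic_mean <- icin %*% p$W_icm + matrix(p$b_icm, B, cfg$ic_dim, byrow = TRUE)
  lv_raw <- icin %*% p$W_icv + matrix(p$b_icv, B, cfg$ic_dim, byrow = TRUE)
  lv_ic <- clamp_cached(lv_raw, LOGVAR_CLAMP)
  eps_ic <- if (sample) matrix(stats::rnorm(B * cfg$ic_dim), B, cfg$ic_dim)
            else matrix(0, B, cfg$ic_dim)
  ic <- ic_mean + exp(0.5 * lv_ic$v) * eps_ic
  g0 <- tanh(ic %*% p$W_g0 + matrix(p$b_g0, B, G, byrow = TRUE))
  f0 <- g0 %*% p$W_fac

  gstate <- vector("list", T); fac <- vector("list", T)
  logr <- vector("list", T); rate_mask <- vector("list", T)
  cache_gen <- vector("list", T)
  cstate <- vector("list", T); cache_con <- vector("list", T)
  co_mean <- vector("list", T); lv_co <- vector("list", T)
  eps_co <- vector("list", T); u_all <- vector("list", T)

  g_prev <- g0; f_prev <- f0
  c_prev <- if (cc > 0) matrix(0, B, cfg$controller_dim) else NULL
  kl_co <- 0
  for (t in seq_len(T)) {
    if (cc > 0) {
      con_in <- cbind(hf[[t]], hb[[t]], f_prev)
      st <- gru_step(p$con, con_in, c_prev)
      c_prev <- st$H; cstate[[t]] <- c_prev; cache_con[[t]] <- st$cache
      mu <- c_prev %*% p$W_com + matrix(p$b_com, B, cc, byrow = TRUE)
      lvr <- c_prev %*% p$W_cov + matrix(p$b_cov, B, cc, byrow = TRUE)
      lv <- clamp_cached(lvr, LOGVAR_CLAMP)
      ep <- if (sample) matrix(stats::rnorm(B * cc), B, cc)
            else matrix(0, B, cc)
      u <- mu + exp(0.5 * lv$v) * ep
      co_mean[[t]] <- mu; lv_co[[t]] <- lv; eps_co[[t]] <- ep
      kl_co <- kl_co + 0.5 * sum(mu^2 + exp(lv$v) - 1 - lv$v)
    } else {
      u <- matrix(0, B, 0)
    }
    u_all[[t]] <- u
    st <- gru_step(p$gen, u, g_prev)
    g_prev <- st$H; gstate[[t]] <- g_prev; cache_gen[[t]] <- st$cache
    f_prev <- g_prev %*% p$W_fac
    fac[[t]] <- f_prev
    lr_raw <- f_prev %*% p$W_rate + matrix(p$b_rate, B, cfg$n_out,
                                           byrow = TRUE)
    cl <- clamp_cached(lr_raw, LOGRATE_CLAMP)
    logr[[t]] <- cl$v; rate_mask[[t]] <- cl$mask
  }

  kl_ic <- 0.5 * sum(ic_mean^2 + exp(lv_ic$v) - 1 - lv_ic$v)
  l2 <- 0.5 * (cfg$l2_gen * sum(p$gen$Wh^2) +
                 if (cc > 0) cfg$l2_con * sum(p$con$Wh^2) else 0)
  recon <- NA_real_
  if (!is.null(S)) {
    recon <- 0
    for (t in seq_len(T)) {
      lam <- exp(logr[[t]])
      recon <- recon + sum(lam - slice_t(S, t) * logr[[t]] +
                             lgamma(slice_t(S, t) + 1))
    }
    recon <- recon / B
  }
  loss <- if (!is.null(S)) {
    recon + kl_ic_w * kl_ic / B + kl_co_w * kl_co / B + l2
  } else NA_real_

  out <- list(loss = loss, recon = recon, kl_ic = kl_ic / B,
              kl_co = kl_co / B, l2 = l2,
              logr = logr, factors = fac, co_mean = co_mean,
              ic_mean = ic_mean, ic_logvar = lv_ic$v)
  if (need_cache) {
    out$cache <- list(X = X, hf = hf, hb = hb, cache_f = cache_f,
                      cache_b = cache_b, icin = icin, ic_mean = ic_mean,
                      lv_ic = lv_ic, eps_ic = eps_ic, ic = ic, g0 = g0,
                      f0 = f0, gstate = gstate, fac = fac, logr = logr,
                      rate_mask = rate_mask, cache_gen = cache_gen,
                      cstate = cstate, cache_con = cache_con,
                      co_mean = co_mean, lv_co = lv_co, eps_co = eps_co,
                      u_all = u_all)
  }
  out
}

# Backpropagation through the full model; mirrors model_forward exactly.
model_backward <- function(p, cfg, cache, S, kl_ic_w, kl_co_w) {
  B <- dim(S)[1]; T <- dim(S)[3]
  E <- cfg$encoder_dim; G <- cfg$generator_dim; Fd <- cfg$factor_dim
  cc <- cfg$co_dim
  g <- zero_like(p)

  df <- vector("list", T)
  for (t in seq_len(T)) {
    dlogr <- (exp(cache$logr[[t]]) - slice_t(S, t)) / B * cache$rate_mask[[t]]
    g$W_rate <- g$W_rate + crossprod(cache$fac[[t]], dlogr)
    g$b_rate <- g$b_rate + colSums(dlogr)
    df[[t]] <- dlogr %*% t(p$W_rate)
  }

  dg_next <- matrix(0, B, G)
  dc_next <- if (cc > 0) matrix(0, B, cfg$controller_dim) else NULL
  dfac_carry <- matrix(0, B, Fd)
  de <- vector("list", T)
  for (t in seq_len(T)) de[[t]] <- matrix(0, B, 2 * E)

  for (t in rev(seq_len(T))) {
    df_tot <- df[[t]] + dfac_carry
    g$W_fac <- g$W_fac + crossprod(cache$gstate[[t]], df_tot)
    dg <- df_tot %*% t(p$W_fac) + dg_next
    bk <- gru_step_backward(p$gen, cache$cache_gen[[t]], dg, g$gen)
    g$gen <- bk$g
    dg_next <- bk$dHprev
    du <- bk$dX
    if (cc > 0) {
      lv <- cache$lv_co[[t]]
      dmu <- du + kl_co_w * cache$co_mean[[t]] / B
      dlv <- (du * cache$eps_co[[t]] * 0.5 * exp(0.5 * lv$v) +
                kl_co_w * 0.5 * (exp(lv$v) - 1) / B) * lv$mask
      g$W_com <- g$W_com + crossprod(cache$cstate[[t]], dmu)
      g$b_com <- g$b_com + colSums(dmu)
      g$W_cov <- g$W_cov + crossprod(cache$cstate[[t]], dlv)
      g$b_cov <- g$b_cov + colSums(dlv)
      dc <- dmu %*% t(p$W_com) + dlv %*% t(p$W_cov) + dc_next
      bk <- gru_step_backward(p$con, cache$cache_con[[t]], dc, g$con)
      g$con <- bk$g
      dc_next <- bk$dHprev
      de[[t]] <- de[[t]] + bk$dX[, seq_len(2 * E), drop = FALSE]
      dfac_carry <- bk$dX[, 2 * E + seq_len(Fd), drop = FALSE]
    } else {
      dfac_carry <- matrix(0, B, Fd)
    }
  }

  # initial factors f0 = g0 W_fac feed the controller at t = 1
  g$W_fac <- g$W_fac + crossprod(cache$g0, dfac_carry)
  dg0 <- dfac_carry %*% t(p$W_fac) + dg_next
  dg0pre <- dg0 * (1 - cache$g0^2)
  g$W_g0 <- g$W_g0 + crossprod(cache$ic, dg0pre)
  g$b_g0 <- g$b_g0 + colSums(dg0pre)
  dic <- dg0pre %*% t(p$W_g0)
  lv <- cache$lv_ic
  dmu_ic <- dic + kl_ic_w * cache$ic_mean / B
  dlv_ic <- (dic * cache$eps_ic * 0.5 * exp(0.5 * lv$v) +
               kl_ic_w * 0.5 * (exp(lv$v) - 1) / B) * lv$mask
  g$W_icm <- g$W_icm + crossprod(cache$icin, dmu_ic)
  g$b_icm <- g$b_icm + colSums(dmu_ic)
  g$W_icv <- g$W_icv + crossprod(cache$icin, dlv_ic)
  g$b_icv <- g$b_icv + colSums(dlv_ic)
  dicin <- dmu_ic %*% t(p$W_icm) + dlv_ic %*% t(p$W_icv)

  # encoder, forward direction (receives the t = T slice of dicin)
  dh <- matrix(0, B, E)
  for (t in rev(seq_len(T))) {
    dh <- dh + de[[t]][, seq_len(E), drop = FALSE]
    if (t == length(de)) dh <- dh + dicin[, seq_len(E), drop = FALSE]
    bk <- gru_step_backward(p$enc_f, cache$cache_f[[t]], dh, g$enc_f)
    g$enc_f <- bk$g
    dh <- bk$dHprev
  }
  # encoder, backward direction (receives the t = 1 slice)
  dh <- matrix(0, B, E)
  for (t in seq_len(T)) {
    dh <- dh + de[[t]][, E + seq_len(E), drop = FALSE]
    if (t == 1L) dh <- dh + dicin[, E + seq_len(E), drop = FALSE]
    bk <- gru_step_backward(p$enc_b, cache$cache_b[[t]], dh, g$enc_b)
    g$enc_b <- bk$g
    dh <- bk$dHprev
  }

  g$gen$Wh <- g$gen$Wh + cfg$l2_gen * p$gen$Wh
  if (cc > 0) g$con$Wh <- g$con$Wh + cfg$l2_con * p$con$Wh
  g
}

# ---- compiled fast path ----------------------------------------------------

# Posterior-sampling noise in the exact order the reference implementation
# draws it (initial condition first, then inferred inputs per step).
model_eps <- function(cfg, B, T, sample) {
  cc <- cfg$co_dim
  if (sample) {
    ic <- matrix(stats::rnorm(B * cfg$ic_dim), B, cfg$ic_dim)
    co <- if (cc > 0) {
      array(stats::rnorm(B * cc * T), c(B, cc, T))
    } else array(0, c(B, 0, T))
  } else {
    ic <- matrix(0, B, cfg$ic_dim)
    co <- array(0, c(B, if (cc > 0) cc else 0, T))
  }
  list(ic = ic, co = co)
}

# Single entry point to the compiled forward/backward core. The pure-R
# implementation above (model_forward/model_backward) is retained as the
# reference the test suite checks this path against.
model_core <- function(p, cfg, X, S = NULL, sample = FALSE,
                       kl_ic_w = cfg$kl_weight_ic,
                       kl_co_w = cfg$kl_weight_co,
                       want_grad = FALSE, want_outputs = FALSE, eps = NULL) {
  B <- dim(X)[1]; T <- dim(X)[3]
  if (is.null(eps)) eps <- model_eps(cfg, B, T, sample)
  dims <- list(encoder_dim = cfg$encoder_dim,
               generator_dim = cfg$generator_dim,
               controller_dim = if (cfg$co_dim > 0) cfg$controller_dim else 0L,
               factor_dim = cfg$factor_dim, co_dim = cfg$co_dim,
               ic_dim = cfg$ic_dim, n_out = cfg$n_out)
  Sc <- if (is.null(S)) array(0, c(0, 0, 0)) else S
  vae_core(p, dims, X, Sc, eps$ic, eps$co, kl_ic_w, kl_co_w,
           cfg$l2_gen, cfg$l2_con, want_grad, want_outputs)
}

# ---- training --------------------------------------------------------------

# Multinomially redistribute each input spike by an integer offset uniform
# on [-jitter, jitter]; spikes shifted past the window edges are dropped.
jitter_spikes <- function(X, jitter) {
  if (jitter == 0) return(X)
  T <- dim(X)[3]
  offsets <- (-jitter):jitter
  out <- X * 0
  remaining <- X
  n_left <- length(offsets)
  for (d in offsets) {
    take <- array(stats::rbinom(length(remaining), size = remaining,
                                prob = 1 / n_left),
                  dim = dim(remaining))
    n_left <- n_left - 1
    src <- seq_len(T)
    dst <- src + d
    ok <- dst >= 1 & dst <= T
    out[, , dst[ok]] <- out[, , dst[ok], drop = FALSE] +
      take[, , src[ok], drop = FALSE]
    remaining <- remaining - take
  }
  out
}

#' Train a dynamics model on segmented session data
#'
#' Stochastic-gradient training (Adam) of the evidence lower bound: Poisson
#' reconstruction of the spike counts plus KL terms with linear warm-up and
#' L2 penalties on the recurrent weights. A seeded shuffle holds out
#' `valid_frac` of the segments; the weights with the best validation loss
#' (evaluated with posterior means and full KL weights) are returned. With
#' spike input, the spike-jitter augmentation is re-drawn on every training
#' step and applied to the model input only, never the target.
#'
#' @param model A [build_model()] result.
#' @param segments A [segment_set()][segment_continuous()] whose `target`
#'   holds spike counts; `input` must match the model's `input_kind`.
#' @param verbose Print a line every 10 epochs?
#' @return The trained `dynamics_model`, with `history` (per-epoch train and
#'   validation losses) attached.
#' @export
train_dynamics <- function(model, segments, verbose = FALSE) {
  stopifnot(inherits(model, "dynamics_model"),
            inherits(segments, "segment_set"))
  cfg <- model$cfg
  if (is.null(segments$target)) {
    stop("train_dynamics: segments must carry a spike-count target")
  }
  X_all <- segments$input
  S_all <- segments$target
  if (dim(X_all)[2] != cfg$n_in) {
    stop("train_dynamics: input has ", dim(X_all)[2], " channels, config ",
         "expects ", cfg$n_in)
  }
  if (dim(S_all)[2] != cfg$n_out) {
    stop("train_dynamics: target has ", dim(S_all)[2], " channels, config ",
         "expects ", cfg$n_out)
  }
  if (any(S_all < 0) || any(S_all != round(S_all))) {
    stop("train_dynamics: target must be non-negative integer counts")
  }
  n_seg <- dim(X_all)[1]

  with_local_seed(cfg$seed + 1, {
    p <- model$params
    # rate bias initialized at the log mean count so training starts near
    # the homogeneous-Poisson solution
    p$b_rate <- log(pmax(apply(S_all, 2, mean), 1e-3))

    perm <- sample.int(n_seg)
    n_val <- max(1L, round(cfg$valid_frac * n_seg))
    if (n_val >= n_seg) stop("train_dynamics: too few segments to split")
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]

    theta <- flatten_params(p)
    opt <- adam_init(length(theta))
    lr <- cfg$learning_rate
    step <- 0L
    best_val <- Inf
    best_theta <- theta
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_recon = numeric(0))
    Xval <- X_all[val_idx, , , drop = FALSE]
    Sval <- S_all[val_idx, , , drop = FALSE]

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0
      for (b in batches) {
        step <- step + 1L
        warm <- min(1, step / max(1, cfg$kl_warmup_steps))
        Xb <- X_all[b, , , drop = FALSE]
        if (cfg$input_kind == "spikes" && cfg$jitter_bins > 0) {
          Xb <- jitter_spikes(Xb, cfg$jitter_bins)
        }
        if (cfg$dropout > 0) {
          mask <- array(stats::rbinom(length(Xb), 1, 1 - cfg$dropout),
                        dim = dim(Xb)) / (1 - cfg$dropout)
          Xb <- Xb * mask
        }
        Sb <- S_all[b, , , drop = FALSE]
        p <- unflatten_params(theta, p)
        fw <- model_core(p, cfg, Xb, Sb, sample = TRUE,
                         kl_ic_w = warm * cfg$kl_weight_ic,
                         kl_co_w = warm * cfg$kl_weight_co,
                         want_grad = TRUE)
        if (!is.finite(fw$loss)) {
          stop("train_dynamics: non-finite loss at step ", step,
               " (epoch ", epoch, "); try a lower learning rate")
        }
        gflat <- clip_global_norm(unlist(fw$grads, use.names = FALSE),
                                  cfg$clip_norm)
        upd <- adam_step(opt, theta, gflat, lr)
        theta <- upd$theta
        opt <- upd$state
        ep_loss <- ep_loss + fw$loss * length(b)
      }
      ep_loss <- ep_loss / length(ord)
      p <- unflatten_params(theta, p)
      vl <- model_core(p, cfg, Xval, Sval, sample = FALSE)
      # the validation ELBO is only comparable across epochs once the KL
      # warm-up has finished (it is always evaluated at full weight)
      if (vl$loss < best_val &&
          (step >= cfg$kl_warmup_steps || epoch == cfg$max_epochs)) {
        best_val <- vl$loss
        best_theta <- theta
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vl$loss,
                                     val_recon = vl$recon))
      if (verbose && epoch %% 10 == 0) {
        message(sprintf("epoch %3d  train %.3f  val %.3f", epoch, ep_loss,
                        vl$loss))
      }
      lr <- lr * cfg$lr_decay
    }
    model$params <- unflatten_params(best_theta, p)
    model$trained <- TRUE
    model$history <- hist
    model$val_loss <- best_val
    model
  })
}

# ---- inference -------------------------------------------------------------

make_posterior_output <- function(rates_mat, fac_mat, co_mat, ic_mean,
                                  ic_logvar, bin_ms, t0_ms, channel_ids) {
  structure(list(
    rates = binned_features(rates_mat, bin_ms, "rates", t0_ms = t0_ms,
                            channel_ids = channel_ids),
    factors = fac_mat, co = co_mat,
    ic_mean = ic_mean, ic_logvar = ic_logvar),
    class = "posterior_output")
}

#' Causal sliding-window inference
#'
#' Streams the trained model over a continuous input: for each bin `t` from
#' the first full window onward, the model runs on the trailing
#' `window_ms` of input ending at `t` using posterior means (no sampling),
#' and only the final bin's rates and factors are emitted. Outputs at bin
#' `t` therefore depend only on input bins `<= t`. The first emitted bin is
#' the last bin of the first full window.
#'
#' @param model A trained `dynamics_model`.
#' @param stream A [binned_features()] matching the model's input kind.
#' @param window_ms Trailing-window length (default 1000 ms).
#' @param batch_size Number of windows evaluated per forward pass.
#' @return A `posterior_output`: `rates` (a [binned_features()] starting at
#'   the first emitted bin), `factors`, `co`, and per-window
#'   initial-condition posterior moments.
#' @export
infer_causal <- function(model, stream, window_ms = 1000, batch_size = 256) {
  stopifnot(inherits(model, "dynamics_model"),
            inherits(stream, "binned_features"))
  cfg <- model$cfg
  v <- stream$values
  wb <- round(window_ms / stream$bin_ms)
  N <- ncol(v)
  if (N < wb) stop("infer_causal: stream shorter than one window")
  ends <- wb:N
  n_emit <- length(ends)
  rates <- matrix(0, cfg$n_out, n_emit)
  facs <- matrix(0, cfg$factor_dim, n_emit)
  cos <- matrix(0, max(cfg$co_dim, 1), n_emit)
  icm <- matrix(0, cfg$ic_dim, n_emit)
  for (chunk in split(seq_len(n_emit), ceiling(seq_len(n_emit) / batch_size))) {
    B <- length(chunk)
    X <- array(0, dim = c(B, cfg$n_in, wb))
    for (j in seq_along(chunk)) {
      e <- ends[chunk[j]]
      X[j, , ] <- v[, (e - wb + 1L):e, drop = FALSE]
    }
    fw <- model_core(model$params, cfg, X, sample = FALSE,
                     want_outputs = TRUE)
    rates[, chunk] <- t(exp(matrix(fw$logr[, , wb], B, cfg$n_out)))
    facs[, chunk] <- t(matrix(fw$factors[, , wb], B, cfg$factor_dim))
    if (cfg$co_dim > 0) {
      cos[, chunk] <- t(matrix(fw$co_mean[, , wb], B, cfg$co_dim))
    }
    icm[, chunk] <- t(fw$ic_mean)
  }
  make_posterior_output(rates, facs,
                        if (cfg$co_dim > 0) cos else NULL,
                        icm, NULL, stream$bin_ms,
                        stream$t0_ms + (wb - 1L) * stream$bin_ms,
                        paste0("rate", seq_len(cfg$n_out)))
}

#' Acausal inference over segmented data with overlap merging
#'
#' Runs full-window inference on every segment. With `n_samples = 1` the
#' posterior means are used deterministically; with more, rates and factors
#' are averaged over posterior samples. Overlapping windows are merged by
#' keeping, for each session bin, the value from the window in which that
#' bin has the most left context (ties to the earlier window) -- i.e. the
#' earliest window containing it.
#'
#' @param model A trained `dynamics_model`.
#' @param segments A `segment_set` of the model's input kind.
#' @param n_samples Posterior samples to average (1 = posterior means).
#' @param batch_size Segments per forward pass.
#' @return A `posterior_output` covering every bin spanned by a full window.
#' @export
infer_acausal <- function(model, segments, n_samples = 1, batch_size = 128) {
  stopifnot(inherits(model, "dynamics_model"),
            inherits(segments, "segment_set"))
  cfg <- model$cfg
  X_all <- segments$input
  n_seg <- dim(X_all)[1]
  wb <- segments$window_bins
  last_bin <- segments$starts_bin[n_seg] + wb # session bins covered (0-based
  first_bin <- segments$starts_bin[1]         # start, exclusive end)
  n_bins_out <- last_bin - first_bin
  rates <- matrix(NA_real_, cfg$n_out, n_bins_out)
  facs <- matrix(NA_real_, cfg$factor_dim, n_bins_out)
  filled <- rep(FALSE, n_bins_out)
  seg_rates <- array(0, dim = c(n_seg, cfg$n_out, wb))
  seg_facs <- array(0, dim = c(n_seg, cfg$factor_dim, wb))
  for (chunk in split(seq_len(n_seg), ceiling(seq_len(n_seg) / batch_size))) {
    Xb <- X_all[chunk, , , drop = FALSE]
    acc_r <- array(0, dim = c(length(chunk), cfg$n_out, wb))
    acc_f <- array(0, dim = c(length(chunk), cfg$factor_dim, wb))
    for (s in seq_len(n_samples)) {
      fw <- model_core(model$params, cfg, Xb, sample = n_samples > 1,
                       want_outputs = TRUE)
      acc_r <- acc_r + exp(fw$logr)
      acc_f <- acc_f + fw$factors
    }
    seg_rates[chunk, , ] <- acc_r / n_samples
    seg_facs[chunk, , ] <- acc_f / n_samples
  }
  for (s in seq_len(n_seg)) { # earlier windows claim their bins first
    sb <- segments$starts_bin[s] - first_bin
    idx <- (sb + 1L):(sb + wb)
    new <- !filled[idx]
    if (any(new)) {
      r_s <- matrix(seg_rates[s, , ], cfg$n_out, wb)
      f_s <- matrix(seg_facs[s, , ], cfg$factor_dim, wb)
      rates[, idx[new]] <- r_s[, new, drop = FALSE]
      facs[, idx[new]] <- f_s[, new, drop = FALSE]
      filled[idx[new]] <- TRUE
    }
  }
  make_posterior_output(rates, facs, NULL, NULL, NULL, segments$bin_ms,
                        segments$t0_ms + first_bin * segments$bin_ms,
                        paste0("rate", seq_len(cfg$n_out)))
}
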