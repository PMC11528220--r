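ns <- asNamespace("lfpdyn")

test_that("poisson NLL matches a term-by-term oracle and its MLE property", {
  withr::with_seed(20, {
    s <- matrix(rpois(12, 2), 3, 4)
    lam <- matrix(rexp(12) + 0.1, 3, 4)
  })
  oracle <- 0
  for (i in 1:3) for (j in 1:4) {
    oracle <- oracle + lam[i, j] - s[i, j] * log(lam[i, j]) +
      lgamma(s[i, j] + 1)
  }
  expect_equal(poisson_nll(lam, s), oracle, tolerance = 1e-12)
  # lambda = s is the per-entry minimum over lambda for each fixed s
  lam_mle <- pmax(s, 1e-12)
  base <- poisson_nll(lam_mle, s)
  for (f in c(0.7, 0.9, 1.1, 1.5)) {
    expect_gte(poisson_nll(pmax(s * f, 1e-12), s), base)
  }
  # s = 0, lambda = 1 contributes exactly 1 per entry
  expect_equal(poisson_nll(matrix(1, 2, 5), matrix(0, 2, 5)), 10)
  expect_error(poisson_nll(matrix(-1, 1, 1), matrix(0, 1, 1)), "positive")
})

test_that("segmentation arithmetic follows the window/overlap rules", {
  x <- binned_features(matrix(rnorm(250), 1, 250), 20, "lfp_power")
  s <- segment_continuous(x, window_ms = 1000, overlap_ms = 200)
  expect_equal(s$starts_bin, seq(0, 200, by = 40))
  expect_equal(dim(s$input), c(6, 1, 50))
  expect_equal(s$input[2, 1, ], x$values[1, 41:90])

  s0 <- segment_continuous(x, window_ms = 1000, overlap_ms = 0)
  expect_equal(s0$starts_bin, c(0, 50, 100, 150, 200))

  s350 <- segment_continuous(x, window_ms = 1000, overlap_ms = 350)
  expect_equal(s350$step_bins, round(650 / 20))

  expect_error(segment_continuous(x, window_ms = 1000, overlap_ms = 1000),
               "overlap")
  short <- binned_features(matrix(1, 1, 10), 20, "lfp_power")
  expect_error(segment_continuous(short), "shorter than one window")
})

test_that("analytic gradients match central differences", {
  for (co in c(2, 0)) {
    cfg <- tiny_model_config(co_dim = co)
    m <- build_model(cfg)
    withr::with_seed(21, {
      X <- array(rnorm(2 * cfg$n_in * 6), c(2, cfg$n_in, 6))
      S <- array(rpois(2 * cfg$n_out * 6, 0.5), c(2, cfg$n_out, 6))
    })
    loss_at <- function(theta) {
      p <- ns$unflatten_params(theta, m$params)
      set.seed(99)
      ns$model_forward(p, cfg, X, S, sample = TRUE,
                       kl_ic_w = 0.7, kl_co_w = 0.5)$loss
    }
    theta <- ns$flatten_params(m$params)
    set.seed(99)
    fw <- ns$model_forward(m$params, cfg, X, S, sample = TRUE,
                           kl_ic_w = 0.7, kl_co_w = 0.5, need_cache = TRUE)
    gr <- ns$model_backward(m$params, cfg, fw$cache, S,
                            kl_ic_w = 0.7, kl_co_w = 0.5)
    gflat <- ns$flatten_params(gr)
    withr::with_seed(22, idx <- sample(length(theta), 40))
    h <- 1e-5
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- theta[i] + h; l1 <- loss_at(tp)
      tp[i] <- theta[i] - h; (l1 - loss_at(tp)) / (2 * h)
    }, numeric(1))
    rel <- abs(num - gflat[idx]) / pmax(abs(num) + abs(gflat[idx]), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("the compiled core agrees with the reference implementation", {
  for (co in c(2, 0)) {
    cfg <- tiny_model_config(co_dim = co)
    m <- build_model(cfg)
    withr::with_seed(31, {
      X <- array(rnorm(3 * cfg$n_in * 7), c(3, cfg$n_in, 7))
      S <- array(rpois(3 * cfg$n_out * 7, 0.4), c(3, cfg$n_out, 7))
    })
    fwR <- ns$model_forward(m$params, cfg, X, S, sample = FALSE,
                            kl_ic_w = 0.7, kl_co_w = 0.5, need_cache = TRUE)
    fwC <- ns$model_core(m$params, cfg, X, S, sample = FALSE,
                         kl_ic_w = 0.7, kl_co_w = 0.5, want_grad = TRUE,
                         want_outputs = TRUE)
    expect_equal(fwC$loss, fwR$loss, tolerance = 1e-12)
    expect_equal(fwC$recon, fwR$recon, tolerance = 1e-12)
    expect_equal(fwC$kl_ic, fwR$kl_ic, tolerance = 1e-12)
    grR <- ns$model_backward(m$params, cfg, fwR$cache, S,
                             kl_ic_w = 0.7, kl_co_w = 0.5)
    expect_equal(unlist(fwC$grads, use.names = FALSE),
                 ns$flatten_params(grR), tolerance = 1e-12)
    for (t in c(1, 7)) {
      expect_equal(matrix(fwC$logr[, , t], 3, cfg$n_out), fwR$logr[[t]],
                   tolerance = 1e-12)
      expect_equal(matrix(fwC$factors[, , t], 3, cfg$factor_dim),
                   fwR$factors[[t]], tolerance = 1e-12)
    }
  }
})

test_that("the compiled gradients match central differences when sampling", {
  cfg <- tiny_model_config(co_dim = 2)
  m <- build_model(cfg)
  withr::with_seed(32, {
    X <- array(rnorm(2 * cfg$n_in * 6), c(2, cfg$n_in, 6))
    S <- array(rpois(2 * cfg$n_out * 6, 0.5), c(2, cfg$n_out, 6))
    eps <- ns$model_eps(cfg, 2, 6, sample = TRUE)
  })
  loss_at <- function(theta) {
    p <- ns$unflatten_params(theta, m$params)
    ns$model_core(p, cfg, X, S, kl_ic_w = 0.7, kl_co_w = 0.5, eps = eps)$loss
  }
  theta <- ns$flatten_params(m$params)
  fw <- ns$model_core(m$params, cfg, X, S, kl_ic_w = 0.7, kl_co_w = 0.5,
                      want_grad = TRUE, eps = eps)
  g <- unlist(fw$grads, use.names = FALSE)
  withr::with_seed(33, idx <- sample(length(theta), 30))
  h <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- theta[i] + h; l1 <- loss_at(tp)
    tp[i] <- theta[i] - h; (l1 - loss_at(tp)) / (2 * h)
  }, numeric(1))
  rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("model structure honors the configuration", {
  m0 <- build_model(tiny_model_config(co_dim = 0))
  expect_false(any(c("con", "W_com", "W_cov") %in% names(m0$params)))
  m2 <- build_model(tiny_model_config(co_dim = 2))
  expect_true(all(c("con", "W_com", "W_cov") %in% names(m2$params)))

  # forward pass on a 1-segment batch: positive rates of the right shape
  cfg <- tiny_model_config()
  X <- array(rnorm(cfg$n_in * 8), c(1, cfg$n_in, 8))
  fw <- ns$model_forward(m2$params, cfg, X, sample = FALSE)
  expect_length(fw$logr, 8)
  expect_equal(dim(fw$logr[[1]]), c(1L, cfg$n_out))
  expect_true(all(is.finite(exp(fw$logr[[8]]))) &&
                all(exp(fw$logr[[8]]) > 0))

  expect_error(model_config(input_kind = "lfp_power", n_in = 3, n_out = 4,
                            factor_dim = 100, generator_dim = 8),
               "factor_dim")
  expect_error(model_config(input_kind = "lfp_power", n_in = 3, n_out = 4,
                            co_dim = -1), "co_dim")
})

test_that("the ELBO dominates the reconstruction NLL (KL terms >= 0)", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  withr::with_seed(23, {
    X <- array(rnorm(3 * cfg$n_in * 6), c(3, cfg$n_in, 6))
    S <- array(rpois(3 * cfg$n_out * 6, 0.4), c(3, cfg$n_out, 6))
  })
  fw <- ns$model_forward(m$params, cfg, X, S, sample = TRUE,
                         kl_ic_w = 1, kl_co_w = 1)
  expect_gte(fw$loss - fw$l2, fw$recon)
  expect_gte(fw$kl_ic, 0)
  expect_gte(fw$kl_co, 0)
})

test_that("spike jitter conserves counts away from window edges", {
  withr::with_seed(24, {
    X <- array(0, c(3, 4, 20))
    X[, , 5:16] <- array(rpois(3 * 4 * 12, 0.8), c(3, 4, 12))
  })
  expect_identical(ns$jitter_spikes(X, 0), X)
  J <- ns$jitter_spikes(X, 2)
  expect_equal(sum(J), sum(X)) # interior spikes cannot fall off
  expect_true(all(J >= 0) && all(J == round(J)))
  expect_true(all(J[, , c(1:2, 19:20)] >= 0)) # may spill into the margins
  # edge spikes may be dropped, never created
  Xe <- array(0, c(1, 1, 4)); Xe[1, 1, 1] <- 10; Xe[1, 1, 4] <- 10
  Je <- ns$jitter_spikes(Xe, 2)
  expect_lte(sum(Je), 20)
})

test_that("training is deterministic and the loss decreases", {
  pp <- prep_session(0)
  segs <- prep_segments(0)
  sub <- segs
  sub$input <- segs$input[1:24, , ]
  sub$target <- segs$target[1:24, , ]
  sub$starts_bin <- segs$starts_bin[1:24]
  cfg <- model_config(input_kind = "lfp_power", n_in = 24,
                      n_out = dim(segs$target)[2],
                      encoder_dim = 16, generator_dim = 16,
                      controller_dim = 8, ic_dim = 8, co_dim = 2,
                      factor_dim = 4, batch_size = 12, max_epochs = 15,
                      kl_weight_ic = 0.05, kl_weight_co = 0.05,
                      learning_rate = 8e-3, seed = 1)
  m1 <- train_dynamics(build_model(cfg), sub)
  expect_lt(m1$history$train_loss[15], m1$history$train_loss[1])
  m2 <- train_dynamics(build_model(cfg), sub)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("causal inference never reads the future", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  withr::with_seed(25, v <- matrix(rnorm(cfg$n_in * 30), cfg$n_in, 30))
  stream <- binned_features(exp(v), 20, "lfp_power")
  win_ms <- 10 * 20
  out1 <- infer_causal(m, stream, window_ms = win_ms)
  # first emitted bin is the last bin of the first full window
  expect_equal(out1$rates$t0_ms, stream$t0_ms + 9 * 20)
  expect_equal(ncol(out1$rates$values), 30 - 10 + 1)
  v2 <- v
  v2[, 21:30] <- v2[, 21:30] + 5 # mutate strictly future bins
  out2 <- infer_causal(m, binned_features(exp(v2), 20, "lfp_power"),
                       window_ms = win_ms)
  # outputs up to bin 20 (emitted positions 1..11) are bit-identical
  expect_identical(out1$rates$values[, 1:11], out2$rates$values[, 1:11])
  expect_identical(out1$factors[, 1:11], out2$factors[, 1:11])
  expect_false(isTRUE(all.equal(out1$rates$values[, 12:21],
                                out2$rates$values[, 12:21])))
  expect_error(infer_causal(m, binned_features(matrix(1, cfg$n_in, 5), 20,
                                               "lfp_power"),
                            window_ms = win_ms), "shorter")
})

test_that("causal inference reaches a fixed point on stationary input", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  stream <- binned_features(matrix(1.3, cfg$n_in, 40), 20, "lfp_power")
  out <- infer_causal(m, stream, window_ms = 200)
  d <- abs(diff(t(out$rates$values)))
  expect_lt(max(d), 1e-12) # identical trailing windows -> identical output
})

test_that("acausal inference merges overlapping windows coherently", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  withr::with_seed(26, v <- exp(matrix(rnorm(cfg$n_in * 130), cfg$n_in, 130)))
  x <- binned_features(v, 20, "lfp_power")
  segs <- segment_continuous(x, window_ms = 1000, overlap_ms = 200)
  out <- infer_acausal(m, segs)
  # covered length: last start + window
  expect_equal(ncol(out$rates$values),
               segs$starts_bin[length(segs$starts_bin)] + 50)
  expect_true(all(is.finite(out$rates$values)))
  # n_samples = 1 is deterministic posterior-mean inference
  out_b <- infer_acausal(m, segs, n_samples = 1)
  expect_identical(out$rates$values, out_b$rates$values)
  # each bin comes from the earliest window containing it: the first 50
  # bins equal the first window's full-forward output
  fw <- ns$model_forward(m$params, cfg,
                         segs$input[1, , , drop = FALSE], sample = FALSE)
  first_win <- vapply(1:50, function(t) exp(fw$logr[[t]][1, ]),
                      numeric(cfg$n_out))
  expect_equal(out$rates$values[, 1:50], first_win, tolerance = 1e-12)
})

test_that("posterior-sample averages converge to the mean-pass output", {
  cfg <- tiny_model_config()
  m <- build_model(cfg)
  withr::with_seed(27, v <- exp(matrix(rnorm(cfg$n_in * 60), cfg$n_in, 60)))
  segs <- segment_continuous(binned_features(v, 20, "lfp_power"),
                             window_ms = 1000, overlap_ms = 0)
  mean_pass <- infer_acausal(m, segs, n_samples = 1)
  withr::with_seed(28, few <- infer_acausal(m, segs, n_samples = 2))
  withr::with_seed(29, many <- infer_acausal(m, segs, n_samples = 64))
  err_few <- mean(abs(few$rates$values - mean_pass$rates$values))
  err_many <- mean(abs(many$rates$values - mean_pass$rates$values))
  expect_lt(err_many, err_few) # Monte Carlo error shrinks with samples
  # a small persistent gap remains (Jensen: E[exp] >= exp(E))
  expect_lt(err_many / mean(mean_pass$rates$values), 0.15)
})
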