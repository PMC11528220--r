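test_that("design matrix layout matches the hand construction", {
  f <- matrix(c(1, 2, 3), 1, 3) # series a, b, c
  d <- build_design(f, history_bins = 1)
  expect_equal(d$X, rbind(c(2, 1, 1), c(3, 2, 1)))
  d0 <- build_design(matrix(1:6, 2, 3), history_bins = 0)
  expect_equal(d0$X[, 1:2], t(matrix(1:6, 2, 3)))
  expect_true(all(d0$X[, 3] == 1))
  dd <- build_design(matrix(rnorm(50), 5, 10), history_bins = 4)
  expect_equal(ncol(dd$X), 5 * 5 + 1)
  expect_error(build_design(matrix(1, 1, 3), history_bins = 4), "too few")
})

test_that("wiener fit interpolates, shrinks, and matches the augmented oracle", {
  withr::with_seed(10, {
    X <- cbind(matrix(rnorm(60), 30, 2), 1)
    W_true <- matrix(c(2, -1, 0.5), 3, 1)
    y <- X %*% W_true
  })
  dec <- fit_wiener(X, y, 0)
  expect_equal(dec$W, W_true, tolerance = 1e-10)
  expect_equal(predict_wiener(dec, X), y, tolerance = 1e-10)

  big <- fit_wiener(X, y, 1e10)
  expect_lt(max(abs(big$W[1:2, ])), 1e-6)
  expect_equal(predict_wiener(big, X)[1], mean(y), tolerance = 1e-4)

  withr::with_seed(11, {
    X2 <- cbind(matrix(rnorm(150), 30, 5), 1)
    y2 <- matrix(rnorm(60), 30, 2)
  })
  lam <- 37
  # independent oracle: least squares on rows augmented with sqrt(penalty)
  P <- diag(c(rep(sqrt(lam), 5), 0))
  Xa <- rbind(X2, P)
  ya <- rbind(y2, matrix(0, 6, 2))
  W_oracle <- qr.solve(Xa, ya)
  expect_equal(fit_wiener(X2, y2, lam)$W, W_oracle, tolerance = 1e-8)

  # literal R'R reading squares the constant
  expect_equal(fit_wiener(X2, y2, sqrt(lam), penalty = "rtr")$W, W_oracle,
               tolerance = 1e-8)
  expect_error(fit_wiener(cbind(X2[, 1], X2[, 1], 1), y2, 0), "singular")
})

test_that("variance-weighted R^2 follows the pooled formula", {
  withr::with_seed(12, {
    y <- cbind(rnorm(40, sd = 5), rnorm(40, sd = 0.5))
    yhat <- y + cbind(rnorm(40), rnorm(40, sd = 0.2))
  })
  expect_equal(variance_weighted_r2(y, y), 1)
  null <- matrix(colMeans(y), 40, 2, byrow = TRUE)
  expect_equal(variance_weighted_r2(y, null), 0)
  manual <- 1 - sum((yhat - y)^2) /
    (sum((y[, 1] - mean(y[, 1]))^2) + sum((y[, 2] - mean(y[, 2]))^2))
  expect_equal(variance_weighted_r2(y, yhat), manual)
  # invariant to adding a per-dimension constant to both
  shift <- matrix(c(3, -7), 40, 2, byrow = TRUE)
  expect_equal(variance_weighted_r2(y + shift, yhat + shift),
               variance_weighted_r2(y, yhat), tolerance = 1e-12)
  expect_error(variance_weighted_r2(matrix(1, 5, 1), matrix(1, 5, 1)),
               "zero total variance")
})

test_that("cross-validated decoding behaves at the extremes", {
  withr::with_seed(13, {
    f <- matrix(rnorm(3 * 300), 3, 300)
    W <- matrix(rnorm(6), 3, 2)
    y_lin <- t(f) %*% W + 5
    y_noise <- matrix(rnorm(600), 300, 2)
  })
  res <- cv_decode(f, y_lin, lam_grid = c(0.001, 1), k = 5)
  expect_gt(res$r2_holdout, 0.999)
  noise <- cv_decode(f, y_noise, lam_grid = c(1, 100), k = 5)
  expect_lt(noise$r2_holdout, 0.1)
  single <- cv_decode(f, y_lin, lam_grid = 10, k = 5)
  expect_equal(nrow(single$cv_table), 1L)
  expect_equal(single$best_lambda, 10)
  expect_error(cv_decode(matrix(1, 1, 20), matrix(1, 20, 1), k = 10),
               "too few rows")
})

test_that("PSTH R^2 is 1 at identity and 0 for the grand-mean predictor", {
  pp <- prep_session(0)
  sm <- gaussian_smooth(pp$spk, 30)
  ident <- psth_r2(sm, pp$spk, pp$trials, smooth_sd_ms = 30)
  expect_equal(ident$r2, 1, tolerance = 1e-12)

  al <- extract_aligned(gaussian_smooth(pp$spk, 30), pp$trials)
  gm <- apply(al$tensor, 2, mean) # grand mean per channel
  const <- binned_features(matrix(pmax(gm, 1e-9), length(gm),
                                  ncol(pp$spk$values)), 20, "rates")
  null <- psth_r2(const, pp$spk, pp$trials, smooth_sd_ms = 30)
  expect_lt(abs(null$r2), 0.05)
})

test_that("PSTH R^2 matches a brute-force recomputation from the tensors", {
  pp <- prep_session(0)
  res <- psth_r2(pp$truth_rates, pp$spk, pp$trials, smooth_sd_ms = 30)
  # independent recomputation straight from the aligned tensors
  sm <- gaussian_smooth(pp$spk, 30)
  ar <- extract_aligned(pp$truth_rates, pp$trials)
  as_ <- extract_aligned(sm, pp$trials)
  conds <- sort(unique(ar$condition))
  oracle <- vapply(seq_len(dim(ar$tensor)[2]), function(ch) {
    rate_cat <- ref_cat <- numeric(0)
    for (cd in conds) {
      rate_cat <- c(rate_cat,
                    colMeans(ar$tensor[ar$condition == cd, ch, ]))
      ref_cat <- c(ref_cat,
                   colMeans(as_$tensor[as_$condition == cd, ch, ]))
    }
    1 - sum((rate_cat - ref_cat)^2) / sum((ref_cat - mean(ref_cat))^2)
  }, numeric(1))
  expect_equal(res$per_channel, oracle, tolerance = 1e-12)
  expect_equal(res$r2, mean(oracle), tolerance = 1e-12)
  # the true rates beat chance against the empirical PSTHs; the ceiling is
  # set by Poisson noise in 12-trial condition averages at ~10 Hz
  expect_gt(res$r2, 0.2)
})

test_that("phoneme error rate is the normalized edit distance", {
  expect_equal(phoneme_error_rate(c("D", "AE", "D"), c("D", "AE", "D")), 0)
  expect_equal(phoneme_error_rate(c("D", "AE"), c("D", "AE", "D")), 1 / 3)
  expect_equal(phoneme_error_rate(c("K", "IY", "T"), c("D", "AE", "D")), 1)
  expect_equal(phoneme_error_rate(character(0), c("A", "B")), 1)
  expect_equal(phoneme_error_rate(c("A", "X", "B"), c("A", "B")), 0.5)
  expect_error(phoneme_error_rate(c("A"), character(0)), "empty truth")
})

test_that("edit distance satisfies the triangle inequality", {
  withr::with_seed(14, {
    alph <- c("AA", "AE", "D", "K", "T", "IY")
    for (i in 1:20) {
      a <- sample(alph, sample(3:8, 1), replace = TRUE)
      b <- sample(alph, sample(3:8, 1), replace = TRUE)
      cc <- sample(alph, sample(3:8, 1), replace = TRUE)
      dab <- phoneme_error_rate(a, b) * length(b)
      dbc <- phoneme_error_rate(b, cc) * length(cc)
      dac <- phoneme_error_rate(a, cc) * length(cc)
      expect_lte(dac, dab + dbc + 1e-9)
    }
  })
})
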