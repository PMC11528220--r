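# Direct-DFT oracle for the STFT band power: loops over windows and
# frequencies, independent of the fft-based implementation.
dft_band_power_oracle <- function(x, fs, freq_res, shift_frac, band) {
  nwin <- round(fs / freq_res)
  hop <- round(nwin * shift_frac)
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  freqs <- (0:(nwin - 1)) * fs / nwin
  sel <- which(freqs >= band$lo_hz & freqs < band$hi_hz & freqs <= fs / 2)
  vapply(starts, function(s) {
    seg <- x[s:(s + nwin - 1)]
    n <- 0:(nwin - 1)
    sum(vapply(sel, function(k) {
      Mod(sum(seg * exp(-2i * pi * (k - 1) * n / nwin)))^2
    }, numeric(1)))
  }, numeric(1))
}

test_that("STFT band power matches a direct DFT-and-sum oracle", {
  rec <- generate_broadband_tone(c(200, 40), fs_hz = 2000, duration_s = 1,
                                 amplitude = c(1, 0.5), noise_sd = 0.3,
                                 seed = 5)
  spec <- power_spec(frequency_band(150, 450))
  pw <- compute_lfp_power(rec, spec)
  oracle <- dft_band_power_oracle(rec$samples[1, ], 2000, 5, 0.10,
                                  frequency_band(150, 450))
  expect_equal(as.numeric(pw$values[1, ]), oracle, tolerance = 1e-9)
})

test_that("band power behaves physically on tones", {
  z <- broadband_recording(matrix(0, 1, 2000), 2000)
  expect_true(all(compute_lfp_power(z, power_spec(frequency_band(150, 450)))
                  $values == 0))
  tone <- generate_broadband_tone(200, fs_hz = 2000, duration_s = 3)
  inband <- compute_lfp_power(tone, power_spec(frequency_band(150, 450)))
  v <- as.numeric(inband$values[1, ])
  expect_lt(diff(range(v)) / mean(v), 0.01) # constant across bins
  outband <- compute_lfp_power(tone, power_spec(frequency_band(25, 50)))
  expect_lt(mean(outband$values), mean(v) * 1e-4) # >= 40 dB down
  double <- tone
  double$samples <- 2 * double$samples
  p2 <- compute_lfp_power(double, power_spec(frequency_band(150, 450)))
  expect_equal(p2$values, 4 * inband$values, tolerance = 1e-12)
  short <- broadband_recording(matrix(1, 1, 100), 2000)
  expect_error(compute_lfp_power(short, power_spec(frequency_band(150, 450))),
               "shorter than one window")
})

test_that("power spec invariants and t0 convention hold", {
  expect_error(power_spec(frequency_band(0, 8), freq_res_hz = 5,
                          shift_frac = 0.04), "hop")
  expect_silent(power_spec(frequency_band(0, 8), freq_res_hz = 2,
                           shift_frac = 0.04))
  tone <- generate_broadband_tone(200, fs_hz = 2000, duration_s = 1)
  pw <- compute_lfp_power(tone, power_spec(frequency_band(150, 450)))
  expect_equal(pw$t0_ms, 180) # 200 ms window, 20 ms hop
})

test_that("channel QC flags exactly the constructed outliers", {
  base <- matrix(1 + stats::runif(96 * 50, -0.01, 0.01), 96, 50)
  pw <- binned_features(base, 20, "lfp_power")
  rep0 <- channel_qc(pw)
  expect_true(all(rep0$flag == "keep"))

  dead <- base; dead[17, ] <- 0.1 * dead[17, ]
  repd <- channel_qc(binned_features(dead, 20, "lfp_power"))
  expect_identical(which(repd$flag == "disconnected"), 17L)
  expect_true(all(repd$flag[-17] == "keep"))

  hot <- base; hot[5, ] <- 10 * hot[5, ]
  reph <- channel_qc(binned_features(hot, 20, "lfp_power"))
  expect_identical(which(reph$flag == "overactive"), 5L)

  # flag assignment is invariant to channel ordering
  perm <- sample(96)
  repp <- channel_qc(binned_features(hot[perm, ], 20, "lfp_power"))
  expect_identical(repp$flag, reph$flag[perm])

  expect_error(channel_qc(binned_features(matrix(1, 1, 5), 20, "lfp_power")),
               "2 channels")
})

test_that("causal z-score matches a brute-force rolling recomputation", {
  withr::with_seed(2, {
    x <- matrix(exp(rnorm(2 * 400)), 2, 400)
  })
  x[1, 200:400] <- x[1, 200:400] * 5 # step change in power
  pw <- binned_features(x, 20, "lfp_power")
  z <- log_and_causal_zscore(pw, window_min = 1, eps = 1e-8)
  wlen <- 60 * 1000 / 20
  lx <- log(pmax(x, 1e-8))
  for (t in c(5, 9, 10, 11, 57, 200, 201, 320, 400)) {
    for (ch in 1:2) {
      n_t <- min(t, wlen)
      if (n_t < 10) {
        expect_equal(z$values[ch, t], 0)
      } else {
        h <- lx[ch, (t - n_t + 1):t]
        expect_equal(z$values[ch, t],
                     (lx[ch, t] - mean(h)) / max(stats::sd(h), 1e-8),
                     tolerance = 1e-10, info = paste(ch, t))
      }
    }
  }
})

test_that("causal z-score is constant-zero after warm-up on constant input", {
  pw <- binned_features(matrix(3, 1, 100), 20, "lfp_power")
  z <- log_and_causal_zscore(pw)
  expect_true(all(z$values == 0))
  expect_true(z$flags$log_transformed && z$flags$zscored)
})

test_that("causal z-score never reads the future", {
  withr::with_seed(3, x <- matrix(exp(rnorm(300)), 1, 300))
  z1 <- log_and_causal_zscore(binned_features(x, 20, "lfp_power"))
  x2 <- x
  x2[1, 151:300] <- x2[1, 151:300] * 100 # mutate strictly future bins
  z2 <- log_and_causal_zscore(binned_features(x2, 20, "lfp_power"))
  expect_identical(z1$values[, 1:150], z2$values[, 1:150])
})

test_that("quantization follows the floor-and-clamp rule", {
  pw <- binned_features(matrix(c(0, 0.5, 1.0), 1, 3), 20, "lfp_power")
  q <- quantize(pw, 2)
  expect_equal(as.numeric(q$values), c(0, 2, 3))
  expect_identical(q$flags$quantized_bits, 2L)

  const <- quantize(binned_features(matrix(7, 2, 5), 20, "lfp_power"), 8)
  expect_true(all(const$values == 0))

  withr::with_seed(4, x <- matrix(runif(200, 2, 9), 2, 100))
  q16 <- quantize(binned_features(x, 20, "lfp_power"), 16)
  mins <- apply(x, 1, min); maxs <- apply(x, 1, max)
  back <- q16$values / 2^16 * (maxs - mins) + mins
  expect_lte(max(abs(back - x)), max(maxs - mins) / 2^16)
  expect_error(quantize(pw, 0), "1..64")
})

test_that("band-limited downsampling hits the stated target rates", {
  rec <- generate_broadband_tone(300, fs_hz = 2000, duration_s = 4)
  ds <- downsample_for_band(rec, frequency_band(150, 450))
  expect_equal(ds$fs_hz, 900)
  lo <- generate_broadband_tone(2, fs_hz = 2000, duration_s = 4)
  expect_equal(downsample_for_band(lo, frequency_band(0, 8))$fs_hz, 50)
  expect_error(downsample_for_band(rec, frequency_band(150, 1200)),
               "Nyquist")
  # tone below the band edge survives; tone above the new Nyquist dies
  mid <- function(x) {
    n <- length(x)
    x[round(n * 0.25):round(n * 0.75)]
  }
  rms_in <- sqrt(mean(mid(rec$samples[1, ])^2))
  rms_out <- sqrt(mean(mid(ds$samples[1, ])^2))
  expect_lt(abs(rms_out - rms_in) / rms_in, 0.01)
  hi <- generate_broadband_tone(600, fs_hz = 2000, duration_s = 4)
  ds_hi <- downsample_for_band(hi, frequency_band(150, 450))
  expect_lt(sqrt(mean(mid(ds_hi$samples[1, ])^2)) /
              sqrt(mean(mid(hi$samples[1, ])^2)), 0.01) # >= 40 dB
})

test_that("coincident-timestep zeroing respects the strict 30% boundary", {
  mk <- function(n_spiking) {
    x <- matrix(0L, 10, 50)
    x[seq_len(n_spiking), 25] <- 1L
    x[1, 10] <- 1L # keep one channel alive elsewhere
    x[2, 40] <- 1L
    binned_features(x, 1, "spike_counts")
  }
  out4 <- clean_and_bin_spikes(mk(4), bin_ms = 10, corr_thresh = 1.1)
  expect_equal(out4$n_zeroed_steps, 1L) # 40% > 30%: zeroed
  expect_equal(sum(out4$features$values), 2)
  out3 <- clean_and_bin_spikes(mk(3), bin_ms = 10, corr_thresh = 1.1)
  expect_equal(out3$n_zeroed_steps, 0L) # exactly 30%: kept
  expect_equal(sum(out3$features$values), 5)
})

test_that("a duplicated channel pair loses exactly one member", {
  withr::with_seed(8, {
    x <- matrix(rpois(6 * 2000, 0.02), 6, 2000)
  })
  x <- rbind(x, x[3, ]) # channel 7 duplicates channel 3
  out <- clean_and_bin_spikes(binned_features(x, 1, "spike_counts"),
                              coincident_frac = 1) # isolate the corr rule
  expect_length(out$removed_idx, 1L)
  expect_true(out$removed_idx %in% c(3L, 7L))
  expect_equal(nrow(out$features$values), 6L)
  # binning arithmetic: 2000 ms at 20 ms bins -> 100 bins, counts conserved
  expect_equal(ncol(out$features$values), 100L)
  expect_equal(sum(out$features$values), sum(x[-out$removed_idx, ]))
})

test_that("the generated session's injected QC defects are exactly removed", {
  pp <- prep_session(0)
  cl <- pp$clean
  # the duplicated channel pair (1, 26) loses exactly one member
  expect_length(cl$removed_idx, 1L)
  expect_true(cl$removed_idx %in% c(1L, 26L))
  # every injected artifact timestep was zeroed
  art <- pp$sess$truth$artifact_steps
  n_steps <- ncol(pp$bundle$features$spikes_1ms$values)
  expect_gt(length(art), 100)
  expect_true(all(art %in% seq_len(n_steps)))
  expect_gte(cl$n_zeroed_steps, length(art))
})

test_that("gaussian smoothing preserves mass, DC, and matches dense conv", {
  imp <- matrix(0, 1, 101); imp[1, 51] <- 1
  sm <- gaussian_smooth(binned_features(imp, 20, "lfp_power"), 30)
  expect_equal(sum(sm$values), 1, tolerance = 1e-9)
  sd_bins <- 30 / 20
  expect_equal(sm$values[1, 51], stats::dnorm(0, sd = sd_bins) /
                 sum(stats::dnorm(-6:6, sd = sd_bins)), tolerance = 1e-9)

  const <- gaussian_smooth(binned_features(matrix(4, 2, 30), 20,
                                           "lfp_power"), 30)
  expect_equal(const$values, matrix(4, 2, 30), tolerance = 1e-12)

  withr::with_seed(5, x <- matrix(rnorm(50), 1, 50))
  sm2 <- gaussian_smooth(binned_features(exp(x), 20, "lfp_power"), 30)
  r <- ceiling(4 * sd_bins)
  k <- stats::dnorm(-r:r, sd = sd_bins); k <- k / sum(k)
  oracle <- vapply(1:50, function(t) {
    js <- (-r):r
    ok <- t + js >= 1 & t + js <= 50
    sum(k[ok] * exp(x)[1, t + js[ok]]) / sum(k[ok])
  }, numeric(1))
  expect_equal(as.numeric(sm2$values), oracle, tolerance = 1e-12)
  expect_error(gaussian_smooth(sm2, -1), "sd_ms")
})

test_that("LFP extraction attenuates DC and powerline, passes the band", {
  fs <- 10000
  n <- fs * 3
  dc <- broadband_recording(matrix(1, 1, n), fs)
  lfp_dc <- extract_lfp(dc, "monkey")
  tail_rms <- sqrt(mean(lfp_dc$samples[1, 2000:ncol(lfp_dc$samples)]^2))
  expect_lt(tail_rms, 0.15) # 0.3 Hz high-pass bleeds DC away

  t60 <- generate_broadband_tone(60, fs_hz = fs, duration_s = 10)
  out60 <- extract_lfp(t60, "monkey")
  mid <- function(x) x[round(length(x) * 0.3):round(length(x) * 0.9)]
  expect_lt(sqrt(mean(mid(out60$samples[1, ])^2)) /
              sqrt(mean(t60$samples[1, ]^2)), 0.10)

  t200 <- generate_broadband_tone(200, fs_hz = fs, duration_s = 5)
  out200 <- extract_lfp(t200, "monkey")
  gain <- sqrt(mean(mid(out200$samples[1, ])^2)) /
    sqrt(mean(t200$samples[1, ]^2))
  bp <- signal::butter(1, c(0.3, 500) / (fs / 2), type = "pass")
  w <- 2 * pi * 200 / fs # closed-form magnitude response at 200 Hz
  h <- abs(sum(bp$b * exp(-1i * w * (seq_along(bp$b) - 1))) /
             sum(bp$a * exp(-1i * w * (seq_along(bp$a) - 1))))
  expect_equal(gain, h, tolerance = 0.05)
  expect_equal(out200$fs_hz, 2000)
  expect_error(extract_lfp(broadband_recording(matrix(0, 1, 100), 500),
                           "monkey"), "fs")
})

test_that("threshold crossings count injected spikes and nothing else", {
  fs <- 20000
  withr::with_seed(6, noise <- rnorm(fs, sd = 1))
  flat <- broadband_recording(matrix(0, 1, fs), fs)
  expect_equal(sum(detect_threshold_crossings(flat)$values), 0)

  x <- noise
  spike_t <- c(2000, 6000, 9000, 13000, 17500)
  shape <- c(-8, -12, -8, 2, 4, 2) # biphasic, ~8x RMS trough
  for (s in spike_t) x[s:(s + 5)] <- x[s:(s + 5)] + shape
  rec <- broadband_recording(matrix(x, 1), fs)
  tc <- detect_threshold_crossings(rec)
  expect_equal(sum(tc$values), length(spike_t))
  hit_bins <- which(tc$values[1, ] > 0)
  expect_equal(hit_bins, floor((spike_t - 1) / fs * 1000) + 1,
               tolerance = 1.01)

  none <- detect_threshold_crossings(rec, threshold_rms = -1000)
  expect_equal(sum(none$values), 0)
  expect_error(detect_threshold_crossings(
    broadband_recording(matrix(0, 1, 100), 8000)), "2 \\* band")
})
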