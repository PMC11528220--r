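# Signal preprocessing: broadband -> 2 kHz LFP, threshold-crossing spike
# detection, STFT band power, channel quality control, log + causal
# normalization, quantization, band-limited downsampling, spike-raster
# cleaning and binning, and Gaussian smoothing.

# ---- filtering helpers -----------------------------------------------------

# 2nd-order IIR notch (RBJ biquad), applied causally at f0 and used at the
# powerline harmonics below Nyquist
notch_coefficients <- function(f0_hz, fs_hz, q = 35) {
  w0 <- 2 * pi * f0_hz / fs_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

apply_notch_harmonics <- function(x, fs_hz, base_hz = 60, q = 35) {
  f0 <- base_hz
  while (f0 < fs_hz / 2) {
    co <- notch_coefficients(f0, fs_hz, q)
    x <- as.numeric(signal::filter(co$b, co$a, x))
    f0 <- f0 + base_hz
  }
  x
}

filter_rows <- function(samples, fn) {
  out <- t(apply(samples, 1, fn))
  if (nrow(samples) == 1L) out <- matrix(out, nrow = 1L)
  out
}

# Rational FIR resampling of each channel to target_fs: zero-stuff by p,
# filter with a long symmetric low-pass (cutoff 0.9x the new Nyquist,
# zero-phase by delay compensation), keep every q-th sample.
resample_rows <- function(samples, fs_hz, target_fs) {
  if (isTRUE(all.equal(fs_hz, target_fs))) return(samples)
  frac <- target_fs / fs_hz
  # smallest integer p/q representation (rates here are small rationals)
  q <- 1L
  while (abs(frac * q - round(frac * q)) > 1e-9 && q < 1e6) q <- q + 1L
  p <- as.integer(round(frac * q))
  g <- gcd_int(p, q)
  p <- p %/% g; q <- q %/% g
  m <- max(p, q)
  ntaps <- 24L * m # even: symmetric FIR with integer group delay ntaps/2
  h <- signal::fir1(ntaps, 0.9 / m) * p
  filter_rows(samples, function(x) {
    up <- numeric(length(x) * p)
    up[seq(1, by = p, length.out = length(x))] <- x
    y <- stats::convolve(up, rev(h), type = "open")
    y <- y[(ntaps / 2 + 1):(ntaps / 2 + length(up))]
    y[seq(1, by = q, length.out = floor((length(up) - 1) / q) + 1)]
  })
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Extract 2 kHz LFP from broadband voltage
#'
#' Two acquisition-matched pipelines: `"monkey"` applies a causal 1st-order
#' band-pass (0.3-500 Hz), resamples to 2 kHz, then notch filters at 60 Hz
#' harmonics; `"human"` applies a causal 5th-order Butterworth low-pass at
#' 1000 Hz, downsamples to 2 kHz, then the same notch chain.
#'
#' @param broadband A [broadband_recording()].
#' @param pipeline `"monkey"` or `"human"`.
#' @return A [broadband_recording()] at 2000 Hz.
#' @export
extract_lfp <- function(broadband, pipeline = c("monkey", "human")) {
  stopifnot(inherits(broadband, "broadband_recording"))
  pipeline <- match.arg(pipeline)
  fs <- broadband$fs_hz
  target <- 2000
  if (pipeline == "monkey") {
    if (fs < 2 * 500) stop("extract_lfp: fs must be >= 1000 Hz for the ",
                           "0.3-500 Hz band-pass")
    if (fs < target) stop("extract_lfp: fs must be >= 2 kHz to resample")
    bp <- signal::butter(1, c(0.3, 500) / (fs / 2), type = "pass")
    x <- filter_rows(broadband$samples, function(v) {
      as.numeric(signal::filter(bp, v))
    })
  } else {
    if (fs <= 2 * 1000) stop("extract_lfp: fs must exceed 2 kHz for the ",
                             "1000 Hz low-pass")
    lp <- signal::butter(5, 1000 / (fs / 2), type = "low")
    x <- filter_rows(broadband$samples, function(v) {
      as.numeric(signal::filter(lp, v))
    })
  }
  x <- resample_rows(x, fs, target)
  x <- filter_rows(x, function(v) apply_notch_harmonics(v, target))
  broadband_recording(x, target, broadband$channel_ids)
}

#' Detect threshold-crossing spikes
#'
#' Band-pass filters each channel, sets a per-channel threshold at
#' `threshold_rms` times the RMS of the filtered trace (negative multiplier,
#' so the threshold sits below baseline), counts downward crossings with a
#' 1 ms refractory period, and bins the events at 1 ms.
#'
#' @param broadband A [broadband_recording()]; `fs_hz >= 2 * band$hi_hz`.
#' @param threshold_rms RMS multiplier (default -4.5).
#' @param band Detection band (default 250-5000 Hz).
#' @param filter_order Butterworth design order (default 4).
#' @return A [binned_features()] of spike counts at 1 ms bins.
#' @export
detect_threshold_crossings <- function(broadband, threshold_rms = -4.5,
                                       band = frequency_band(250, 5000),
                                       filter_order = 4) {
  stopifnot(inherits(broadband, "broadband_recording"),
            inherits(band, "frequency_band"))
  fs <- broadband$fs_hz
  if (fs < 2 * band$hi_hz) {
    stop("detect_threshold_crossings: fs (", fs, ") must be >= 2 * band ",
         "upper edge (", 2 * band$hi_hz, ")")
  }
  bp <- signal::butter(filter_order, c(band$lo_hz, band$hi_hz) / (fs / 2),
                       type = "pass")
  n <- ncol(broadband$samples)
  refrac <- fs / 1000 # samples per ms
  n_ms <- floor(n / fs * 1000)
  counts <- matrix(0L, nrow(broadband$samples), n_ms)
  for (c_i in seq_len(nrow(broadband$samples))) {
    v <- as.numeric(signal::filter(bp, broadband$samples[c_i, ]))
    rms <- sqrt(mean(v^2))
    thr <- threshold_rms * rms
    if (rms == 0) next
    cand <- which(v[-1] < thr & v[-n] >= thr) + 1L
    if (length(cand) == 0L) next
    keep <- cand[1]
    last <- cand[1]
    for (i in cand[-1]) {
      if (i - last >= refrac) {
        keep <- c(keep, i)
        last <- i
      }
    }
    bins <- floor((keep - 1) / fs * 1000) + 1L
    bins <- bins[bins <= n_ms]
    tb <- table(bins)
    counts[c_i, as.integer(names(tb))] <- as.integer(tb)
  }
  binned_features(counts, bin_ms = 1, kind = "spike_counts",
                  channel_ids = broadband$channel_ids)
}

# ---- STFT band power -------------------------------------------------------

#' STFT band-power specification
#'
#' The window length is `fs / freq_res_hz` samples (a rectangular window has
#' exactly this frequency resolution) and the hop is `shift_frac` of the
#' window, which must equal one output bin (`bin_ms`).
#'
#' @param band A [frequency_band()].
#' @param freq_res_hz STFT frequency resolution in Hz (default 5; the 0-8 Hz
#'   band conventionally uses 2).
#' @param shift_frac Hop as a fraction of the window length (default 0.10;
#'   0.04 for the 0-8 Hz band).
#' @param bin_ms Output bin width (ms), default 20.
#' @return A `power_spec` list.
#' @export
power_spec <- function(band, freq_res_hz = 5, shift_frac = 0.10,
                       bin_ms = 20) {
  stopifnot(inherits(band, "frequency_band"))
  if (abs(shift_frac / freq_res_hz - bin_ms / 1000) > 1e-9) {
    stop("power_spec: (1/freq_res_hz) * shift_frac must equal bin_ms/1000 ",
         "(hop = one output bin)")
  }
  structure(list(band = band, freq_res_hz = freq_res_hz,
                 shift_frac = shift_frac, bin_ms = bin_ms),
            class = "power_spec")
}

#' Compute LFP band power with a short-time Fourier transform
#'
#' Rectangular windows of `fs / freq_res_hz` samples hop by one output bin;
#' per hop, the squared magnitudes of the one-sided DFT coefficients whose
#' center frequency lies in `[band$lo_hz, band$hi_hz)` are summed, giving one
#' power value per channel per 20 ms bin. The first full window defines the
#' output time origin.
#'
#' @param lfp A [broadband_recording()] (conventionally 2 kHz).
#' @param spec A [power_spec()].
#' @return A [binned_features()] of kind `lfp_power`.
#' @export
compute_lfp_power <- function(lfp, spec) {
  stopifnot(inherits(lfp, "broadband_recording"),
            inherits(spec, "power_spec"))
  fs <- lfp$fs_hz
  if (spec$band$hi_hz > fs / 2) {
    stop("compute_lfp_power: band must fit below Nyquist (", fs / 2, " Hz)")
  }
  nwin <- round(fs / spec$freq_res_hz)
  hop <- round(nwin * spec$shift_frac)
  stopifnot(abs(hop - fs * spec$bin_ms / 1000) < 1e-9)
  n <- ncol(lfp$samples)
  if (n < nwin) {
    stop("compute_lfp_power: signal (", n, " samples) shorter than one ",
         "window (", nwin, " samples)")
  }
  starts <- seq(1L, n - nwin + 1L, by = hop)
  freqs <- (seq_len(nwin) - 1) * fs / nwin
  sel <- which(freqs >= spec$band$lo_hz & freqs < spec$band$hi_hz &
                 freqs <= fs / 2)
  out <- matrix(0, nrow(lfp$samples), length(starts))
  for (w in seq_along(starts)) {
    seg <- lfp$samples[, starts[w]:(starts[w] + nwin - 1L), drop = FALSE]
    spec_w <- stats::mvfft(t(seg))
    out[, w] <- colSums(abs(spec_w[sel, , drop = FALSE])^2)
  }
  binned_features(out, bin_ms = spec$bin_ms, kind = "lfp_power",
                  t0_ms = (nwin - hop) / fs * 1000, band = spec$band,
                  channel_ids = lfp$channel_ids)
}

# ---- channel QC ------------------------------------------------------------

#' Flag disconnected and overly active channels from band power
#'
#' A channel is flagged `disconnected` when its mean band power is below 50%
#' of the median of the per-channel means, and `overactive` when its mean is
#' at least twice the 99th quantile of the per-channel means.
#'
#' @param power Un-normalized [binned_features()] of kind `lfp_power`.
#' @return A `channel_qc_report`: data frame of per-channel mean power and
#'   flag, with the thresholds used as attributes.
#' @export
channel_qc <- function(power) {
  stopifnot(inherits(power, "binned_features"))
  if (power$kind != "lfp_power") {
    stop("channel_qc: expected lfp_power features, got ", power$kind)
  }
  if (isTRUE(power$flags$log_transformed) || isTRUE(power$flags$zscored)) {
    stop("channel_qc: power must be un-normalized (no log/z-score)")
  }
  if (nrow(power$values) < 2L) stop("channel_qc: need at least 2 channels")
  means <- rowMeans(power$values)
  med <- stats::median(means)
  q99 <- stats::quantile(means, 0.99, names = FALSE)
  flag <- rep("keep", length(means))
  flag[means >= 2 * q99] <- "overactive"
  flag[means < 0.5 * med] <- "disconnected"
  rep_df <- data.frame(channel = power$channel_ids, mean_power = means,
                       flag = flag, stringsAsFactors = FALSE)
  structure(rep_df,
            thresholds = list(disconnected_below = 0.5 * med,
                              overactive_at = 2 * q99),
            class = c("channel_qc_report", "data.frame"))
}

#' @rdname channel_qc
#' @param report A `channel_qc_report`.
#' @return For `qc_keep_mask`, a logical vector of channels to keep.
#' @export
qc_keep_mask <- function(report) {
  stopifnot(inherits(report, "channel_qc_report"))
  report$flag == "keep"
}

# ---- normalization ---------------------------------------------------------

#' Log-transform and causally z-score band power
#'
#' Takes the log of the power (clamped at `eps`), then z-scores each bin
#' using the mean and standard deviation of the trailing `window_min`-minute
#' window (current bin included, future bins never read). Before the window
#' fills, all available history is used, with a minimum of 10 bins; earlier
#' bins emit 0.
#'
#' @param power A [binned_features()] of kind `lfp_power`.
#' @param window_min Rolling window length in minutes (default 3).
#' @param eps Clamp for the log and zero-variance guard (default 1e-8).
#' @return Normalized [binned_features()] with `log_transformed` and
#'   `zscored` flags set.
#' @export
log_and_causal_zscore <- function(power, window_min = 3, eps = 1e-8) {
  stopifnot(inherits(power, "binned_features"))
  if (power$kind != "lfp_power") {
    stop("log_and_causal_zscore: expected lfp_power, got ", power$kind)
  }
  x <- log(pmax(power$values, eps))
  # center per channel (on the first bin, so no future bin is read) before
  # the cumulative sums: the rolling mean/sd are shift-invariant and this
  # avoids catastrophic cancellation in the running-variance update
  x <- x - x[, 1]
  nb <- ncol(x)
  wlen <- round(window_min * 60 * 1000 / power$bin_ms)
  min_hist <- 10L
  z <- matrix(0, nrow(x), nb)
  cs <- t(apply(x, 1, cumsum))
  cs2 <- t(apply(x^2, 1, cumsum))
  if (nrow(x) == 1L) { cs <- matrix(cs, 1); cs2 <- matrix(cs2, 1) }
  for (t in seq_len(nb)) {
    n_t <- min(t, wlen)
    if (n_t < min_hist) next
    lo <- t - n_t # exclusive
    s1 <- cs[, t] - if (lo > 0) cs[, lo] else 0
    s2 <- cs2[, t] - if (lo > 0) cs2[, lo] else 0
    m <- s1 / n_t
    v <- pmax((s2 - n_t * m^2) / (n_t - 1), 0)
    sdv <- sqrt(v)
    z[, t] <- ifelse(sdv < eps, 0, (x[, t] - m) / sdv)
  }
  out <- power
  out$values <- z
  out$flags$log_transformed <- TRUE
  out$flags$zscored <- TRUE
  out
}

# ---- quantization ----------------------------------------------------------

#' Quantize features channel-wise to b bits
#'
#' Min-max scales each channel over the whole session to `[0, 2^b]` and
#' floors to integers, clamping to `2^b - 1`. Constant channels map to 0.
#'
#' @param power A [binned_features()].
#' @param bits Bit depth `b` (1-64; the transmission analyses use 4, 8, 16,
#'   and 64).
#' @return Quantized [binned_features()] with `quantized_bits` set.
#' @export
quantize <- function(power, bits) {
  stopifnot(inherits(power, "binned_features"))
  if (!is.numeric(bits) || length(bits) != 1L || bits < 1 || bits > 64 ||
      bits != round(bits)) {
    stop("quantize: bits must be an integer in 1..64")
  }
  if (any(!is.finite(power$values))) stop("quantize: non-finite input")
  levels <- 2^bits
  x <- power$values
  mins <- apply(x, 1, min)
  maxs <- apply(x, 1, max)
  rng <- maxs - mins
  q <- matrix(0, nrow(x), ncol(x))
  ok <- rng > 0
  if (any(ok)) {
    q[ok, ] <- floor((x[ok, , drop = FALSE] - mins[ok]) / rng[ok] * levels)
    q[ok, ] <- pmin(q[ok, , drop = FALSE], levels - 1)
  }
  out <- power
  out$values <- q
  out$flags$quantized_bits <- as.integer(bits)
  attr(out$values, "quantize_min") <- mins
  attr(out$values, "quantize_max") <- maxs
  out
}

# ---- band-limited downsampling --------------------------------------------

#' Downsample a recording to the Nyquist rate of a band's upper edge
#'
#' Target rate is `2 * band$hi_hz`, with a floor of 50 Hz (the lowest rate
#' that maintains 20 ms bins, used for the 0-8 Hz band). Resampling is
#' anti-alias filtered (polyphase FIR).
#'
#' @param lfp A [broadband_recording()].
#' @param band A [frequency_band()] with `hi_hz <= fs/2`.
#' @return A [broadband_recording()] at the target rate.
#' @export
downsample_for_band <- function(lfp, band) {
  stopifnot(inherits(lfp, "broadband_recording"),
            inherits(band, "frequency_band"))
  if (band$hi_hz > lfp$fs_hz / 2) {
    stop("downsample_for_band: band upper edge (", band$hi_hz,
         " Hz) above input Nyquist (", lfp$fs_hz / 2, " Hz)")
  }
  target <- max(2 * band$hi_hz, 50)
  x <- resample_rows(lfp$samples, lfp$fs_hz, target)
  broadband_recording(x, target, lfp$channel_ids)
}

# ---- spike cleaning and binning -------------------------------------------

#' Remove coincident artifacts and correlated channels, then bin spikes
#'
#' Three steps on a 1 ms spike raster: (1) any timestep on which more than
#' `coincident_frac` of channels spike is zeroed across all channels;
#' (2) channels are removed greedily (the channel in the most
#' above-threshold Pearson pairs first, ties to the lower index) until no
#' pairwise correlation on the raster exceeds `corr_thresh`; (3) remaining
#' counts are summed into `bin_ms` bins (half-open, trailing partial bin
#' dropped).
#'
#' @param raster A [binned_features()] of 1 ms spike counts.
#' @param coincident_frac Fraction of spiking channels above which a
#'   timestep is treated as an artifact (default 0.30, strictly greater).
#' @param corr_thresh Maximum allowed pairwise correlation (default 0.2).
#' @param bin_ms Output bin width (default 20).
#' @return A list: `features` (binned counts), `removed_channels` (ids),
#'   `removed_idx`, `n_zeroed_steps`.
#' @export
clean_and_bin_spikes <- function(raster, coincident_frac = 0.30,
                                 corr_thresh = 0.2, bin_ms = 20) {
  stopifnot(inherits(raster, "binned_features"))
  if (raster$kind != "spike_counts") {
    stop("clean_and_bin_spikes: expected spike_counts, got ", raster$kind)
  }
  x <- raster$values
  n_ch <- nrow(x)
  # (1) coincident-timestep removal
  frac <- colSums(x > 0) / n_ch
  zero_steps <- which(frac > coincident_frac)
  if (length(zero_steps)) x[, zero_steps] <- 0L
  # (2) greedy correlated-channel removal
  cmat <- suppressWarnings(stats::cor(t(x)))
  cmat[!is.finite(cmat)] <- 0
  diag(cmat) <- 0
  alive <- rep(TRUE, n_ch)
  repeat {
    sub <- cmat[alive, alive, drop = FALSE]
    if (!any(sub > corr_thresh)) break
    offenders <- rowSums(sub > corr_thresh)
    local_i <- which(offenders == max(offenders))[1] # ties: lower index
    victim <- which(alive)[local_i]
    alive[victim] <- FALSE
    if (!any(alive)) stop("clean_and_bin_spikes: all channels removed")
  }
  x <- x[alive, , drop = FALSE]
  # (3) sum into bin_ms bins
  spb <- round(bin_ms / raster$bin_ms)
  n_out <- floor(ncol(x) / spb)
  if (n_out < 1L) stop("clean_and_bin_spikes: raster shorter than one bin")
  idx <- rep(seq_len(n_out), each = spb)
  binned <- t(rowsum(t(x[, seq_len(n_out * spb), drop = FALSE]), idx))
  feats <- binned_features(binned, bin_ms = bin_ms, kind = "spike_counts",
                           t0_ms = raster$t0_ms,
                           channel_ids = raster$channel_ids[alive])
  list(features = feats,
       removed_channels = raster$channel_ids[!alive],
       removed_idx = which(!alive),
       n_zeroed_steps = length(zero_steps))
}

# ---- smoothing -------------------------------------------------------------

#' Gaussian-smooth binned features along time
#'
#' Symmetric Gaussian convolution with the kernel truncated at +/- 4 SD and
#' renormalized at the edges, so constant signals pass through unchanged.
#' Smoothed spike counts are no longer integers; the `kind` is preserved and
#' the `smoothed_sd_ms` flag records the kernel.
#'
#' @param x A [binned_features()].
#' @param sd_ms Kernel standard deviation in ms (30 for monkey-style
#'   analyses, 50 for human).
#' @param causal If `TRUE`, use only the trailing half of the kernel
#'   (renormalized); default is the symmetric offline kernel.
#' @return Smoothed [binned_features()].
#' @export
gaussian_smooth <- function(x, sd_ms = 30, causal = FALSE) {
  stopifnot(inherits(x, "binned_features"))
  if (sd_ms <= 0) stop("gaussian_smooth: sd_ms must be > 0")
  sd_bins <- sd_ms / x$bin_ms
  r <- ceiling(4 * sd_bins)
  offs <- (-r):r
  k <- stats::dnorm(offs, sd = sd_bins)
  if (causal) k[offs > 0] <- 0
  k <- k / sum(k)
  v <- x$values
  nb <- ncol(v)
  acc <- matrix(0, nrow(v), nb)
  wsum <- numeric(nb)
  for (i in seq_along(offs)) {
    j <- offs[i]
    dest <- max(1, 1 - j):min(nb, nb - j)
    src <- dest + j
    acc[, dest] <- acc[, dest, drop = FALSE] +
      k[i] * v[, src, drop = FALSE]
    wsum[dest] <- wsum[dest] + k[i]
  }
  out <- x
  out$values <- sweep(acc, 2, wsum, "/")
  out$flags$smoothed_sd_ms <- sd_ms
  out
}
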