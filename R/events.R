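# Behavioral event detection: movement-onset alignment with trial rejection,
# aligned-window extraction, and speech onset/offset from a microphone
# envelope.

#' Movement alignment specification
#'
#' @param search_offset_ms Skip this much after trial start before searching
#'   for the speed crossing (default 250 ms).
#' @param peak_frac Threshold as a fraction of the within-trial peak speed
#'   (default 0.70).
#' @param window_pre_ms,window_post_ms Analysis window around the alignment
#'   point (defaults 250 and 500 ms).
#' @return An `alignment_spec` list.
#' @export
alignment_spec <- function(search_offset_ms = 250, peak_frac = 0.70,
                           window_pre_ms = 250, window_post_ms = 500) {
  if (!(peak_frac > 0 && peak_frac < 1)) {
    stop("alignment_spec: peak_frac must be in (0, 1)")
  }
  if (window_pre_ms <= 0 || window_post_ms <= 0) {
    stop("alignment_spec: window bounds must be positive")
  }
  structure(list(search_offset_ms = search_offset_ms, peak_frac = peak_frac,
                 window_pre_ms = window_pre_ms,
                 window_post_ms = window_post_ms),
            class = "alignment_spec")
}

#' Detect movement onsets and fill trial alignment times
#'
#' Within each trial's search window (`search_offset_ms` after trial start to
#' trial stop), the alignment time is the first upward crossing of
#' `peak_frac` times the trial's peak speed: the first bin at or above
#' threshold whose predecessor is below it. A trial is accepted only when
#' the first crossing found scanning forward equals the last crossing found
#' scanning backward (i.e. the speed crosses the threshold exactly once);
#' trials whose speed starts above threshold, or with multiple crossings
#' (corrective movements), are rejected with `align_ms` left empty.
#'
#' @param speed Numeric vector of speed (cm/s) on the feature bin clock.
#' @param trials A [trial_table()].
#' @param spec An [alignment_spec()].
#' @param bin_ms Bin width of `speed` in ms (default 20).
#' @param t0_ms Time of the first speed bin (default 0).
#' @return The trial table with `align_ms` and `accepted` filled.
#' @export
movement_onsets <- function(speed, trials, spec = alignment_spec(),
                            bin_ms = 20, t0_ms = 0) {
  validate_trial_table(trials)
  nb <- length(speed)
  out <- trials
  out$align_ms <- NA_real_
  out$accepted <- FALSE
  for (i in seq_len(nrow(trials))) {
    a_ms <- trials$start_ms[i] + spec$search_offset_ms
    b_ms <- trials$stop_ms[i]
    a <- floor((a_ms - t0_ms) / bin_ms) + 1L
    b <- min(floor((b_ms - t0_ms) / bin_ms), nb) # stop is exclusive
    if (a < 1L || b - a < 1L) next # empty/out-of-range window: reject
    s <- speed[a:b]
    thr <- spec$peak_frac * max(s)
    up <- which(s[-1] >= thr & s[-length(s)] < thr) + 1L
    if (length(up) == 0L) next # starts above threshold: no defined crossing
    first_fwd <- up[1]
    last_bwd <- up[length(up)]
    if (first_fwd != last_bwd) next # multiple crossings: reject
    out$align_ms[i] <- t0_ms + (a - 1L + first_fwd - 1L) * bin_ms
    out$accepted[i] <- TRUE
  }
  validate_trial_table(out)
  out
}

#' Extract feature windows aligned to trial events
#'
#' For every accepted trial with an alignment time, extracts the window from
#' `pre_ms` before to `post_ms` after the alignment bin. The window spans
#' `floor((pre_ms + post_ms) / bin_ms)` bins: `floor(pre_ms / bin_ms)` bins
#' before the alignment bin, the alignment bin itself, and the remainder
#' after (so the default 250/500 ms window at 20 ms bins is 37 bins).
#'
#' @param x A [binned_features()].
#' @param trials A [trial_table()] with `align_ms`/`accepted` filled.
#' @param pre_ms,post_ms Window bounds (defaults 250 and 500 ms).
#' @return A list: `tensor` (trial x channel x bin array over the accepted,
#'   in-range trials), `trial_id`, `condition`, `n_bins`.
#' @export
extract_aligned <- function(x, trials, pre_ms = 250, post_ms = 500) {
  stopifnot(inherits(x, "binned_features"))
  validate_trial_table(trials)
  nb_win <- as.integer(floor((pre_ms + post_ms) / x$bin_ms))
  pre_bins <- as.integer(floor(pre_ms / x$bin_ms))
  usable <- which(trials$accepted %in% TRUE & !is.na(trials$align_ms))
  keep <- integer(0)
  rows <- list()
  for (i in usable) {
    ctr <- bin_index(x, trials$align_ms[i])
    a <- ctr - pre_bins
    b <- a + nb_win - 1L
    if (a < 1L || b > ncol(x$values)) {
      warning("extract_aligned: trial ", trials$trial_id[i],
              " window out of range; dropped")
      next
    }
    keep <- c(keep, i)
    rows[[length(rows) + 1L]] <- x$values[, a:b, drop = FALSE]
  }
  tensor <- array(0, dim = c(length(keep), nrow(x$values), nb_win))
  for (j in seq_along(rows)) tensor[j, , ] <- rows[[j]]
  list(tensor = tensor, trial_id = trials$trial_id[keep],
       condition = trials$condition_label[keep], n_bins = nb_win,
       channel_ids = x$channel_ids)
}

#' Compute a speech envelope from microphone audio
#'
#' Mean-centers the waveform, high-pass filters at `hp_hz`, rectifies,
#' low-pass filters at `lp_hz` (both 4th-order Butterworth, applied
#' causally), and downsamples to `out_fs` (50 Hz puts the envelope on the
#' 20 ms feature clock).
#'
#' @param mic Numeric waveform.
#' @param fs_hz Sampling rate of `mic`; must exceed `2 * hp_hz`.
#' @param hp_hz High-pass cutoff (default 65 Hz).
#' @param lp_hz Low-pass cutoff (default 10 Hz).
#' @param out_fs Output rate (default 50 Hz).
#' @return Numeric envelope at `out_fs`.
#' @export
audio_envelope <- function(mic, fs_hz, hp_hz = 65, lp_hz = 10, out_fs = 50) {
  if (fs_hz <= 2 * hp_hz) {
    stop("audio_envelope: fs_hz must exceed 2 * hp_hz (", 2 * hp_hz, ")")
  }
  x <- mic - mean(mic)
  hp <- signal::butter(4, hp_hz / (fs_hz / 2), type = "high")
  x <- as.numeric(signal::filter(hp, x))
  x <- abs(x)
  lp <- signal::butter(4, lp_hz / (fs_hz / 2), type = "low")
  x <- as.numeric(signal::filter(lp, x))
  env <- resample_rows(matrix(x, 1), fs_hz, out_fs)
  as.numeric(env)
}

#' Detect speech onset and offset from an envelope
#'
#' Differentiates the envelope (first difference scaled to per-second
#' units), restricts to `[go_ms, stop_ms]`, and finds strict local maxima of
#' the derivative (onsets) and of its negation (offsets) with magnitude at
#' least `peak_min` and a minimum separation of 60 ms. The onset is the
#' first qualifying positive peak, the offset the last qualifying negative
#' peak.
#'
#' @param envelope Numeric envelope series.
#' @param fs_hz Envelope sampling rate (default 50 Hz).
#' @param go_ms,stop_ms Search interval in ms (envelope assumed to start at
#'   t = 0).
#' @param peak_min Minimum derivative-peak magnitude (default 3.5, in
#'   envelope units per second).
#' @return A list with `onset_ms` and `offset_ms` (`NA` when no qualifying
#'   peak exists; the caller decides trial rejection).
#' @export
speech_onset_offset <- function(envelope, fs_hz = 50, go_ms, stop_ms,
                                peak_min = 3.5) {
  n <- length(envelope)
  d <- diff(envelope) * fs_hz # derivative at sample boundaries i+1
  t_ms <- (seq_len(n - 1)) / fs_hz * 1000
  inside <- t_ms >= go_ms & t_ms <= stop_ms
  min_sep <- ceiling(0.060 * fs_hz)
  find_peaks <- function(v) {
    idx <- which(v > c(-Inf, v[-length(v)]) & v > c(v[-1], -Inf) &
                   v >= peak_min & inside)
    if (length(idx) <= 1L) return(idx)
    kept <- idx[1]
    for (i in idx[-1]) {
      if (i - kept[length(kept)] >= min_sep) kept <- c(kept, i)
    }
    kept
  }
  pos <- find_peaks(d)
  neg <- find_peaks(-d)
  list(onset_ms = if (length(pos)) t_ms[pos[1]] else NA_real_,
       offset_ms = if (length(neg)) t_ms[neg[length(neg)]] else NA_real_)
}
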