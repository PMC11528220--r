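#' Frequency band
#'
#' A half-open frequency interval `[lo_hz, hi_hz)` used to select spectral
#' content, e.g. the 150-450 Hz band whose power drives the dynamics model.
#'
#' @param lo_hz Lower edge in Hz (inclusive). Must satisfy `0 <= lo_hz`.
#' @param hi_hz Upper edge in Hz (exclusive). Must satisfy `lo_hz < hi_hz`.
#' @return An object of class `frequency_band` with fields `lo_hz`, `hi_hz`.
#' @examples
#' band <- frequency_band(150, 450)
#' band_width(band)
#' @export
frequency_band <- function(lo_hz, hi_hz) {
  stopifnot(is.numeric(lo_hz), is.numeric(hi_hz),
            length(lo_hz) == 1L, length(hi_hz) == 1L)
  if (!(lo_hz >= 0 && lo_hz < hi_hz)) {
    stop("frequency_band: need 0 <= lo_hz < hi_hz, got [",
         lo_hz, ", ", hi_hz, ")")
  }
  structure(list(lo_hz = as.numeric(lo_hz), hi_hz = as.numeric(hi_hz)),
            class = "frequency_band")
}

#' @rdname frequency_band
#' @param band A `frequency_band`.
#' @export
band_width <- function(band) {
  stopifnot(inherits(band, "frequency_band"))
  band$hi_hz - band$lo_hz
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> [%g, %g) Hz (width %g Hz)\n",
              x$lo_hz, x$hi_hz, band_width(x)))
  invisible(x)
}

#' Broadband voltage recording
#'
#' A multichannel extracellular voltage trace sampled at a fixed rate, the
#' raw material for spike detection and LFP band-power extraction.
#'
#' @param samples Channels x samples numeric matrix of voltage (uV).
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param channel_ids Optional character/integer vector of channel labels;
#'   defaults to `ch1 ... chN`.
#' @return An object of class `broadband_recording`.
#' @export
broadband_recording <- function(samples, fs_hz, channel_ids = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("broadband_recording: samples must be a finite numeric matrix")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("broadband_recording: fs_hz must be a positive scalar")
  }
  if (is.null(channel_ids)) {
    channel_ids <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_ids) != nrow(samples)) {
    stop("broadband_recording: channel_ids length (", length(channel_ids),
         ") must equal channel count (", nrow(samples), ")")
  }
  structure(list(samples = samples, fs_hz = as.numeric(fs_hz),
                 channel_ids = as.character(channel_ids)),
            class = "broadband_recording")
}

#' @export
print.broadband_recording <- function(x, ...) {
  cat(sprintf("<broadband_recording> %d ch x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              ncol(x$samples) / x$fs_hz))
  invisible(x)
}

default_feature_flags <- function() {
  list(log_transformed = FALSE, zscored = FALSE,
       smoothed_sd_ms = NA_real_, quantized_bits = NA_integer_)
}

#' Binned feature matrix
#'
#' Channels x bins matrix on a common bin clock. Carries LFP band power
#' p(t), spike counts s(t), model-inferred rates, or latent factors, plus a
#' record of every transform applied (log, z-score, smoothing, quantization).
#'
#' All binned data use a 0-based half-open bin convention: bin `k` covers
#' `[t0_ms + k * bin_ms, t0_ms + (k + 1) * bin_ms)`.
#'
#' @param values Channels x bins numeric matrix. Units depend on `kind`:
#'   spike counts per bin, power in uV^2, or rates in spikes/bin.
#' @param bin_ms Bin width in ms.
#' @param kind One of `"lfp_power"`, `"spike_counts"`, `"rates"`, `"factors"`.
#' @param t0_ms Time of the first bin start in ms (default 0).
#' @param band Optional [frequency_band()] the values were extracted from.
#' @param flags Transform provenance; see `default_feature_flags()` fields.
#' @param channel_ids Optional channel labels.
#' @return An object of class `binned_features`.
#' @export
binned_features <- function(values, bin_ms, kind, t0_ms = 0, band = NULL,
                            flags = NULL, channel_ids = NULL) {
  values <- as.matrix(values)
  kinds <- c("lfp_power", "spike_counts", "rates", "factors")
  kind <- match.arg(kind, kinds)
  if (!is.numeric(values)) stop("binned_features: values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("binned_features: values must be finite")
  }
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || bin_ms <= 0) {
    stop("binned_features: bin_ms must be a positive scalar")
  }
  if (kind == "spike_counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("binned_features: spike_counts must be non-negative integers")
    }
  }
  if (kind == "rates" && any(values <= 0)) {
    stop("binned_features: rates must be strictly positive")
  }
  if (!is.null(band)) stopifnot(inherits(band, "frequency_band"))
  f <- default_feature_flags()
  if (!is.null(flags)) {
    unknown <- setdiff(names(flags), names(f))
    if (length(unknown)) {
      stop("binned_features: unknown flags: ", paste(unknown, collapse = ", "))
    }
    f[names(flags)] <- flags
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(values)))
  if (length(channel_ids) != nrow(values)) {
    stop("binned_features: channel_ids length must equal channel count")
  }
  structure(list(values = values, bin_ms = as.numeric(bin_ms),
                 t0_ms = as.numeric(t0_ms), kind = kind, band = band,
                 flags = f, channel_ids = as.character(channel_ids)),
            class = "binned_features")
}

#' @export
print.binned_features <- function(x, ...) {
  tr <- c(if (isTRUE(x$flags$log_transformed)) "log",
          if (isTRUE(x$flags$zscored)) "zscored",
          if (!is.na(x$flags$smoothed_sd_ms))
            sprintf("smoothed(%gms)", x$flags$smoothed_sd_ms),
          if (!is.na(x$flags$quantized_bits))
            sprintf("%d-bit", x$flags$quantized_bits))
  cat(sprintf("<binned_features:%s> %d ch x %d bins @ %g ms (t0 = %g ms)%s\n",
              x$kind, nrow(x$values), ncol(x$values), x$bin_ms, x$t0_ms,
              if (length(tr)) paste0(" [", paste(tr, collapse = ", "), "]")
              else ""))
  invisible(x)
}

n_bins <- function(x) ncol(x$values)

#' Map a session time (ms) to a bin index
#'
#' Uses the half-open convention: bin `k` (1-based index `k + 1`) covers
#' `[t0_ms + k*bin_ms, t0_ms + (k+1)*bin_ms)`.
#'
#' @param x A [binned_features()].
#' @param t_ms Time(s) in ms.
#' @return 1-based bin indices (may lie outside `1..ncol` for out-of-range t).
#' @export
bin_index <- function(x, t_ms) {
  as.integer(floor((t_ms - x$t0_ms) / x$bin_ms)) + 1L
}

#' Trial table
#'
#' One row per trial: identifiers, start/stop times, optional go cue,
#' condition label, the alignment time filled in by event detection, and an
#' acceptance flag.
#'
#' @param trial_id Integer trial identifiers.
#' @param start_ms,stop_ms Trial bounds in ms; `start_ms < stop_ms`.
#' @param condition_label Condition per trial (reach target index or word).
#' @param go_cue_ms Optional go-cue times (ms).
#' @param align_ms Optional alignment times, normally filled by
#'   [movement_onsets()]; when present must lie within the trial.
#' @param accepted Logical acceptance flags (default `NA`, i.e. undecided).
#' @return A `data.frame` with class `trial_table`.
#' @export
trial_table <- function(trial_id, start_ms, stop_ms, condition_label,
                        go_cue_ms = NA_real_, align_ms = NA_real_,
                        accepted = NA) {
  n <- length(trial_id)
  tt <- data.frame(trial_id = as.integer(trial_id),
                   start_ms = as.numeric(start_ms),
                   stop_ms = as.numeric(stop_ms),
                   go_cue_ms = rep_len(as.numeric(go_cue_ms), n),
                   condition_label = condition_label,
                   align_ms = rep_len(as.numeric(align_ms), n),
                   accepted = rep_len(as.logical(accepted), n),
                   stringsAsFactors = FALSE)
  validate_trial_table(tt)
  class(tt) <- c("trial_table", "data.frame")
  tt
}

validate_trial_table <- function(tt) {
  if (any(tt$start_ms >= tt$stop_ms)) {
    stop("trial_table: start_ms must be < stop_ms for every trial")
  }
  ok <- is.na(tt$align_ms) |
    (tt$align_ms >= tt$start_ms & tt$align_ms <= tt$stop_ms)
  if (!all(ok)) {
    stop("trial_table: align_ms must lie within [start_ms, stop_ms] (trials ",
         paste(tt$trial_id[!ok], collapse = ", "), ")")
  }
  invisible(tt)
}

#' Session bundle
#'
#' One recording session: optional broadband/LFP voltage, a named collection
#' of binned features sharing a bin clock, continuous behavior on the same
#' clock, an optional audio envelope, a trial table, and provenance metadata.
#'
#' @param features Named list of [binned_features()]; all members must share
#'   `bin_ms` and a consistent time origin.
#' @param behavior Time x dims numeric matrix (e.g. cursor velocity in cm/s)
#'   on the feature bin clock, or `NULL`.
#' @param trials A [trial_table()].
#' @param broadband,lfp Optional [broadband_recording()] objects.
#' @param audio_envelope Optional numeric vector (50 Hz envelope).
#' @param meta Free-form provenance list; should record the generator seed or
#'   source file.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(features, trials, behavior = NULL,
                           broadband = NULL, lfp = NULL,
                           audio_envelope = NULL, meta = list()) {
  b <- structure(list(broadband = broadband, lfp = lfp, features = features,
                      behavior = behavior, audio_envelope = audio_envelope,
                      trials = trials, meta = meta),
                 class = "session_bundle")
  validate_session_bundle(b)
  b
}

#' Validate a session bundle
#'
#' Checks member types, the shared bin clock across all binned features, and
#' the trial-table invariants. Called by [session_bundle()], [write_session()]
#' and [read_session()].
#'
#' @param b A `session_bundle`.
#' @return `b`, invisibly; errors name the offending field.
#' @export
validate_session_bundle <- function(b) {
  stopifnot(inherits(b, "session_bundle"))
  if (!is.list(b$features) || is.null(names(b$features)) ||
      any(names(b$features) == "")) {
    stop("session_bundle: features must be a named list")
  }
  for (nm in names(b$features)) {
    if (!inherits(b$features[[nm]], "binned_features")) {
      stop("session_bundle: features$", nm, " is not binned_features")
    }
  }
  if (length(b$features) >= 1L) {
    bins <- vapply(b$features, function(f) f$bin_ms, numeric(1))
    base <- min(bins)
    # Nested clocks are allowed (a 1 ms raster alongside 20 ms features) but
    # every bin width must be an integer multiple of the finest one.
    mult <- bins / base
    if (any(abs(mult - round(mult)) > 1e-9)) {
      stop("session_bundle: feature bin widths are not nested: ",
           paste(unique(bins), collapse = ", "))
    }
    t0 <- vapply(b$features, function(f) f$t0_ms, numeric(1))
    # Members may start on different bins (e.g. STFT warm-up) but must share
    # the same clock phase.
    ph <- (t0 - min(t0)) %% base
    if (any(abs(ph) > 1e-9 & abs(ph - base) > 1e-9)) {
      stop("session_bundle: features t0_ms values are not on a common ",
           "bin clock")
    }
  }
  if (!is.null(b$behavior) && !is.matrix(b$behavior)) {
    stop("session_bundle: behavior must be a time x dims matrix or NULL")
  }
  if (!is.null(b$broadband)) stopifnot(inherits(b$broadband,
                                                "broadband_recording"))
  if (!is.null(b$lfp)) stopifnot(inherits(b$lfp, "broadband_recording"))
  if (!inherits(b$trials, "data.frame")) {
    stop("session_bundle: trials must be a trial_table")
  }
  validate_trial_table(b$trials)
  if (!is.list(b$meta)) stop("session_bundle: meta must be a list")
  invisible(b)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>\n")
  cat(sprintf("  features: %s\n",
              paste(sprintf("%s (%s, %d ch x %d bins)", names(x$features),
                            vapply(x$features, `[[`, "", "kind"),
                            vapply(x$features, function(f) nrow(f$values), 1L),
                            vapply(x$features, function(f) ncol(f$values), 1L)),
                    collapse = "; ")))
  cat(sprintf("  behavior: %s\n",
              if (is.null(x$behavior)) "none"
              else paste(dim(x$behavior), collapse = " x ")))
  cat(sprintf("  trials: %d (%d accepted)\n", nrow(x$trials),
              sum(x$trials$accepted %in% TRUE)))
  invisible(x)
}
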