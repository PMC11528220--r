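# Closed-form analog front-end power model for a wireless iBCI recording
# chain: amplifier power from the noise-efficiency-factor (NEF) relation,
# ADC power from the Schreier figure of merit, wireless transmission rates,
# and scenario comparisons across acquisition bands. Feature extraction is
# treated as free (orders of magnitude below the analog front-end).

#' Amplifier electrical specification
#'
#' @param bandwidth_hz Amplifier signal bandwidth (Hz); by convention the
#'   width of the acquired band (`hi - lo`).
#' @param v_source Supply voltage (V), default 3.3.
#' @param nef Noise efficiency factor (dimensionless), default 4.0.
#' @param v_rms Input-referred noise (V RMS), default 2e-6.
#' @param u_t Thermal voltage (V), default 0.0267.
#' @param temperature Temperature (K), default 310.
#' @param k_boltzmann Boltzmann constant (J/K).
#' @return An `amplifier_spec` list.
#' @export
amplifier_spec <- function(bandwidth_hz, v_source = 3.3, nef = 4.0,
                           v_rms = 2e-6, u_t = 0.0267, temperature = 310,
                           k_boltzmann = 1.38e-23) {
  vals <- c(bandwidth_hz = bandwidth_hz, v_source = v_source, nef = nef,
            v_rms = v_rms, u_t = u_t, temperature = temperature,
            k_boltzmann = k_boltzmann)
  if (any(vals < 0)) stop("amplifier_spec: all fields must be non-negative")
  structure(as.list(vals), class = "amplifier_spec")
}

#' ADC electrical specification
#'
#' @param sampling_bandwidth_hz Sampling bandwidth (Hz), i.e. half the
#'   sampling rate.
#' @param fom_s_db Schreier figure of merit (dB), default 185.
#' @param sndr_db Signal-to-noise-and-distortion ratio (dB), default 96.
#' @return An `adc_spec` list.
#' @export
adc_spec <- function(sampling_bandwidth_hz, fom_s_db = 185, sndr_db = 96) {
  if (sampling_bandwidth_hz <= 0) {
    stop("adc_spec: sampling_bandwidth_hz must be > 0")
  }
  if (fom_s_db <= sndr_db) stop("adc_spec: fom_s_db must exceed sndr_db")
  structure(list(sampling_bandwidth_hz = sampling_bandwidth_hz,
                 fom_s_db = fom_s_db, sndr_db = sndr_db),
            class = "adc_spec")
}

#' One front-end acquisition scenario
#'
#' @param label Scenario name.
#' @param amplifier An [amplifier_spec()].
#' @param adc An [adc_spec()].
#' @return A `front_end_config`.
#' @export
front_end_config <- function(label, amplifier, adc) {
  stopifnot(inherits(amplifier, "amplifier_spec"), inherits(adc, "adc_spec"))
  structure(list(label = label, amplifier = amplifier, adc = adc),
            class = "front_end_config")
}

#' Per-channel amplifier power from the NEF formula
#'
#' `P_amp = V_source * (NEF / V_RMS)^2 * pi * U_T * 4kT * BW / 2`,
#' returned in mW per channel. Linear in bandwidth.
#'
#' @param spec An [amplifier_spec()].
#' @return Power in mW.
#' @export
amplifier_power <- function(spec) {
  stopifnot(inherits(spec, "amplifier_spec"))
  watts <- spec$v_source * (spec$nef / spec$v_rms)^2 *
    pi * spec$u_t * 4 * spec$k_boltzmann * spec$temperature *
    spec$bandwidth_hz / 2
  watts * 1000
}

#' Per-channel ADC power from the Schreier figure of merit
#'
#' `P_ADC = BW / 10^((FoM_s - SNDR) / 10)`, returned in mW per channel.
#' Linear in sampling bandwidth.
#'
#' @param spec An [adc_spec()].
#' @return Power in mW.
#' @export
adc_power <- function(spec) {
  stopifnot(inherits(spec, "adc_spec"))
  watts <- spec$sampling_bandwidth_hz /
    10^((spec$fom_s_db - spec$sndr_db) / 10)
  watts * 1000
}

#' Wireless transmission rate
#'
#' `n_channels * bits_per_sample / bin_s`, in Kbps (1 Kbps = 1000 bps).
#'
#' @param n_channels Channel count.
#' @param bits_per_sample Bits per transmitted sample.
#' @param bin_s Bin (sample) period in seconds.
#' @return Rate in Kbps.
#' @export
transmission_rate <- function(n_channels, bits_per_sample, bin_s) {
  if (any(c(n_channels, bits_per_sample, bin_s) <= 0)) {
    stop("transmission_rate: all arguments must be positive")
  }
  n_channels * bits_per_sample / bin_s / 1000
}

#' Compare two front-end scenarios
#'
#' Total per-channel power (amplifier + ADC) for each scenario in uW, the
#' absolute saving of `a` relative to `b`, and the percent saving
#' (`saving / total_b * 100`).
#'
#' @param a,b [front_end_config()] objects; `a` is the proposed low-power
#'   scenario, `b` the reference.
#' @return A list: `total_a_uw`, `total_b_uw`, `saving_uw`,
#'   `percent_saving`.
#' @export
front_end_comparison <- function(a, b) {
  stopifnot(inherits(a, "front_end_config"), inherits(b, "front_end_config"))
  total <- function(cfg) {
    (amplifier_power(cfg$amplifier) + adc_power(cfg$adc)) * 1000 # mW -> uW
  }
  ta <- total(a); tb <- total(b)
  list(total_a_uw = ta, total_b_uw = tb, saving_uw = tb - ta,
       percent_saving = (tb - ta) / tb * 100)
}

#' The standard acquisition scenarios
#'
#' The nine bands compared in the front-end analysis, each with its
#' amplifier bandwidth (band width) and ADC sampling bandwidth (band upper
#' edge at Nyquist-rate sampling, except that signals acquired at 2 kHz --
#' raw LFP and spike band power -- use 1000 Hz, and the 0-25 Hz band is
#' sampled at 50 Hz).
#'
#' @return A data frame: label, band edges, amplifier and sampling
#'   bandwidths.
#' @export
standard_scenarios <- function() {
  data.frame(
    label = c("high-bandwidth spikes", "low-bandwidth spikes", "raw LFP",
              "SBP", "LFP 150-450", "LFP 100-200", "LFP 50-100",
              "LFP 25-50", "LFP 0-25"),
    lo_hz = c(5, 500, 0, 300, 150, 100, 50, 25, 0),
    hi_hz = c(10000, 3000, 1000, 1000, 450, 200, 100, 50, 25),
    amp_bw_hz = c(9995, 2500, 1000, 700, 300, 100, 50, 25, 25),
    sampling_bw_hz = c(10000, 3000, 1000, 1000, 450, 200, 100, 50, 25),
    stringsAsFactors = FALSE)
}

#' Front-end power table across scenarios
#'
#' Evaluates amplifier and ADC power for each scenario (defaults to
#' [standard_scenarios()]); display columns are rounded to 2 significant
#' figures, full precision is retained in the `_mw` columns.
#'
#' @param scenarios Data frame with columns `label`, `amp_bw_hz`,
#'   `sampling_bw_hz`.
#' @param ... Passed to [amplifier_spec()] / [adc_spec()] to override the
#'   electrical constants.
#' @return A data frame of per-channel powers.
#' @export
scenario_table <- function(scenarios = standard_scenarios(), ...) {
  amp <- vapply(scenarios$amp_bw_hz,
                function(bw) amplifier_power(amplifier_spec(bw, ...)),
                numeric(1))
  adc <- vapply(scenarios$sampling_bw_hz,
                function(bw) adc_power(adc_spec(bw)), numeric(1))
  out <- data.frame(scenarios,
                    amp_mw = amp, adc_mw = adc,
                    amp_mw_2sf = signif(amp, 2), adc_mw_2sf = signif(adc, 2),
                    total_uw = (amp + adc) * 1000,
                    stringsAsFactors = FALSE)
  attr(out, "note") <- paste("Feature-extraction power is treated as zero",
                             "(orders of magnitude below the front-end).")
  out
}
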