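# Synthetic session generator. Emulates the statistical structure the
# modeling pipeline assumes -- low-dimensional rotational latent dynamics
# driving Poisson spiking, coupled LFP band power with slow multiplicative
# drift, a linear velocity readout with bell-shaped speed profiles, and a
# center-out-style trial structure -- so that every downstream stage can be
# exercised and scored against ground truth without real recordings.

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic session generator configuration
#'
#' Defaults describe a desk-scale eight-direction reaching session: ~25
#' spiking channels and 24 LFP-power channels driven by 4 shared latent
#' dimensions, 240 trials of 1.6 s each (~6.4 minutes), 10 Hz mean firing
#' with several-fold movement modulation, LFP power integrating a hidden
#' local population at a 4:1 signal-to-extrinsic-noise ratio, and a 20%
#' multiplicative drift with a 6-minute period.
#'
#' @param n_channels_spk Number of spiking channels (before the optional
#'   duplicated channel is appended).
#' @param n_channels_lfp Number of LFP-power channels.
#' @param latent_dim Latent dimensionality. Rotational dynamics require an
#'   even value >= 4; Lorenz dynamics require exactly 3.
#' @param dynamics `"rotational"` (block-diagonal 2-D rotations with decay,
#'   default) or `"lorenz"` for a nonlinearity stress test.
#' @param n_trials,n_conditions Trial count and number of reach directions
#'   (conditions cycle through trials).
#' @param bin_ms Feature bin width (ms); the analysis clock.
#' @param raster_dt_ms Spike raster resolution (ms).
#' @param base_rate_hz Mean firing rate each channel is calibrated to.
#' @param coupling_snr Ratio of latent-driven to extrinsic noise variance
#'   in log LFP power; `Inf` gives noiseless power (expected hidden
#'   counts, no lognormal noise).
#' @param n_hidden_lfp Size of the latent-driven hidden population whose
#'   realized spiking the LFP band power integrates.
#' @param n_pool_lfp Number of hidden neurons each LFP channel pools.
#' @param drift_amp Relative amplitude of the slow multiplicative drift
#'   applied to LFP power (0 disables).
#' @param drift_period_s Drift period in seconds (>= 300).
#' @param trial_len_ms Trial length (ms); trials are back-to-back.
#' @param baseline_ms Pre-movement hold at the start of each trial (ms).
#' @param rotation_period_ms Period of the movement-generating rotation (ms).
#' @param rotation_decay Per-bin amplitude decay of the rotations.
#' @param peak_speed Peak hand speed (cm/s).
#' @param vel_noise_sd Additive velocity noise SD (cm/s).
#' @param rate_gain Scale of the latent-to-log-rate readout.
#' @param coincident_frac_inject Fraction of 1 ms timesteps turned into
#'   coincident artifacts (spikes added on 60% of channels) to exercise QC.
#' @param duplicate_channel Append a perfect copy of channel 1 to the spike
#'   raster so correlated-channel QC has something to remove?
#' @param seed RNG seed; the generated session is a pure function of the
#'   whole configuration including the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_channels_spk = 25, n_channels_lfp = 24,
                             latent_dim = 4,
                             dynamics = c("rotational", "lorenz"),
                             n_trials = 240, n_conditions = 8,
                             bin_ms = 20, raster_dt_ms = 1,
                             base_rate_hz = 10, coupling_snr = 4,
                             drift_amp = 0.2, drift_period_s = 360,
                             trial_len_ms = 1600, baseline_ms = 400,
                             rotation_period_ms = 300, rotation_decay = 0.9,
                             peak_speed = 10, vel_noise_sd = 0.2,
                             rate_gain = 3,
                             n_hidden_lfp = 128, n_pool_lfp = 24,
                             coincident_frac_inject = 0.002,
                             duplicate_channel = TRUE, seed = 0) {
  dynamics <- match.arg(dynamics)
  cfg <- as.list(environment())
  counts <- c(n_channels_spk = n_channels_spk, n_channels_lfp = n_channels_lfp,
              latent_dim = latent_dim, n_trials = n_trials,
              n_conditions = n_conditions)
  if (any(counts <= 0)) {
    stop("generator_config: all counts must be positive (",
         paste(names(counts)[counts <= 0], collapse = ", "), ")")
  }
  if (dynamics == "rotational" && (latent_dim < 4 || latent_dim %% 2 != 0)) {
    stop("generator_config: rotational dynamics need an even latent_dim >= 4")
  }
  if (dynamics == "lorenz" && latent_dim != 3) {
    stop("generator_config: lorenz dynamics need latent_dim = 3")
  }
  if (!(coupling_snr > 0)) stop("generator_config: coupling_snr must be > 0")
  if (base_rate_hz * bin_ms <= 0) {
    stop("generator_config: base_rate_hz * bin must be > 0")
  }
  if (drift_amp > 0 && drift_period_s < 300) {
    stop("generator_config: drift_period_s must be >= 300 s")
  }
  if (trial_len_ms %% bin_ms != 0 || baseline_ms %% bin_ms != 0) {
    stop("generator_config: trial_len_ms and baseline_ms must be multiples ",
         "of bin_ms")
  }
  structure(cfg, class = "generator_config")
}

# block-diagonal rotation-with-decay transition matrix on the bin clock
rotation_transition <- function(cfg) {
  L <- cfg$latent_dim
  A <- matrix(0, L, L)
  periods <- numeric(L / 2)
  periods[1:2] <- cfg$rotation_period_ms
  if (L > 4) {
    # extra blocks: fixed spread of periods in the 150-400 ms range
    k <- L / 2 - 2
    periods[3:(L / 2)] <- seq(150, 400, length.out = k)
  }
  for (j in seq_len(L / 2)) {
    om <- 2 * pi * cfg$bin_ms / periods[j]
    rot <- cfg$rotation_decay * matrix(c(cos(om), sin(om),
                                         -sin(om), cos(om)), 2, 2)
    idx <- (2 * j - 1):(2 * j)
    A[idx, idx] <- rot
  }
  A
}

# condition-dependent initial state: direction (cos, sin) split across the
# first two rotation blocks so the readout of coordinates 2 and 4 traces a
# bell-shaped reach at angle theta
condition_ic <- function(cfg, theta) {
  L <- cfg$latent_dim
  z0 <- numeric(L)
  z0[1] <- cos(theta)
  z0[3] <- sin(theta)
  if (L > 4) {
    for (j in 3:(L / 2)) {
      idx <- (2 * j - 1):(2 * j)
      z0[idx] <- 0.5 * c(cos((j - 1) * theta), sin((j - 1) * theta))
    }
  }
  z0
}

lorenz_step <- function(z, dt_s) {
  # classic parameters, state scaled down to O(1) for the readouts
  s <- 10; r <- 28; b <- 8 / 3
  x <- z * 10
  dx <- c(s * (x[2] - x[1]),
          x[1] * (r - x[3]) - x[2],
          x[1] * x[2] - b * x[3])
  (x + dt_s * dx) / 10
}

# first upward crossing of 70% of peak within the search window; returns
# list(first, last, peak) of crossing bin indices relative to the window
speed_crossings <- function(speed, peak_frac = 0.7) {
  if (length(speed) < 2L) return(list(first = NA, last = NA))
  thr <- peak_frac * max(speed)
  up <- which(speed[-1] >= thr & speed[-length(speed)] < thr) + 1L
  if (length(up) == 0L) return(list(first = NA, last = NA))
  list(first = up[1], last = up[length(up)])
}

#' Generate a synthetic recording session with ground truth
#'
#' Builds one continuous session per the configuration: latent trajectories
#' evolve under the chosen dynamics with a condition-dependent impulse at
#' each movement onset; ground-truth rates are `exp(W_r z + b_r)` calibrated
#' so each channel's mean rate equals `base_rate_hz`; spikes are Poisson
#' draws on the 1 ms raster (plus injected coincident artifacts and one
#' duplicated channel for QC); LFP power is
#' `softplus(W_p z + b_p) * (1 + drift) * lognormal noise`; behavior is a
#' linear velocity readout with bell-shaped speed profiles.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements
#'   \describe{
#'     \item{bundle}{A [session_bundle()] with features `lfp_power` (20 ms),
#'       `spikes_1ms` (raster), behavior (velocity), and a trial table.}
#'     \item{truth}{Ground truth: latents `z` (latent x bins), `rates`
#'       (channels x bins, spikes/bin, including the duplicated channel),
#'       `onset_ms` per trial, the readout matrices, and the config.}
#'   }
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_local_seed(cfg$seed, {
    bins_per_trial <- cfg$trial_len_ms / cfg$bin_ms
    n_bins <- cfg$n_trials * bins_per_trial
    L <- cfg$latent_dim
    bin_s <- cfg$bin_ms / 1000

    conditions <- ((seq_len(cfg$n_trials) - 1L) %% cfg$n_conditions) + 1L
    thetas <- 2 * pi * (conditions - 1) / cfg$n_conditions
    start_ms <- (seq_len(cfg$n_trials) - 1) * cfg$trial_len_ms
    move_bin <- (start_ms + cfg$baseline_ms) / cfg$bin_ms + 1L # 1-based

    if (cfg$dynamics == "rotational") {
      A <- rotation_transition(cfg)
      step_fn <- function(z) as.numeric(A %*% z)
    } else {
      step_fn <- function(z) lorenz_step(z, bin_s)
    }

    # noiseless unit response of the movement blocks, used to scale velocity
    # and to compute ground-truth onsets
    unit_resp <- matrix(0, L, bins_per_trial)
    z <- condition_ic(cfg, 0)
    for (t in seq_len(bins_per_trial)) {
      unit_resp[, t] <- z
      z <- step_fn(z)
    }
    unit_speed <- sqrt(unit_resp[2, ]^2 + if (L >= 4) unit_resp[4, ]^2 else 0)
    vel_scale <- cfg$peak_speed / max(unit_speed)

    # latent trajectory: continuous evolution with condition impulses
    sigma_z <- 0.02
    Z <- matrix(0, L, n_bins)
    z <- numeric(L)
    trial_of_bin <- rep(seq_len(cfg$n_trials), each = bins_per_trial)
    for (t in seq_len(n_bins)) {
      tr <- trial_of_bin[t]
      if (t == move_bin[tr]) z <- z + condition_ic(cfg, thetas[tr])
      Z[, t] <- z
      z <- step_fn(z) + stats::rnorm(L, sd = sigma_z)
    }

    # behavior: velocity reads the second coordinate of each movement block
    W_v <- matrix(0, 2, L)
    W_v[1, 2] <- vel_scale
    if (L >= 4) W_v[2, 4] <- vel_scale
    vel_clean <- W_v %*% Z
    velocity <- t(vel_clean +
                    matrix(stats::rnorm(2 * n_bins, sd = cfg$vel_noise_sd),
                           2, n_bins))
    colnames(velocity) <- c("vx", "vy")

    # ground-truth onsets from the noiseless speed, same 70%-of-peak upward
    # crossing rule the event detector uses, searched from 250 ms after start
    speed_clean <- sqrt(vel_clean[1, ]^2 + vel_clean[2, ]^2)
    search_off_bins <- 250 %/% cfg$bin_ms
    onset_ms <- rep(NA_real_, cfg$n_trials)
    for (i in seq_len(cfg$n_trials)) {
      a <- (i - 1L) * bins_per_trial + 1L + search_off_bins
      b <- i * bins_per_trial
      cr <- speed_crossings(speed_clean[a:b])
      if (!is.na(cr$first)) {
        onset_ms[i] <- ((a - 1L) + (cr$first - 1L)) * cfg$bin_ms
      }
    }

    # ground-truth rates, calibrated to base_rate_hz per channel. Readout
    # rows are random directions of fixed norm rate_gain, so every channel
    # modulates by the same log-depth (motor-cortex-like several-fold
    # swings) with no heavy-tailed outlier channels.
    C <- cfg$n_channels_spk
    unit_rows <- function(n, d) {
      W <- matrix(stats::rnorm(n * d), n, d)
      W / sqrt(rowSums(W^2))
    }
    W_r <- cfg$rate_gain * unit_rows(C, L)
    eta <- W_r %*% Z
    b_r <- log(cfg$base_rate_hz * bin_s) - log(rowMeans(exp(eta)))
    rates <- exp(eta + b_r) # spikes per 20 ms bin

    # Poisson raster at raster_dt_ms resolution
    steps_per_bin <- cfg$bin_ms / cfg$raster_dt_ms
    n_steps <- n_bins * steps_per_bin
    rate_ms <- rates[, rep(seq_len(n_bins), each = steps_per_bin),
                     drop = FALSE] / steps_per_bin
    raster <- matrix(stats::rpois(length(rate_ms), rate_ms), nrow = C)

    # coincident artifacts: spikes added on 60% of channels at random steps
    n_art <- round(cfg$coincident_frac_inject * n_steps)
    artifact_steps <- integer(0)
    if (n_art > 0) {
      artifact_steps <- sort(sample.int(n_steps, n_art))
      n_hit <- max(ceiling(0.6 * C), floor(0.3 * C) + 1L)
      for (t in artifact_steps) {
        ch <- sample.int(C, n_hit)
        raster[ch, t] <- raster[ch, t] + 1L
      }
    }

    channel_ids <- paste0("spk", seq_len(C))
    truth_rates <- rates
    if (cfg$duplicate_channel) {
      raster <- rbind(raster, raster[1, ])
      truth_rates <- rbind(truth_rates, rates[1, ])
      channel_ids <- c(channel_ids, "spk1_dup")
    }

    # LFP band power: the 150-450 Hz band integrates the spiking energy of
    # the local population, most of which is never isolated as a recorded
    # unit. Each power channel therefore pools the realized 20 ms spiking
    # of a random subset of a latent-driven hidden population through a
    # softplus, times slow drift and extrinsic lognormal noise scaled by
    # coupling_snr. Poisson shot noise of the hidden population is thus
    # inherent to the power signal (independent of the recorded units'
    # noise given the latent state). In the noiseless limit
    # (coupling_snr = Inf) the drive uses the expected hidden counts, so
    # power is a deterministic softplus readout of the latent state.
    P <- cfg$n_channels_lfp
    Hn <- cfg$n_hidden_lfp
    W_h <- cfg$rate_gain * unit_rows(Hn, L)
    eta_h <- W_h %*% Z
    b_h <- log(cfg$base_rate_hz * bin_s) - log(rowMeans(exp(eta_h)))
    rates_h <- exp(eta_h + b_h)
    M_lfp <- matrix(0, P, Hn)
    for (ci in seq_len(P)) {
      src <- sample.int(Hn, min(cfg$n_pool_lfp, Hn))
      M_lfp[ci, src] <- stats::runif(length(src), 0.5, 1.5)
    }
    M_lfp <- M_lfp / rowSums(M_lfp)
    drive_counts <- if (is.finite(cfg$coupling_snr)) {
      matrix(stats::rpois(length(rates_h), rates_h), Hn, n_bins)
    } else rates_h
    mix <- M_lfp %*% drive_counts
    mix_mean <- rowMeans(mix)
    mix_sd <- pmax(apply(mix, 1, stats::sd), 1e-12)
    sig <- softplus((mix - mix_mean) / mix_sd + 0.5)
    drift <- if (cfg$drift_amp > 0) {
      tt <- (seq_len(n_bins) - 0.5) * bin_s
      1 + cfg$drift_amp * sin(2 * pi * tt / cfg$drift_period_s)
    } else rep(1, n_bins)
    log_sig <- log(sig)
    sd_log <- apply(log_sig, 1, stats::sd)
    sigma_ln <- if (is.finite(cfg$coupling_snr)) sd_log / sqrt(cfg$coupling_snr)
                else rep(0, P)
    noise <- exp(matrix(stats::rnorm(P * n_bins), P, n_bins) * sigma_ln)
    lfp_power <- sig * rep(drift, each = P) * noise

    trials <- trial_table(trial_id = seq_len(cfg$n_trials),
                          start_ms = start_ms,
                          stop_ms = start_ms + cfg$trial_len_ms,
                          go_cue_ms = start_ms + cfg$baseline_ms,
                          condition_label = conditions)

    bundle <- session_bundle(
      features = list(
        lfp_power = binned_features(lfp_power, cfg$bin_ms, "lfp_power",
                                    band = frequency_band(150, 450)),
        spikes_1ms = binned_features(raster, cfg$raster_dt_ms, "spike_counts",
                                     channel_ids = channel_ids)),
      behavior = velocity,
      trials = trials,
      meta = list(generator = "lfpdyn::generate_session", seed = cfg$seed,
                  config = unclass(cfg)))

    truth <- list(z = Z, rates = truth_rates, onset_ms = onset_ms,
                  speed_clean = speed_clean,
                  W_r = W_r, b_r = b_r, W_v = W_v,
                  lfp_readout = list(M = M_lfp, W_h = W_h, b_h = b_h,
                                     mix_mean = mix_mean, mix_sd = mix_sd,
                                     offset = 0.5),
                  artifact_steps = artifact_steps, config = cfg)
    list(bundle = bundle, truth = truth)
  })
}

#' Generate a sinusoid-plus-noise broadband fixture
#'
#' A deterministic-frequency test signal for exercising the STFT band-power
#' and filtering paths independently of the session generator.
#'
#' @param freq_hz Tone frequency (Hz); may be a vector (one component each).
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Duration (s).
#' @param amplitude Tone amplitude (uV), recycled across `freq_hz`.
#' @param noise_sd Additive white noise SD (uV).
#' @param n_channels Number of identical-statistics channels.
#' @param seed RNG seed for the noise.
#' @return A [broadband_recording()].
#' @export
generate_broadband_tone <- function(freq_hz, fs_hz = 2000, duration_s = 2,
                                    amplitude = 1, noise_sd = 0,
                                    n_channels = 1, seed = 0) {
  n <- round(fs_hz * duration_s)
  t <- (seq_len(n) - 1) / fs_hz
  amplitude <- rep_len(amplitude, length(freq_hz))
  tone <- rep(0, n)
  for (i in seq_along(freq_hz)) {
    tone <- tone + amplitude[i] * sin(2 * pi * freq_hz[i] * t)
  }
  with_local_seed(seed, {
    samples <- matrix(rep(tone, each = n_channels), n_channels, n) +
      matrix(stats::rnorm(n_channels * n, sd = noise_sd), n_channels, n)
    broadband_recording(samples, fs_hz)
  })
}
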