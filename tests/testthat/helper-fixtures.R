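# Shared fixtures, built once per test run and cached so the expensive
# pieces (session generation, preprocessing, model training) are reused
# across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

default_session <- function(seed = 0) {
  cached(paste0("session_", seed),
         generate_session(generator_config(seed = seed)))
}

# Standard preprocessing of a generated session: spike QC + 20 ms binning,
# log + causal z-score of LFP power, movement-onset alignment, and the
# ground-truth rates restricted to the QC-surviving channels.
prep_session <- function(seed = 0) {
  cached(paste0("prep_", seed), {
    sess <- default_session(seed)
    b <- sess$bundle
    cl <- clean_and_bin_spikes(b$features$spikes_1ms)
    spk <- cl$features
    lfp <- log_and_causal_zscore(b$features$lfp_power)
    speed <- sqrt(rowSums(b$behavior^2))
    trials <- movement_onsets(speed, b$trials)
    kept <- setdiff(seq_len(nrow(sess$truth$rates)), cl$removed_idx)
    truth_rates <- binned_features(sess$truth$rates[kept, , drop = FALSE],
                                   b$features$spikes_1ms$bin_ms * 20, "rates")
    list(sess = sess, bundle = b, clean = cl, spk = spk, lfp = lfp,
         trials = trials, truth_rates = truth_rates,
         velocity = b$behavior)
  })
}

# Segments for dynamics-model training on the standard session.
prep_segments <- function(seed = 0) {
  cached(paste0("segs_", seed), {
    pp <- prep_session(seed)
    segment_continuous(pp$lfp, target = pp$spk,
                       window_ms = 1000, overlap_ms = 200)
  })
}

# Trained LFP-input model on the standard session for a given seed.
lfp_model <- function(seed = 0) {
  cached(paste0("lfp_model_", seed), {
    pp <- prep_session(seed)
    segs <- prep_segments(seed)
    cfg <- model_config(input_kind = "lfp_power",
                        n_in = nrow(pp$lfp$values),
                        n_out = nrow(pp$spk$values), seed = seed)
    train_dynamics(build_model(cfg), segs)
  })
}

spikes_model <- function(seed = 0) {
  cached(paste0("spk_model_", seed), {
    pp <- prep_session(seed)
    segs <- segment_continuous(pp$spk, target = pp$spk,
                               window_ms = 1000, overlap_ms = 200)
    cfg <- model_config(input_kind = "spikes",
                        n_in = nrow(pp$spk$values),
                        n_out = nrow(pp$spk$values), seed = seed)
    train_dynamics(build_model(cfg), segs)
  })
}

# Merged acausal rate stream for a trained model.
model_rates <- function(model, segs, key) {
  cached(paste0("rates_", key), infer_acausal(model, segs))
}

# A tiny model configuration for fast unit tests.
tiny_model_config <- function(co_dim = 2, seed = 7, ...) {
  model_config(input_kind = "lfp_power", n_in = 3, n_out = 4,
               encoder_dim = 5, generator_dim = 6, controller_dim = 4,
               ic_dim = 3, co_dim = co_dim, factor_dim = 3,
               l2_gen = 1e-3, l2_con = 1e-3, seed = seed, ...)
}
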