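# Shared fixture builders: everything is generated in code at test time.

std_time <- function() seq(-100, 500, by = 2)

# Minimal epoch set around explicit PO7/PO8 traces (one trial).
epochs_from_traces <- function(po7, po8, extra = list(), time = std_time(),
                               trials = NULL) {
  chans <- c("PO7", "PO8", names(extra))
  dat <- array(0, dim = c(1, length(chans), length(time)))
  dat[1, 1, ] <- po7
  dat[1, 2, ] <- po8
  for (i in seq_along(extra)) dat[1, 2 + i, ] <- extra[[i]]
  eeg_epochs(dat, chans, time, 500, trials)
}

# Epoch set with given per-trial x per-channel constant values or traces.
epochs_from_matrix <- function(traces, channels, time = std_time(),
                               trials = NULL) {
  # traces: list (per trial) of list (per channel) of traces
  n_tr <- length(traces)
  dat <- array(0, dim = c(n_tr, length(channels), length(time)))
  for (i in seq_len(n_tr)) {
    for (j in seq_along(channels)) dat[i, j, ] <- traces[[i]][[j]]
  }
  eeg_epochs(dat, channels, time, 500, trials)
}

# A difference wave from explicit values.
wave_of <- function(values, time = std_time()) {
  stopifnot(length(values) == length(time))
  structure(list(values = values, time = time, condition = NULL,
                 participant_id = NULL), class = "difference_wave")
}

# Smooth random waves with negative excursions (band-limited noise).
random_smooth_wave <- function(time = std_time(), sd = 1) {
  n <- length(time)
  k <- 8
  phases <- stats::runif(k, 0, 2 * pi)
  freqs <- stats::runif(k, 2, 12)                 # Hz
  amps <- stats::rnorm(k, 0, sd)
  v <- rep(0, n)
  for (j in seq_len(k)) {
    v <- v + amps[j] * sin(2 * pi * freqs[j] * time / 1000 + phases[j])
  }
  v
}

# A 19-participant cohort at the simulated study conditions: 98 trials per
# symbol-position condition of Exemplar Match trials, -2 uV raised-cosine
# negativity (width 120 ms) at the given onsets, 10 uV noise, 40 Hz
# low-pass filtering and baseline correction; returns per-participant
# patterned/random difference waves.
recovery_cohort <- function(seed, onset_patterned = 180, onset_random = 180) {
  lapply(1:19, function(i) {
    sched <- generate_design(
      7, c(exemplar_match = 28, foil = 0, target_absent = 0),
      pattern_side = if (i %% 2) "left" else "right", seed = seed * 100 + i)
    truth <- ground_truth(
      amplitude_uv = -2,
      onset_ms = c(onset_patterned, onset_random,
                   onset_patterned, onset_random),
      width_ms = 120, noise_sd_uv = 10, artifact_rate = 0)
    ep <- simulate_epochs(sched, truth, seed = seed * 100 + 50 + i,
                          scalp_channels = c("PO7", "PO8"),
                          include_eog = FALSE)
    ep <- filter_epochs(ep, filter_spec(highpass_hz = NULL, notch_hz = NULL))
    ep <- baseline_correct(ep)
    list(patterned = difference_wave(
           condition_average(ep, "patterned", "exemplar_match", i)),
         random = difference_wave(
           condition_average(ep, "random", "exemplar_match", i)))
  })
}

# Trial metadata for hand-built epochs.
trial_meta <- function(trial_type, item_side, pattern_side = "left",
                       correct = TRUE) {
  data.frame(
    block_index = 1L, trial_index = seq_along(trial_type),
    trial_type = trial_type, item_side = item_side,
    pattern_side = pattern_side,
    symbol_position = ifelse(trial_type == "target_absent", NA,
                             ifelse(item_side == pattern_side,
                                    "patterned", "random")),
    response = "present", correct = correct, rt_ms = 500,
    stringsAsFactors = FALSE
  )
}
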