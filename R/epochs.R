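#' Construct an epoched EEG container
#'
#' Holds a trials x channels x samples voltage array (microvolts) together
#' with its channel labels, sampling rate, time axis and per-trial metadata.
#' The posterior electrodes PO7 and PO8 must each be present exactly once;
#' the time axis must be an arithmetic grid at the sampling interval.
#'
#' @param data Numeric array `[n_trials, n_channels, n_samples]` in uV.
#' @param channels Character vector of channel labels (axis 2).
#' @param time Numeric time axis in ms (axis 3), e.g. -100..500 at 500 Hz.
#' @param srate Sampling rate in Hz.
#' @param trials Data frame of per-trial metadata aligned to axis 1
#'   (typically a schedule from [generate_design()]).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, channels, time, srate, trials = NULL) {
  if (length(dim(data)) != 3L) stop("data must be a 3-axis array")
  if (dim(data)[2] != length(channels)) {
    stop("channel axis length (", dim(data)[2], ") != number of labels (",
         length(channels), ")")
  }
  if (dim(data)[3] != length(time)) {
    stop("sample axis length (", dim(data)[3], ") != length of time axis (",
         length(time), ")")
  }
  if (anyDuplicated(channels)) stop("duplicated channel labels")
  if (sum(channels == "PO7") != 1L || sum(channels == "PO8") != 1L) {
    stop("channels must include PO7 and PO8 exactly once")
  }
  step <- 1000 / srate
  if (length(time) > 1L &&
      max(abs(diff(time) - step)) > 1e-6 * step) {
    stop("time axis must increase in constant steps of 1000/srate ms")
  }
  if (!is.null(trials) && nrow(trials) != dim(data)[1]) {
    stop("trial metadata rows (", nrow(trials), ") != trial axis length (",
         dim(data)[1], ")")
  }
  structure(
    list(data = data, channels = channels, time = time, srate = srate,
         trials = trials),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$srate, " Hz\n", sep = "")
  cat("  time: ", x$time[1], "..", x$time[length(x$time)], " ms\n", sep = "")
  if (!is.null(x$trials) && "trial_type" %in% names(x$trials)) {
    tt <- table(x$trials$trial_type)
    cat("  trials:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Keep a subset of trials of an epoch set
#'
#' @param epochs An `eeg_epochs` object.
#' @param keep Logical or integer index over the trial axis.
#' @return An `eeg_epochs` with the selected trials, order preserved.
#' @export
subset_trials <- function(epochs, keep) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dat <- epochs$data[keep, , , drop = FALSE]
  tr <- if (!is.null(epochs$trials)) epochs$trials[keep, , drop = FALSE]
  eeg_epochs(dat, epochs$channels, epochs$time, epochs$srate, tr)
}

chan_index <- function(epochs, label) {
  i <- match(label, epochs$channels)
  if (anyNA(i)) stop("channel(s) not found: ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

#' Default 30-channel scalp montage
#'
#' Extended 10/20 scalp labels used by the synthetic recordings (EOG and
#' earlobe reference channels are added separately by [simulate_epochs()]).
#'
#' @return Character vector of 30 scalp labels, including PO7 and PO8.
#' @export
default_scalp_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO8", "O1", "Oz", "O2")
}

#' Ground-truth component parameters for the simulator
#'
#' One row per analysis condition (symbol position x trial type) giving the
#' injected contralateral negativity: peak amplitude (uV, <= 0), onset and
#' duration of a raised-cosine pulse, plus per-condition noise sd and the
#' probability of an injected ocular artifact.  Scalars are recycled across
#' the four conditions.  The defaults encode the simulated study conditions:
#' a -2 uV, 120 ms wide negativity at 180 ms onset in 10 uV r.m.s. noise.
#'
#' @param amplitude_uv Peak amplitude of the injected negativity (<= 0).
#' @param onset_ms Pulse onset relative to search-array onset.
#' @param width_ms Pulse duration (> 0).
#' @param noise_sd_uv Standard deviation of the additive noise (>= 0).
#' @param artifact_rate Per-trial probability of an injected HEOG artifact.
#' @return Data frame of class `ground_truth` with columns
#'   `symbol_position`, `trial_type`, `amplitude_uv`, `onset_ms`,
#'   `width_ms`, `noise_sd_uv`, `artifact_rate`.
#' @export
ground_truth <- function(amplitude_uv = -2, onset_ms = 180, width_ms = 120,
                         noise_sd_uv = 10, artifact_rate = 0.05) {
  g <- expand.grid(symbol_position = c("patterned", "random"),
                   trial_type = c("exemplar_match", "foil"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$amplitude_uv <- rep_len(amplitude_uv, 4L)
  g$onset_ms <- rep_len(onset_ms, 4L)
  g$width_ms <- rep_len(width_ms, 4L)
  g$noise_sd_uv <- rep_len(noise_sd_uv, 4L)
  g$artifact_rate <- rep_len(artifact_rate, 4L)
  if (any(g$amplitude_uv > 0)) stop("amplitude_uv must be <= 0")
  if (any(g$width_ms <= 0)) stop("width_ms must be > 0")
  if (any(g$noise_sd_uv < 0)) stop("noise_sd_uv must be >= 0")
  if (any(g$artifact_rate < 0 | g$artifact_rate > 1)) {
    stop("artifact_rate must lie in [0, 1]")
  }
  class(g) <- c("ground_truth", "data.frame")
  g
}

#' Raised-cosine component pulse
#'
#' The injected component waveform: `amplitude/2 * (1 - cos(2*pi*(t -
#' onset)/width))` on `[onset, onset + width]`, zero elsewhere.  Smooth,
#' compactly supported and analytically integrable, which makes closed-form
#' oracles for amplitude, area and latency measures straightforward.
#'
#' @param time Time axis in ms.
#' @param amplitude_uv Peak value (negative for an N2pc-like deflection).
#' @param onset_ms,width_ms Support of the pulse.
#' @return Numeric vector along `time`.
#' @export
raised_cosine_pulse <- function(time, amplitude_uv, onset_ms, width_ms) {
  y <- numeric(length(time))
  inside <- time >= onset_ms & time <= onset_ms + width_ms
  y[inside] <- amplitude_uv / 2 *
    (1 - cos(2 * pi * (time[inside] - onset_ms) / width_ms))
  y
}

# n x s matrix of unit-sd noise: equal-power mix of white and 1/f-shaped
# Gaussian noise, generated in the frequency domain.
noise_matrix <- function(n, n_samples, srate) {
  white <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  if (n_samples < 4L) return(white)
  # 1/f amplitude shaping of white noise via FFT along the sample axis
  freqs <- seq(0, srate, length.out = n_samples + 1L)[seq_len(n_samples)]
  half <- freqs > srate / 2
  freqs[half] <- srate - freqs[half]            # fold to physical frequency
  shape <- ifelse(freqs < 1, 0, 1 / sqrt(freqs))
  z <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  spec <- t(stats::mvfft(t(z))) * rep(shape, each = n)
  pink <- Re(t(stats::mvfft(t(spec), inverse = TRUE))) / n_samples
  psd <- stats::sd(as.vector(pink))
  if (psd > 0) pink <- pink / psd
  (white + pink) / sqrt(2)
}

#' Simulate epoched EEG for a trial schedule
#'
#' For every item-present trial a raised-cosine negativity with the
#' condition's ground-truth parameters is injected into the posterior
#' channel contralateral to the item (PO8 for left items, PO7 for right
#' items); the ipsilateral channel receives no component.  All channels get
#' additive noise (equal-power white + 1/f Gaussian mix, independent per
#' channel and trial).  With probability `artifact_rate` a trial receives a
#' square HEOG excursion (40 uV, 100-250 ms) that exceeds the +-25 uV
#' rejection criterion; the injected-artifact flag is recorded in the trial
#' metadata as ground truth.  A trial's condition is `patterned` iff its
#' item appeared on the participant's `pattern_side`.
#'
#' @param schedule Schedule from [generate_design()] (behavior optional).
#' @param truth A [ground_truth()] table covering all four conditions.
#' @param seed Integer seed; identical seeds give identical arrays.
#' @param scalp_channels Scalp montage (must contain PO7 and PO8).
#' @param include_eog,include_earlobes Add HEOG/VEOG and A1/A2 channels.
#' @param srate Sampling rate in Hz (default 500).
#' @param epoch_ms Epoch limits in ms relative to array onset.
#' @return An [eeg_epochs()] object; `trials` carries the schedule plus
#'   `symbol_position` and logical `artifact_injected`.
#' @export
simulate_epochs <- function(schedule, truth = ground_truth(), seed = NULL,
                            scalp_channels = default_scalp_channels(),
                            include_eog = TRUE, include_earlobes = FALSE,
                            srate = 500, epoch_ms = c(-100, 500)) {
  stopifnot(inherits(truth, "ground_truth"))
  time <- seq(epoch_ms[1], epoch_ms[2], by = 1000 / srate)
  if (any(truth$onset_ms < epoch_ms[1]) ||
      any(truth$onset_ms + truth$width_ms > epoch_ms[2])) {
    stop("ground-truth pulse (onset + width) must lie inside the epoch")
  }
  channels <- c(scalp_channels,
                if (include_eog) c("HEOG", "VEOG"),
                if (include_earlobes) c("A1", "A2"))
  n_tr <- nrow(schedule)
  n_ch <- length(channels)
  n_s <- length(time)

  sched <- schedule
  sched$symbol_position <- ifelse(
    sched$trial_type == "target_absent", NA_character_,
    ifelse(sched$item_side == sched$pattern_side, "patterned", "random"))

  key <- paste(truth$symbol_position, truth$trial_type)
  trial_key <- paste(sched$symbol_position, sched$trial_type)
  cond_row <- match(trial_key, key)              # NA for target_absent
  if (any(is.na(cond_row) & sched$trial_type != "target_absent")) {
    stop("ground truth lacks parameters for some schedule conditions")
  }

  with_seed(seed, {
    data <- array(0, dim = c(n_tr, n_ch, n_s))
    # noise, generated trial-major for reproducibility
    noise_sd <- ifelse(is.na(cond_row), mean(truth$noise_sd_uv),
                       truth$noise_sd_uv[ifelse(is.na(cond_row), 1L,
                                                cond_row)])
    for (ch in seq_len(n_ch)) {
      data[, ch, ] <- data[, ch, ] + noise_matrix(n_tr, n_s, srate) * noise_sd
    }
    # lateralized component
    i_po7 <- match("PO7", channels)
    i_po8 <- match("PO8", channels)
    for (i in seq_len(n_tr)) {
      r <- cond_row[i]
      if (is.na(r)) next                         # target_absent: no signal
      contra <- if (sched$item_side[i] == "left") i_po8 else i_po7
      data[i, contra, ] <- data[i, contra, ] +
        raised_cosine_pulse(time, truth$amplitude_uv[r], truth$onset_ms[r],
                            truth$width_ms[r])
    }
    # ocular artifacts
    art_rate <- ifelse(is.na(cond_row), mean(truth$artifact_rate),
                       truth$artifact_rate[ifelse(is.na(cond_row), 1L,
                                                  cond_row)])
    injected <- stats::runif(n_tr) < art_rate
    if (include_eog && any(injected)) {
      i_heog <- match("HEOG", channels)
      art_win <- time >= 100 & time <= 250
      sign <- sample(c(-1, 1), sum(injected), replace = TRUE)
      data[injected, i_heog, art_win] <-
        data[injected, i_heog, art_win] + 40 * sign
    }
    sched$artifact_injected <- injected
    eeg_epochs(data, channels, time, srate, sched)
  })
}

#' Simulate a full cohort
#'
#' Convenience generator for a multi-participant study: per participant a
#' schedule, simulated behavior, a 2AFC block and an epoch array, with the
#' patterned-stream side counterbalanced across participants.
#'
#' @param n_participants Number of participants (default 19).
#' @param n_blocks Blocks per participant (default 7).
#' @param truth Ground-truth table, shared across participants.
#' @param rt_model Behavioral model as in [simulate_behavior()].
#' @param p_2afc True-triplet choice probability in the recognition test.
#' @param seed Master seed; per-participant seeds are derived from it.
#' @param ... Further arguments passed to [simulate_epochs()].
#' @return List of participants, each a list with `id`, `schedule`,
#'   `epochs`, `afc`.
#' @export
simulate_study <- function(n_participants = 19, n_blocks = 7,
                           truth = ground_truth(),
                           rt_model = default_rt_model(),
                           p_2afc = 0.5, seed = NULL, ...) {
  stopifnot(n_participants >= 1)
  lapply(seq_len(n_participants), function(i) {
    side <- if (i %% 2L == 1L) "left" else "right"
    sched <- generate_design(n_blocks = n_blocks, pattern_side = side,
                             seed = derive_seed(seed, i))
    sched <- simulate_behavior(sched, rt_model,
                               seed = derive_seed(seed, 1000 + i))
    ep <- simulate_epochs(sched, truth, seed = derive_seed(seed, 2000 + i),
                          ...)
    afc <- simulate_2afc(p_correct = p_2afc,
                         seed = derive_seed(seed, 3000 + i))
    list(id = i, schedule = ep$trials, epochs = ep, afc = afc)
  })
}
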