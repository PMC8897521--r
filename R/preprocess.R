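#' Artifact rejection criteria
#'
#' Amplitude thresholds per channel class with the window (ms) in which each
#' is checked: horizontal EOG +-25 uV in 0-300 ms, vertical EOG +-60 uV in
#' 0-300 ms, all other channels +-80 uV over the whole -100..500 ms epoch.
#' "Exceeding" is read as absolute instantaneous amplitude `|v| > threshold`
#' at any sample inside the closed window.
#'
#' @param heog_abs_uv,veog_abs_uv,other_abs_uv Thresholds in uV (> 0).
#' @param heog_window_ms,veog_window_ms,other_window_ms Closed windows (ms).
#' @return A list of class `rejection_criteria`.
#' @export
rejection_criteria <- function(heog_abs_uv = 25, heog_window_ms = c(0, 300),
                               veog_abs_uv = 60, veog_window_ms = c(0, 300),
                               other_abs_uv = 80,
                               other_window_ms = c(-100, 500)) {
  if (any(c(heog_abs_uv, veog_abs_uv, other_abs_uv) <= 0)) {
    stop("rejection thresholds must be positive")
  }
  structure(
    list(heog_abs_uv = heog_abs_uv, heog_window_ms = heog_window_ms,
         veog_abs_uv = veog_abs_uv, veog_window_ms = veog_window_ms,
         other_abs_uv = other_abs_uv, other_window_ms = other_window_ms),
    class = "rejection_criteria"
  )
}

#' Filter specification
#'
#' Zero-phase Butterworth filtering: 40 Hz low-pass (8th order, approx. 48
#' dB/octave), 0.1 Hz high-pass (2nd order, approx. 12 dB/octave) and a 60
#' Hz notch (band-stop, default half-width 2.5 Hz).  Orders refer to a
#' single pass; filters are applied forward-backward so no group delay is
#' introduced.  Set a cutoff to `NULL` to skip that stage.
#'
#' @param lowpass_hz,lowpass_order Low-pass cutoff and order.
#' @param highpass_hz,highpass_order High-pass cutoff and order.
#' @param notch_hz,notch_halfwidth_hz,notch_order Notch center, half-width
#'   and order.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(lowpass_hz = 40, lowpass_order = 8,
                        highpass_hz = 0.1, highpass_order = 2,
                        notch_hz = 60, notch_halfwidth_hz = 2.5,
                        notch_order = 2) {
  if (!is.null(highpass_hz) && !is.null(lowpass_hz) &&
      highpass_hz >= lowpass_hz) {
    stop("highpass cutoff must be below lowpass cutoff")
  }
  structure(
    list(lowpass_hz = lowpass_hz, lowpass_order = lowpass_order,
         highpass_hz = highpass_hz, highpass_order = highpass_order,
         notch_hz = notch_hz, notch_halfwidth_hz = notch_halfwidth_hz,
         notch_order = notch_order),
    class = "filter_spec"
  )
}

#' Re-reference epochs to averaged earlobes
#'
#' Subtracts the sample-wise mean of the two earlobe channels from every
#' channel, then drops the earlobe channels from the analysis montage.
#'
#' @param epochs An `eeg_epochs` object.
#' @param earlobe_channels Labels of the two earlobe channels.
#' @return Re-referenced `eeg_epochs` without the earlobe channels.
#' @export
rereference_to_earlobes <- function(epochs, earlobe_channels = c("A1", "A2")) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  ie <- chan_index(epochs, earlobe_channels)
  ref <- (epochs$data[, ie[1], , drop = FALSE] +
          epochs$data[, ie[2], , drop = FALSE]) / 2
  keep <- setdiff(seq_along(epochs$channels), ie)
  dat <- epochs$data[, keep, , drop = FALSE]
  dat <- dat - ref[, rep(1L, length(keep)), , drop = FALSE]
  eeg_epochs(dat, epochs$channels[keep], epochs$time, epochs$srate,
             epochs$trials)
}

# Forward-backward (zero-phase) application of one IIR filter to every
# trial x channel trace.
filtfilt_array <- function(data, filt) {
  d <- dim(data)
  out <- data
  for (ch in seq_len(d[2])) {
    for (tr in seq_len(d[1])) {
      out[tr, ch, ] <- signal::filtfilt(filt, data[tr, ch, ])
    }
  }
  out
}

#' Zero-phase Butterworth filtering of epochs
#'
#' Applies the stages of a [filter_spec()] (high-pass, low-pass, notch) with
#' `signal::filtfilt`, i.e. forward-backward so the net phase response is
#' zero: a symmetric pulse keeps its extremum at the same sample.  Epochs
#' should comfortably exceed the filter's impulse-response length; with the
#' default spec the -100..500 ms epoch at 500 Hz is sufficient for the
#' low-pass and notch, while the 0.1 Hz high-pass mainly removes offsets.
#'
#' @param epochs An `eeg_epochs` object.
#' @param spec A [filter_spec()].
#' @return Filtered `eeg_epochs`.
#' @export
filter_epochs <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(spec, "filter_spec"))
  nyq <- epochs$srate / 2
  dat <- epochs$data
  if (!is.null(spec$highpass_hz)) {
    if (spec$highpass_hz >= nyq) stop("highpass cutoff at or above Nyquist")
    bf <- signal::butter(spec$highpass_order, spec$highpass_hz / nyq, "high")
    dat <- filtfilt_array(dat, bf)
  }
  if (!is.null(spec$lowpass_hz)) {
    if (spec$lowpass_hz >= nyq) stop("lowpass cutoff at or above Nyquist")
    bf <- signal::butter(spec$lowpass_order, spec$lowpass_hz / nyq, "low")
    dat <- filtfilt_array(dat, bf)
  }
  if (!is.null(spec$notch_hz)) {
    hi <- spec$notch_hz + spec$notch_halfwidth_hz
    if (hi >= nyq) stop("notch band reaches Nyquist")
    w <- c(spec$notch_hz - spec$notch_halfwidth_hz, hi) / nyq
    bf <- signal::butter(spec$notch_order, w, "stop")
    dat <- filtfilt_array(dat, bf)
  }
  eeg_epochs(dat, epochs$channels, epochs$time, epochs$srate, epochs$trials)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window, so the corrected baseline mean is zero to float precision.  The
#' operation is idempotent.
#'
#' @param epochs An `eeg_epochs` object.
#' @param baseline_window_ms Closed window in ms (default -100..0).
#' @return Baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, baseline_window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- window_index(epochs$time, baseline_window_ms)
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  dat <- epochs$data - array(bl, dim = dim(epochs$data))
  eeg_epochs(dat, epochs$channels, epochs$time, epochs$srate, epochs$trials)
}

#' Reject trials exceeding amplitude thresholds
#'
#' A trial is rejected iff any sample of a channel class exceeds that
#' class's absolute threshold anywhere inside the class's window (closed at
#' both ends at sample resolution): HEOG and VEOG have their own thresholds
#' and windows, every other channel falls under the `other` criterion.
#'
#' @param epochs An `eeg_epochs` object.
#' @param criteria A [rejection_criteria()].
#' @return List with `epochs` (retained trials, order preserved),
#'   `rejected` (logical mask over the input trials) and `counts`
#'   (per-criterion rejection counts; a trial can trip several).
#' @export
reject_artifacts <- function(epochs, criteria = rejection_criteria()) {
  stopifnot(inherits(epochs, "eeg_epochs"),
            inherits(criteria, "rejection_criteria"))
  exceed <- function(chans, thr, win) {
    present <- intersect(chans, epochs$channels)
    if (length(present) == 0L) return(rep(FALSE, dim(epochs$data)[1]))
    idx <- window_index(epochs$time, win)
    sub <- abs(epochs$data[, chan_index(epochs, present), idx, drop = FALSE])
    apply(sub, 1, max) > thr
  }
  other <- setdiff(epochs$channels, c("HEOG", "VEOG"))
  bad_heog <- exceed("HEOG", criteria$heog_abs_uv, criteria$heog_window_ms)
  bad_veog <- exceed("VEOG", criteria$veog_abs_uv, criteria$veog_window_ms)
  bad_other <- exceed(other, criteria$other_abs_uv, criteria$other_window_ms)
  rejected <- bad_heog | bad_veog | bad_other
  list(
    epochs = subset_trials(epochs, !rejected),
    rejected = rejected,
    counts = c(heog = sum(bad_heog), veog = sum(bad_veog),
               other = sum(bad_other), total = sum(rejected))
  )
}

#' Keep only trials entering the ERP analyses
#'
#' Retains correct trials and drops Target Absent trials (they contain no
#' reference object for the contralateral/ipsilateral assignment).  The
#' retention proportion is attached as attribute `retention`.
#'
#' @param epochs An `eeg_epochs` whose `trials` metadata has `correct` and
#'   `trial_type` columns.
#' @return Filtered `eeg_epochs`.
#' @export
select_analysis_trials <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tr <- epochs$trials
  if (is.null(tr) || !all(c("correct", "trial_type") %in% names(tr))) {
    stop("trial metadata with 'correct' and 'trial_type' is required")
  }
  keep <- !is.na(tr$correct) & tr$correct & tr$trial_type != "target_absent"
  if (!any(keep)) warning("no trials remain after analysis selection")
  out <- subset_trials(epochs, keep)
  attr(out, "retention") <- mean(keep)
  out
}

#' Full preprocessing chain
#'
#' Applies, in order: re-referencing to averaged earlobes (skipped when the
#' earlobe channels are absent), zero-phase filtering, baseline correction,
#' amplitude-threshold artifact rejection and analysis-trial selection.
#'
#' @param epochs Raw `eeg_epochs`.
#' @param spec A [filter_spec()] or `NULL` to skip filtering.
#' @param criteria A [rejection_criteria()].
#' @param baseline_window_ms Baseline window in ms.
#' @param earlobe_channels Earlobe labels for re-referencing.
#' @return List with the cleaned `epochs`, the artifact `rejected` mask (on
#'   the pre-selection trial axis), per-criterion `counts` and the final
#'   `retention` proportion relative to the input trial count.
#' @export
preprocess <- function(epochs, spec = filter_spec(),
                       criteria = rejection_criteria(),
                       baseline_window_ms = c(-100, 0),
                       earlobe_channels = c("A1", "A2")) {
  n0 <- dim(epochs$data)[1]
  if (all(earlobe_channels %in% epochs$channels)) {
    epochs <- rereference_to_earlobes(epochs, earlobe_channels)
  }
  if (!is.null(spec)) epochs <- filter_epochs(epochs, spec)
  epochs <- baseline_correct(epochs, baseline_window_ms)
  rej <- reject_artifacts(epochs, criteria)
  clean <- select_analysis_trials(rej$epochs)
  list(epochs = clean, rejected = rej$rejected, counts = rej$counts,
       retention = dim(clean$data)[1] / n0)
}
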