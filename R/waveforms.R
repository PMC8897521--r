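#' Contralateral/ipsilateral channel assignment
#'
#' Relative to the item (target or foil) side: a left-hemifield item is
#' contralateral to the right-hemisphere electrode PO8 and ipsilateral to
#' PO7, and vice versa.  Target-absent trials carry no reference object and
#' are rejected.
#'
#' @param item_side `"left"` or `"right"`.
#' @return Named character vector with elements `contra` and `ipsi`.
#' @export
assign_laterality <- function(item_side) {
  if (length(item_side) != 1L || !item_side %in% c("left", "right")) {
    stop("item_side must be 'left' or 'right' (target-absent trials have ",
         "no reference object)")
  }
  if (item_side == "left") c(contra = "PO8", ipsi = "PO7")
  else c(contra = "PO7", ipsi = "PO8")
}

# Per-trial contralateral and ipsilateral traces at PO7/PO8.
# Returns list(contra, ipsi): n_trials x n_samples matrices.
lateral_traces <- function(epochs) {
  side <- epochs$trials$item_side
  if (any(!side %in% c("left", "right"))) {
    stop("all trials must have item_side 'left' or 'right'; exclude ",
         "target-absent trials first")
  }
  po7 <- epochs$data[, chan_index(epochs, "PO7"), , drop = TRUE]
  po8 <- epochs$data[, chan_index(epochs, "PO8"), , drop = TRUE]
  if (is.null(dim(po7))) {
    po7 <- matrix(po7, nrow = 1)
    po8 <- matrix(po8, nrow = 1)
  }
  left <- side == "left"
  contra <- po7; contra[left, ] <- po8[left, ]
  ipsi <- po8; ipsi[left, ] <- po7[left, ]
  list(contra = contra, ipsi = ipsi)
}

#' Per-trial contralateral-minus-ipsilateral difference traces
#'
#' Single-trial building block for the permutation test and the bootstrapped
#' SME: each row is the trial's contralateral PO7/PO8 trace minus its
#' ipsilateral one.
#'
#' @param epochs An `eeg_epochs` of item-present trials.
#' @return `n_trials x n_samples` matrix in uV.
#' @export
lateral_trial_diffs <- function(epochs) {
  tr <- lateral_traces(epochs)
  tr$contra - tr$ipsi
}

#' Condition-average lateralized ERP
#'
#' Averages the contralateral and the ipsilateral PO7/PO8 traces over the
#' retained trials of one analysis condition (symbol position x trial
#' type).
#'
#' @param epochs A preprocessed `eeg_epochs`; its `trials` metadata must
#'   carry `trial_type`, `item_side` and `symbol_position` (as produced by
#'   [simulate_epochs()]).
#' @param symbol_position `"patterned"` or `"random"`.
#' @param trial_type `"exemplar_match"` or `"foil"`.
#' @param participant_id Optional identifier stored in the result.
#' @return Object of class `lateralized_erp`: `contra`, `ipsi` (uV per
#'   sample), `time`, `n_trials`, `condition`, `participant_id`.
#' @export
condition_average <- function(epochs, symbol_position, trial_type,
                              participant_id = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tr <- epochs$trials
  sel <- which(tr$symbol_position == symbol_position &
               tr$trial_type == trial_type)
  if (length(sel) == 0L) {
    stop("no trials in condition ", symbol_position, "/", trial_type,
         " - flag this participant rather than dropping it silently")
  }
  lt <- lateral_traces(subset_trials(epochs, sel))
  structure(
    list(contra = colMeans(lt$contra), ipsi = colMeans(lt$ipsi),
         time = epochs$time, n_trials = length(sel),
         condition = c(symbol_position = symbol_position,
                       trial_type = trial_type),
         participant_id = participant_id),
    class = "lateralized_erp"
  )
}

#' Contralateral-minus-ipsilateral difference wave
#'
#' @param erp A `lateralized_erp` from [condition_average()].
#' @return Object of class `difference_wave`: `values` (uV), `time`,
#'   `condition`, `participant_id`, `n_trials`.
#' @export
difference_wave <- function(erp) {
  stopifnot(inherits(erp, "lateralized_erp"))
  if (length(erp$contra) != length(erp$ipsi)) stop("axis mismatch")
  structure(
    list(values = erp$contra - erp$ipsi, time = erp$time,
         condition = erp$condition, participant_id = erp$participant_id,
         n_trials = erp$n_trials),
    class = "difference_wave"
  )
}

new_difference_wave <- function(values, time, condition = NULL,
                                participant_id = NULL, n_participants = NULL) {
  structure(
    list(values = values, time = time, condition = condition,
         participant_id = participant_id, n_participants = n_participants),
    class = "difference_wave"
  )
}

#' @export
print.difference_wave <- function(x, ...) {
  cat("<difference_wave> ", length(x$values), " samples, ",
      x$time[1], "..", x$time[length(x$time)], " ms", sep = "")
  if (!is.null(x$condition)) {
    cat(" [", paste(x$condition, collapse = "/"), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

wave_values <- function(w) {
  if (inherits(w, "difference_wave")) w$values else as.numeric(w)
}

check_common_axis <- function(waves) {
  t0 <- waves[[1]]$time
  for (w in waves[-1]) {
    if (length(w$time) != length(t0) || max(abs(w$time - t0)) > 1e-9) {
      stop("waves do not share a common time axis")
    }
  }
  t0
}

#' Grand average across participants
#'
#' Unweighted (per-participant) mean of difference waves sharing a time
#' axis, the standard ERP convention.
#'
#' @param waves List of `difference_wave` objects (>= 2).
#' @return A `difference_wave` with `participant_id = "grand"` and
#'   `n_participants` recorded.
#' @export
grand_average <- function(waves) {
  if (length(waves) < 2L) stop("grand average needs >= 2 participants")
  t0 <- check_common_axis(waves)
  vals <- rowMeans(vapply(waves, wave_values, numeric(length(t0))))
  new_difference_wave(vals, t0, condition = waves[[1]]$condition,
                      participant_id = "grand",
                      n_participants = length(waves))
}

#' Leave-one-out jackknife grand averages
#'
#' The i-th output is the grand average of all input waves except the i-th;
#' these subsample waveforms are the substrate of the jackknife latency
#' analysis.
#'
#' @param waves List of n >= 3 `difference_wave` objects.
#' @return List of n `difference_wave` objects.
#' @export
jackknife_grand_averages <- function(waves) {
  n <- length(waves)
  if (n < 3L) stop("jackknife needs >= 3 participants")
  t0 <- check_common_axis(waves)
  m <- vapply(waves, wave_values, numeric(length(t0)))
  tot <- rowSums(m)
  lapply(seq_len(n), function(i) {
    new_difference_wave((tot - m[, i]) / (n - 1), t0,
                        condition = waves[[i]]$condition,
                        participant_id = paste0("loo-", i),
                        n_participants = n - 1L)
  })
}
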