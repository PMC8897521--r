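n2pc_conditions <- function() {
  expand.grid(symbol_position = c("patterned", "random"),
              trial_type = c("exemplar_match", "foil"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Fit the lateralized-component analysis to a cohort
#'
#' The central estimator of the package: from each participant's
#' preprocessed, artifact-free, correct item-present epochs it builds the
#' four condition-wise contralateral/ipsilateral averages (symbol position
#' x trial type), their difference waves, and grand averages; measures mean
#' amplitude (200-300 ms), signed negative area and fractional-area latency
#' (150-300 ms) per participant and on the grand averages; runs the
#' within-subject 2 x 2 ANOVA on amplitude and area; and performs the
#' jackknife onset-latency analysis (leave-one-out grand averages, -0.75 uV
#' threshold, corrected statistics) with the patterned-vs-random contrast
#' within each trial type.
#'
#' @param x List of `eeg_epochs`, one per participant, each already passed
#'   through [preprocess()] (or equivalent) so that only correct,
#'   artifact-free, item-present trials remain and `symbol_position` is in
#'   the trial metadata.
#' @param amp_window_ms Mean-amplitude window (default 200-300 ms).
#' @param area_window_ms Area/latency window (default 150-300 ms).
#' @param onset_threshold_uv Jackknife onset threshold (default -0.75 uV).
#' @param area_fraction Fractional-area fraction (default 0.5).
#' @return An object of class `n2pc`; see [summary.n2pc()], [coef.n2pc()],
#'   [plot.n2pc()].
#' @examples
#' \donttest{
#' truth <- ground_truth(noise_sd_uv = 3, artifact_rate = 0)
#' cohort <- simulate_study(n_participants = 4, n_blocks = 1, truth = truth,
#'                          seed = 1, scalp_channels = c("PO7", "PO8"),
#'                          include_eog = FALSE)
#' eps <- lapply(cohort, function(p) {
#'   select_analysis_trials(baseline_correct(p$epochs))
#' })
#' fit <- n2pc(eps)
#' coef(fit)
#' }
#' @export
n2pc <- function(x, amp_window_ms = c(200, 300),
                 area_window_ms = c(150, 300),
                 onset_threshold_uv = -0.75, area_fraction = 0.5) {
  stopifnot(is.list(x), length(x) >= 2L)
  lapply(x, function(e) stopifnot(inherits(e, "eeg_epochs")))
  conds <- n2pc_conditions()
  cond_key <- paste(conds$symbol_position, conds$trial_type, sep = ".")
  n_part <- length(x)

  waves <- lapply(seq_len(n_part), function(i) {
    stats::setNames(lapply(seq_len(nrow(conds)), function(j) {
      difference_wave(condition_average(x[[i]], conds$symbol_position[j],
                                        conds$trial_type[j],
                                        participant_id = i))
    }), cond_key)
  })

  grand <- stats::setNames(lapply(cond_key, function(k) {
    grand_average(lapply(waves, `[[`, k))
  }), cond_key)

  measure_one <- function(w) {
    c(mean_amplitude = mean_amplitude(w, amp_window_ms)$value,
      signed_negative_area = signed_negative_area(w, area_window_ms)$value,
      fractional_area_latency =
        fractional_area_latency(w, area_window_ms, area_fraction)$value,
      onset_latency =
        onset_threshold_crossing(w, onset_threshold_uv, area_window_ms)$value)
  }
  per_part <- do.call(rbind, lapply(seq_len(n_part), function(i) {
    do.call(rbind, lapply(cond_key, function(k) {
      m <- measure_one(waves[[i]][[k]])
      data.frame(participant = i,
                 symbol_position = strsplit(k, ".", fixed = TRUE)[[1]][1],
                 trial_type = strsplit(k, ".", fixed = TRUE)[[1]][2],
                 t(m), stringsAsFactors = FALSE)
    }))
  }))
  grand_measures <- t(vapply(cond_key, function(k) measure_one(grand[[k]]),
                             numeric(4)))

  # within-subject 2x2 ANOVAs on the participant-level measures
  to_cube <- function(col) {
    v <- array(NA_real_, dim = c(n_part, 2, 2),
               dimnames = list(NULL, c("patterned", "random"),
                               c("exemplar_match", "foil")))
    for (r in seq_len(nrow(per_part))) {
      v[per_part$participant[r], per_part$symbol_position[r],
        per_part$trial_type[r]] <- per_part[[col]][r]
    }
    v
  }
  anovas <- list(
    mean_amplitude = rm_anova_2x2(to_cube("mean_amplitude")),
    signed_negative_area = rm_anova_2x2(to_cube("signed_negative_area"))
  )
  fal <- to_cube("fractional_area_latency")
  complete <- apply(!is.na(fal), 1, all)
  anovas$fractional_area_latency <- if (sum(complete) >= 3L) {
    rm_anova_2x2(fal[complete, , , drop = FALSE])
  }

  # jackknife onset latencies: patterned vs random within each trial type
  jack <- if (n_part >= 3L) {
    stats::setNames(lapply(c("exemplar_match", "foil"), function(ty) {
      loo_p <- jackknife_grand_averages(
        lapply(waves, `[[`, paste0("patterned.", ty)))
      loo_r <- jackknife_grand_averages(
        lapply(waves, `[[`, paste0("random.", ty)))
      jackknife_latency_analysis(loo_p, loo_r, onset_threshold_uv,
                                 area_window_ms)
    }), c("exemplar_match", "foil"))
  }

  structure(
    list(waves = waves, grand = grand, measures = per_part,
         grand_measures = grand_measures, anovas = anovas, jackknife = jack,
         n_participants = n_part,
         params = list(amp_window_ms = amp_window_ms,
                       area_window_ms = area_window_ms,
                       onset_threshold_uv = onset_threshold_uv,
                       area_fraction = area_fraction)),
    class = "n2pc"
  )
}

#' @export
print.n2pc <- function(x, ...) {
  cat("N2pc analysis of", x$n_participants, "participants\n")
  cat("Grand-average condition measures:\n")
  print(signif(x$grand_measures, 4))
  invisible(x)
}

#' Grand-average condition measures of an `n2pc` fit
#'
#' @param object An `n2pc` object.
#' @param ... Unused.
#' @return Matrix of grand-average measures (rows = conditions).
#' @export
coef.n2pc <- function(object, ...) object$grand_measures

#' Summarize an `n2pc` fit
#'
#' Prints the grand-average measures, the within-subject 2 x 2 ANOVAs for
#' mean amplitude and signed negative area (and fractional-area latency
#' where enough participants have defined values) and the jackknife
#' onset-latency contrasts.
#'
#' @param object An `n2pc` object.
#' @param ... Unused.
#' @export
summary.n2pc <- function(object, ...) {
  print(object)
  for (nm in names(object$anovas)) {
    if (is.null(object$anovas[[nm]])) next
    cat("\n2x2 ANOVA on", nm, "\n")
    print(object$anovas[[nm]])
  }
  if (!is.null(object$jackknife)) {
    for (ty in names(object$jackknife)) {
      cat("\nJackknife onset, patterned vs random,", ty, "\n")
      print(object$jackknife[[ty]])
    }
  }
  invisible(object)
}

#' Plot grand-average difference waves
#'
#' One trace per condition; negative deflections in the 150-300 ms window
#' are the lateralized attention component.
#'
#' @param x An `n2pc` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.n2pc <- function(x, ...) {
  time <- x$grand[[1]]$time
  m <- vapply(x$grand, `[[`, numeric(length(time)), "values")
  graphics::matplot(time, m, type = "l", lty = 1:4, col = 1:4,
                    xlab = "time (ms)", ylab = "contra - ipsi (uV)", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("bottomleft", colnames(m), lty = 1:4, col = 1:4,
                   cex = 0.8, bty = "n")
  invisible(x)
}
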