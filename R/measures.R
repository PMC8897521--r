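measure_result <- function(measure, value, window, defined = TRUE,
                           params = NULL) {
  structure(
    list(measure = measure,
         value = if (defined) value else NA_real_,
         window_ms = window, defined = defined, params = params),
    class = "measure_result"
  )
}

#' @export
print.measure_result <- function(x, ...) {
  unit <- switch(x$measure,
                 mean_amplitude = "uV",
                 signed_negative_area = "uV*ms",
                 "ms")
  cat("<measure_result> ", x$measure, " [",
      x$window_ms[1], "-", x$window_ms[2], " ms]: ",
      if (x$defined) paste(signif(x$value, 6), unit) else "undefined",
      "\n", sep = "")
  invisible(x)
}

resolve_wave <- function(wave, time) {
  if (inherits(wave, "difference_wave")) {
    list(values = wave$values, time = wave$time)
  } else {
    if (is.null(time)) stop("a numeric wave needs an explicit time axis")
    stopifnot(length(wave) == length(time))
    list(values = as.numeric(wave), time = as.numeric(time))
  }
}

#' Mean amplitude in a window
#'
#' Arithmetic mean of the wave's samples whose times lie in the closed
#' window; 200-300 ms is the canonical N2pc measurement window.
#'
#' @param wave A `difference_wave` or numeric vector.
#' @param window_ms Closed window in ms.
#' @param time Time axis, required when `wave` is a bare vector.
#' @return A `measure_result` (value in uV).
#' @export
mean_amplitude <- function(wave, window_ms = c(200, 300), time = NULL) {
  w <- resolve_wave(wave, time)
  idx <- window_index(w$time, window_ms)
  measure_result("mean_amplitude", mean(w$values[idx]), window_ms)
}

# Exact per-interval integrals of -min(w, 0) for a piecewise-linear wave:
# zero crossings inside an interval are resolved analytically, so the
# measure does not depend on where samples fall relative to crossings.
neg_area_intervals <- function(t, v) {
  n <- length(v)
  a <- v[-n]; b <- v[-1]; h <- diff(t)
  area <- numeric(n - 1L)
  bn <- a <= 0 & b <= 0
  area[bn] <- -h[bn] * (a[bn] + b[bn]) / 2
  up <- a < 0 & b > 0                      # crossing upward: negative head
  if (any(up)) {
    x0 <- h[up] * a[up] / (a[up] - b[up])
    area[up] <- -a[up] * x0 / 2
  }
  dn <- a > 0 & b < 0                      # crossing downward: negative tail
  if (any(dn)) {
    x0 <- h[dn] * a[dn] / (a[dn] - b[dn])
    area[dn] <- -b[dn] * (h[dn] - x0) / 2
  }
  area
}

#' Signed negative area
#'
#' Magnitude of the negative-going portion of the wave over a window:
#' `-integral of min(w(t), 0) dt`, reported as a non-negative number in
#' uV*ms (larger = more negative area).  The integral treats the sampled
#' wave as piecewise linear and resolves zero crossings exactly.  The broad
#' 150-300 ms window captures components with variable latency.
#'
#' @inheritParams mean_amplitude
#' @return A `measure_result` (value >= 0, uV*ms).
#' @export
signed_negative_area <- function(wave, window_ms = c(150, 300), time = NULL) {
  w <- resolve_wave(wave, time)
  idx <- window_index(w$time, window_ms)
  if (length(idx) < 2L) stop("window must span at least two samples")
  area <- sum(neg_area_intervals(w$time[idx], w$values[idx]))
  measure_result("signed_negative_area", area, window_ms)
}

#' Fractional-area latency
#'
#' The time at which the cumulative negative area inside the window reaches
#' `fraction` of the total negative area, with linear interpolation of the
#' cumulative-area curve between samples.  Undefined (flagged, not an
#' error) when the wave has no negative area in the window - such
#' participants are excluded from comparisons rather than scored 0.
#'
#' @inheritParams mean_amplitude
#' @param fraction Fraction of total negative area in (0, 1); default 0.5.
#' @return A `measure_result` (ms); `defined = FALSE` if no negative area.
#' @export
fractional_area_latency <- function(wave, window_ms = c(150, 300),
                                    fraction = 0.5, time = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  w <- resolve_wave(wave, time)
  idx <- window_index(w$time, window_ms)
  if (length(idx) < 2L) stop("window must span at least two samples")
  tt <- w$time[idx]
  area <- neg_area_intervals(tt, w$values[idx])
  total <- sum(area)
  if (total <= 0) {
    return(measure_result("fractional_area_latency", NA_real_, window_ms,
                          defined = FALSE, params = list(fraction = fraction)))
  }
  target <- fraction * total
  cum <- c(0, cumsum(area))
  k <- which(cum >= target - 1e-12)[1]          # first grid point at/after
  if (k == 1L) {
    lat <- tt[1]
  } else {
    gain <- cum[k] - cum[k - 1L]
    frac <- if (gain > 0) (target - cum[k - 1L]) / gain else 1
    lat <- tt[k - 1L] + frac * (tt[k] - tt[k - 1L])
  }
  measure_result("fractional_area_latency", lat, window_ms,
                 params = list(fraction = fraction))
}

#' Onset latency by threshold crossing
#'
#' First time inside the search window at which the wave reaches a negative
#' threshold (-0.75 uV by default), linearly interpolated between the
#' bracketing samples.  "First crossing" means the first sample pair where
#' the wave passes from above the threshold to at-or-below it; a wave
#' already at/below threshold at the window start returns the window start.
#' Undefined (flagged) when the threshold is never reached.
#'
#' @inheritParams mean_amplitude
#' @param threshold_uv Negative threshold in uV (default -0.75).
#' @param window_ms Search window in ms.
#' @return A `measure_result` (ms); `defined = FALSE` if never reached.
#' @export
onset_threshold_crossing <- function(wave, threshold_uv = -0.75,
                                     window_ms = c(150, 300), time = NULL) {
  if (threshold_uv >= 0) stop("threshold_uv must be negative")
  w <- resolve_wave(wave, time)
  idx <- window_index(w$time, window_ms)
  v <- w$values[idx]; tt <- w$time[idx]
  params <- list(threshold_uv = threshold_uv)
  if (v[1] <= threshold_uv) {
    return(measure_result("onset_latency", tt[1], window_ms, params = params))
  }
  below <- which(v <= threshold_uv)
  if (length(below) == 0L) {
    return(measure_result("onset_latency", NA_real_, window_ms,
                          defined = FALSE, params = params))
  }
  k <- below[1]
  frac <- (v[k - 1L] - threshold_uv) / (v[k - 1L] - v[k])
  measure_result("onset_latency", tt[k - 1L] + frac * (tt[k] - tt[k - 1L]),
                 window_ms, params = params)
}

jackknife_onsets <- function(loo_waves, threshold_uv, window_ms) {
  vapply(loo_waves, function(w) {
    onset_threshold_crossing(w, threshold_uv, window_ms)$value
  }, numeric(1))
}

#' Jackknife onset-latency analysis
#'
#' Onset latency estimated on leave-one-participant-out grand averages
#' (from [jackknife_grand_averages()]), with per-participant scores
#' retrieved by the standard back-transformation `score_i = n * L_all -
#' (n - 1) * L_(-i)` (`L_all` measured on the full grand average, i.e. the
#' mean of the leave-one-out waves).  When a second condition is supplied, a
#' paired comparison of the subsample latencies is computed with the
#' jackknife-corrected statistic `t_c = t / (n - 1)` on `n - 1` degrees of
#' freedom.  If any subsample wave fails to reach the threshold, that
#' condition is flagged undefined and excluded from the contrast - mirroring
#' the exclusion of participants whose data do not meet the threshold.
#'
#' @param loo_waves List of n >= 3 leave-one-out grand-average waves for
#'   condition A.
#' @param loo_waves_b Optional matching list for condition B (paired
#'   contrast A - B).
#' @param threshold_uv Onset threshold in uV (default -0.75).
#' @param window_ms Search window in ms.
#' @return List of class `jackknife_latency`: per-condition subsample
#'   `latencies`, `grand_latency`, retrieved `scores`, `defined` flags and
#'   (for a contrast) `t_corrected`, `df`, `p_value`, `mean_difference`.
#' @export
jackknife_latency_analysis <- function(loo_waves, loo_waves_b = NULL,
                                       threshold_uv = -0.75,
                                       window_ms = c(150, 300)) {
  n <- length(loo_waves)
  if (n < 3L) stop("jackknife needs >= 3 participants")
  one <- function(loo) {
    lat <- jackknife_onsets(loo, threshold_uv, window_ms)
    full <- grand_average(loo)                  # mean of loo waves = full GA
    l_all <- onset_threshold_crossing(full, threshold_uv, window_ms)$value
    ok <- !anyNA(lat) && !is.na(l_all)
    scores <- if (ok) n * l_all - (n - 1) * lat else rep(NA_real_, n)
    list(latencies = lat, grand_latency = l_all, scores = scores,
         defined = ok)
  }
  a <- one(loo_waves)
  out <- list(a = a, threshold_uv = threshold_uv, window_ms = window_ms,
              n = n)
  if (!is.null(loo_waves_b)) {
    if (length(loo_waves_b) != n) stop("conditions must share participants")
    b <- one(loo_waves_b)
    out$b <- b
    if (a$defined && b$defined) {
      d <- a$latencies - b$latencies
      sd_d <- stats::sd(d)
      if (sd_d == 0) {
        out$contrast <- list(mean_difference = mean(d), t_corrected = NA_real_,
                             df = n - 1L, p_value = NA_real_,
                             note = "zero variance among subsample latencies")
      } else {
        t_raw <- mean(d) / (sd_d / sqrt(n))
        t_c <- t_raw / (n - 1)
        out$contrast <- list(
          mean_difference = mean(d), t_corrected = t_c, df = n - 1L,
          p_value = 2 * stats::pt(-abs(t_c), df = n - 1)
        )
      }
    } else {
      out$contrast <- list(
        note = "a condition did not reach threshold in every subsample; excluded from the pairwise comparison")
    }
  }
  class(out) <- "jackknife_latency"
  out
}

#' @export
print.jackknife_latency <- function(x, ...) {
  cat("<jackknife_latency> threshold ", x$threshold_uv, " uV, window ",
      x$window_ms[1], "-", x$window_ms[2], " ms, n = ", x$n, "\n", sep = "")
  cat("  condition A: grand onset ",
      if (x$a$defined) paste0(signif(x$a$grand_latency, 5), " ms")
      else "undefined", "\n", sep = "")
  if (!is.null(x$b)) {
    cat("  condition B: grand onset ",
        if (x$b$defined) paste0(signif(x$b$grand_latency, 5), " ms")
        else "undefined", "\n", sep = "")
    if (!is.null(x$contrast$t_corrected)) {
      cat("  paired contrast: diff = ",
          signif(x$contrast$mean_difference, 5), " ms, corrected t(",
          x$contrast$df, ") = ", signif(x$contrast$t_corrected, 4),
          ", p = ", signif(x$contrast$p_value, 3), "\n", sep = "")
    } else if (!is.null(x$contrast$note)) {
      cat("  paired contrast: ", x$contrast$note, "\n", sep = "")
    }
  }
  invisible(x)
}
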