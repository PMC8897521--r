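#' Percentile criterion for a permutation null
#'
#' Significance is declared when the observed statistic exceeds the given
#' percentile of the null distribution (nearest-rank rule); the p-value is
#' the add-one permutation estimator `(b + 1) / (N + 1)` with `b` the
#' number of null values at or above the observed one.
#'
#' @param observed Observed statistic.
#' @param null_distribution Numeric vector of null statistics.
#' @param percentile Criterion percentile (default 95).
#' @return List with `significant`, `p_value` and `critical_value`.
#' @export
percentile_criterion <- function(observed, null_distribution,
                                 percentile = 95) {
  if (length(null_distribution) == 0L) stop("empty null distribution")
  if (anyNA(null_distribution) || anyNA(observed)) {
    stop("NaN/NA in observed value or null distribution")
  }
  ns <- sort(null_distribution)
  k <- ceiling(percentile / 100 * length(ns))
  crit <- ns[max(1L, k)]
  b <- sum(null_distribution >= observed)
  list(significant = observed > crit,
       p_value = (b + 1) / (length(null_distribution) + 1),
       critical_value = crit)
}

#' Signed-area permutation test on grand-average difference waves
#'
#' Tests each condition's signed negative area against a within-participant
#' label-shuffling null: for every permutation, each participant's trials
#' are randomly reassigned to the patterned/random symbol positions
#' (separately for Exemplar Match and Foil trials), condition averages,
#' difference waves and the grand average are rebuilt, and the signed
#' negative area is recomputed - yielding one null distribution per
#' condition.  A condition is significant when its observed area exceeds
#' the 95th percentile of its null.
#'
#' @param diffs List (one element per participant) of `n_trials x
#'   n_samples` matrices of single-trial contralateral-minus-ipsilateral
#'   traces (see [lateral_trial_diffs()]).
#' @param labels List of per-trial symbol-position labels (`"patterned"` /
#'   `"random"`), parallel to `diffs`.
#' @param trial_types Optional list of per-trial trial-type labels; label
#'   shuffling is stratified within each trial type.  `NULL` treats all of
#'   a participant's trials as one stratum.
#' @param time Epoch time axis in ms.
#' @param window_ms Area window (default 150-300 ms).
#' @param n_permutations Number of random reassignments (default 500).
#' @param percentile Criterion percentile (default 95).
#' @param seed Integer seed; fixed seeds give identical nulls.
#' @return Object of class `permutation_result`: `observed` (named by
#'   condition), `null_distribution` (matrix `n_permutations x
#'   conditions`), `p_value`, `significant`, `critical`, `n_permutations`,
#'   `seed`.
#' @export
signed_area_permutation_test <- function(diffs, labels, trial_types = NULL,
                                         time, window_ms = c(150, 300),
                                         n_permutations = 500,
                                         percentile = 95, seed = NULL) {
  stopifnot(is.list(diffs), is.list(labels),
            length(diffs) == length(labels))
  if (length(diffs) < 2L) stop("need >= 2 participants")
  if (n_permutations < 100) {
    warning("fewer than 100 permutations gives a coarse p-value grid")
  }
  if (is.null(trial_types)) {
    trial_types <- lapply(diffs, function(m) rep("all", nrow(m)))
  }
  # drop participants lacking a label within any stratum they have trials in
  ok <- vapply(seq_along(diffs), function(i) {
    tab <- table(trial_types[[i]], labels[[i]])
    ncol(tab) == 2L && all(tab > 0)
  }, logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " participant(s) lack trials for one label and were ",
            "excluded")
    diffs <- diffs[ok]; labels <- labels[ok]; trial_types <- trial_types[ok]
    if (length(diffs) < 2L) stop("fewer than 2 usable participants")
  }
  n_part <- length(diffs)
  types <- sort(unique(unlist(trial_types)))
  poss <- c("patterned", "random")
  conds <- as.vector(outer(poss, types, paste, sep = "."))
  idx_w <- window_index(time, window_ms)
  tw <- time[idx_w]

  # per-participant condition means for one label assignment
  cond_means <- function(i, lab) {
    out <- matrix(0, length(conds), length(idx_w))
    r <- 0L
    for (ty in types) for (po in poss) {
      r <- match(paste(po, ty, sep = "."), conds)
      sel <- trial_types[[i]] == ty & lab == po
      out[r, ] <- colMeans(diffs[[i]][sel, idx_w, drop = FALSE])
    }
    out
  }
  area_of <- function(ga_rows) {
    vapply(seq_len(nrow(ga_rows)), function(r) {
      sum(neg_area_intervals(tw, ga_rows[r, ]))
    }, numeric(1))
  }
  grand_areas <- function(lab_list) {
    acc <- matrix(0, length(conds), length(idx_w))
    for (i in seq_len(n_part)) acc <- acc + cond_means(i, lab_list[[i]])
    area_of(acc / n_part)
  }

  with_seed(seed, {
    observed <- grand_areas(labels)
    null <- matrix(NA_real_, n_permutations, length(conds))
    for (p in seq_len(n_permutations)) {
      shuffled <- lapply(seq_len(n_part), function(i) {
        lab <- labels[[i]]
        for (ty in types) {
          sel <- trial_types[[i]] == ty
          lab[sel] <- sample(lab[sel])
        }
        lab
      })
      null[p, ] <- grand_areas(shuffled)
    }
    names(observed) <- colnames(null) <- conds
    crit <- p_val <- sig <- stats::setNames(numeric(length(conds)), conds)
    for (j in seq_along(conds)) {
      pc <- percentile_criterion(observed[j], null[, j], percentile)
      crit[j] <- pc$critical_value
      p_val[j] <- pc$p_value
      sig[j] <- pc$significant
    }
    structure(
      list(observed = observed, null_distribution = null, p_value = p_val,
           significant = as.logical(sig), critical = crit,
           criterion_percentile = percentile,
           n_permutations = n_permutations, window_ms = window_ms,
           seed = seed),
      class = "permutation_result"
    )
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> signed negative area, ", x$n_permutations,
      " permutations, window ", x$window_ms[1], "-", x$window_ms[2],
      " ms\n", sep = "")
  df <- data.frame(observed = signif(x$observed, 4),
                   critical = signif(x$critical, 4),
                   p = signif(x$p_value, 3),
                   significant = x$significant)
  print(df)
  invisible(x)
}

# Maximal runs of TRUE; returns list of (start, end) index pairs.
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], ends[k]))
}

#' Observed cluster-level t mass of a decoding timecourse
#'
#' Per time point, a one-sample t test of the participants' accuracies
#' against chance (one-tailed, above chance); maximal runs of contiguous
#' significant points form clusters, each scored by its t mass (the sum of
#' the per-point t statistics inside the cluster).  Points with zero
#' variance across participants and mean at chance have an undefined t and
#' are treated as non-significant with a warning; zero variance with the
#' mean away from chance is a decidable degenerate case (t = +-Inf).
#'
#' @param acc `n_participants x n_timepoints` accuracy matrix.
#' @param time Time axis (ms) for the columns of `acc`.
#' @param chance_level Chance accuracy (default 0.5).
#' @param alpha Per-point cluster-forming threshold (default 0.05).
#' @return List of class `cluster_result`: `clusters` (data frame with
#'   `start_ms`, `end_ms`, `t_mass`), per-point `t` and `significant`.
#' @export
cluster_t_mass <- function(acc, time, chance_level = 0.5, alpha = 0.05) {
  stopifnot(is.matrix(acc), ncol(acc) == length(time))
  if (nrow(acc) < 3L) stop("cluster t test needs >= 3 participants")
  n <- nrow(acc)
  mu <- colMeans(acc)
  sdv <- col_sds(acc)
  tstat <- rep(NA_real_, ncol(acc))
  nz <- sdv > 1e-12
  tstat[nz] <- (mu[nz] - chance_level) / (sdv[nz] / sqrt(n))
  tstat[!nz & mu > chance_level] <- Inf
  tstat[!nz & mu < chance_level] <- -Inf
  undef <- !nz & mu == chance_level
  if (any(undef)) {
    warning(sum(undef), " time point(s) with zero variance at chance: t ",
            "undefined, treated as non-significant")
  }
  pvals <- rep(1, ncol(acc))
  ok <- !is.na(tstat)
  pvals[ok] <- stats::pt(tstat[ok], df = n - 1, lower.tail = FALSE)
  sig <- pvals < alpha
  cl <- runs_of(sig)
  clusters <- data.frame(
    start_ms = vapply(cl, function(r) time[r[1]], numeric(1)),
    end_ms = vapply(cl, function(r) time[r[2]], numeric(1)),
    t_mass = vapply(cl, function(r) sum(tstat[r[1]:r[2]]), numeric(1))
  )
  structure(list(clusters = clusters, t = tstat, significant = sig,
                 time = time, chance_level = chance_level, alpha = alpha,
                 n_participants = n),
            class = "cluster_result")
}

col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- (colSums(x * x) - n * mu * mu) / (n - 1)
  sqrt(pmax(v, 0))
}

max_cluster_mass <- function(acc, chance_level, alpha) {
  n <- nrow(acc)
  mu <- colMeans(acc)
  sdv <- col_sds(acc)
  nz <- sdv > 1e-12
  tstat <- numeric(ncol(acc))
  tstat[nz] <- (mu[nz] - chance_level) / (sdv[nz] / sqrt(n))
  tstat[!nz & mu > chance_level] <- Inf
  crit_t <- stats::qt(1 - alpha, df = n - 1)
  sig <- tstat > crit_t
  if (!any(sig)) return(0)
  max(vapply(runs_of(sig), function(r) sum(tstat[r[1]:r[2]]), numeric(1)))
}

#' Cluster-mass permutation test
#'
#' Builds a null distribution of maximal cluster-level t masses and scores
#' the observed clusters of [cluster_t_mass()] against it.  Two null
#' generators are available: `"binomial"` (default at desk scale) draws
#' each participant's per-point accuracy under the null as
#' `Binomial(n_attempts, chance) / n_attempts` - the chance-level sampling
#' distribution of an accuracy estimated from `n_attempts` decoding
#' attempts; `"label_permutation"` re-runs the decoder per participant with
#' class labels shuffled (exact but expensive; supply `decode_inputs`).  A
#' cluster is significant when its t mass exceeds the 95th percentile of
#' the null; exact add-one permutation p-values are reported per cluster.
#'
#' @param acc Observed `n_participants x n_timepoints` accuracy matrix.
#' @param time Time axis (ms).
#' @param chance_level Chance accuracy (default 0.5).
#' @param alpha Cluster-forming threshold (default 0.05).
#' @param n_permutations Null size (default 1000; the full-scale analysis
#'   uses 10000).
#' @param n_attempts Decoding attempts per accuracy estimate (default 60).
#' @param method `"binomial"` or `"label_permutation"`.
#' @param decode_inputs For `"label_permutation"`: list per participant of
#'   `list(x = epochs-or-array, labels = class labels, ...)` passed on to
#'   [decode_timecourse()] (with shuffled labels).
#' @param seed Integer seed.
#' @return A `cluster_result` augmented with `null_t_mass`,
#'   `critical_t_mass`, per-cluster `p_values` and `cluster_significant`.
#' @export
cluster_permutation_null <- function(acc, time, chance_level = 0.5,
                                     alpha = 0.05, n_permutations = 1000,
                                     n_attempts = 60,
                                     method = c("binomial",
                                                "label_permutation"),
                                     decode_inputs = NULL, seed = NULL) {
  method <- match.arg(method)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations gives a coarse p-value grid")
  }
  obs <- cluster_t_mass(acc, time, chance_level, alpha)
  n <- nrow(acc); m <- ncol(acc)
  with_seed(seed, {
    null <- numeric(n_permutations)
    if (method == "binomial") {
      for (p in seq_len(n_permutations)) {
        surrogate <- matrix(
          stats::rbinom(n * m, n_attempts, chance_level) / n_attempts, n, m)
        null[p] <- max_cluster_mass(surrogate, chance_level, alpha)
      }
    } else {
      if (is.null(decode_inputs) || length(decode_inputs) != n) {
        stop("label_permutation needs decode_inputs, one element per ",
             "participant")
      }
      for (p in seq_len(n_permutations)) {
        surrogate <- t(vapply(decode_inputs, function(di) {
          args <- di
          args$labels <- sample(di$labels)
          args$seed <- sample.int(2147483646L, 1L)
          decode_timecourse_args(args)$accuracy
        }, numeric(m)))
        null[p] <- max_cluster_mass(surrogate, chance_level, alpha)
      }
    }
    ns <- sort(null)
    crit <- ns[max(1L, ceiling(0.95 * n_permutations))]
    pv <- vapply(obs$clusters$t_mass, function(tm) {
      (sum(null >= tm) + 1) / (n_permutations + 1)
    }, numeric(1))
    obs$null_t_mass <- null
    obs$critical_t_mass <- crit
    obs$p_values <- pv
    obs$cluster_significant <- obs$clusters$t_mass > crit
    obs$n_permutations <- n_permutations
    obs$method <- method
    obs$seed <- seed
    obs
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s), alpha = ",
      x$alpha, ", chance = ", x$chance_level, "\n", sep = "")
  if (nrow(x$clusters) > 0) {
    df <- x$clusters
    if (!is.null(x$p_values)) {
      df$p <- signif(x$p_values, 3)
      df$significant <- x$cluster_significant
    }
    print(df)
  }
  if (!is.null(x$critical_t_mass)) {
    cat("critical t mass (95th pct of ", x$n_permutations,
        " permutations): ", signif(x$critical_t_mass, 5), "\n", sep = "")
  }
  invisible(x)
}

#' Bootstrapped standardized measurement error (bSME)
#'
#' Simulates the participant's condition `n_bootstrap` times by resampling
#' trials with replacement (same size), averaging the resampled single-trial
#' difference traces, and recomputing the measure on each averaged
#' waveform.  The bSME is the standard deviation of the bootstrap measure
#' values, in the measure's own units.  Bootstrap iterations in which a
#' latency measure is undefined are dropped from the SD, with the count
#' reported.
#'
#' @param trials `n_trials x n_samples` matrix of single-trial
#'   contralateral-minus-ipsilateral traces for one participant/condition.
#' @param time Epoch time axis (ms).
#' @param measure_fn One of [mean_amplitude()], [signed_negative_area()],
#'   [fractional_area_latency()] (or any function of `(wave, time =)`
#'   returning a `measure_result`).
#' @param n_bootstrap Number of resamples (default 2000; full scale 10000).
#' @param seed Integer seed.
#' @param ... Passed to `measure_fn` (e.g. `window_ms`).
#' @return List of class `sme_result`: `bsme`, `n_bootstrap`, `n_undefined`,
#'   `defined` (FALSE when every iteration was undefined), `measure`.
#' @export
bootstrap_sme <- function(trials, time, measure_fn = mean_amplitude,
                          n_bootstrap = 2000, seed = NULL, ...) {
  stopifnot(is.matrix(trials), ncol(trials) == length(time))
  if (nrow(trials) < 2L) stop("bootstrap SME needs >= 2 trials")
  n <- nrow(trials)
  with_seed(seed, {
    vals <- vapply(seq_len(n_bootstrap), function(b) {
      avg <- colMeans(trials[sample.int(n, n, replace = TRUE), ,
                             drop = FALSE])
      measure_fn(avg, time = time, ...)$value
    }, numeric(1))
    n_undef <- sum(is.na(vals))
    ok <- !is.na(vals)
    structure(
      list(bsme = if (any(ok)) stats::sd(vals[ok]) else NA_real_,
           n_bootstrap = n_bootstrap, n_undefined = n_undef,
           defined = any(ok),
           measure = attr(measure_fn, "name") %||% NULL),
      class = "sme_result"
    )
  })
}

#' Root-mean-square aggregate of bSME values
#'
#' Group-level data-quality summary: `sqrt(mean(bsme^2))` over
#' participants.  For non-negative inputs the RMS lies between the mean and
#' the maximum.
#'
#' @param bsme_values Non-empty numeric vector of non-negative bSMEs.
#' @return The RMS.
#' @export
rms_aggregate <- function(bsme_values) {
  if (length(bsme_values) == 0L) stop("empty bSME list")
  if (any(is.na(bsme_values)) || any(bsme_values < 0)) {
    stop("bSME values must be non-negative and non-missing")
  }
  sqrt(mean(bsme_values^2))
}
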