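#' Analysis configuration
#'
#' Central parameter record: every downstream stage reads its constants from
#' this object so a run is fully described by its config (plus the seed).
#' Defaults are the canonical analysis constants: 500 Hz sampling, -100..500
#' ms epochs, -100..0 ms baseline, 25/60/80 uV rejection thresholds, 200-300
#' ms amplitude window, 150-300 ms broad window, -0.75 uV onset threshold,
#' 50% area fraction, 500 area permutations, 3 folds x 10 iterations of
#' decoding, alpha 0.05.  `n_cluster_perm` and `n_boot` default to
#' desk-scale values (1000 / 2000); the full-scale analyses use 10000.
#'
#' @param n_participants,n_blocks Cohort and design size.
#' @param truth Ground-truth table for the simulator ([ground_truth()]).
#' @param rt_model Behavioral model ([default_rt_model()]).
#' @param scalp_channels Simulated scalp montage.
#' @param srate,epoch_ms,baseline_ms Sampling and epoch constants.
#' @param criteria Rejection criteria ([rejection_criteria()]).
#' @param filter Filter spec ([filter_spec()]) or `NULL` to skip filtering.
#' @param amp_window_ms,area_window_ms,onset_threshold_uv,area_fraction
#'   Measurement constants.
#' @param n_perm,n_cluster_perm,n_boot Resampling sizes.
#' @param n_folds,n_iterations Decoding cross-validation constants.
#' @param alpha Significance level.
#' @param p_2afc Simulated 2AFC choice probability.
#' @param seed Master seed (required for a reproducible run).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_participants = 19, n_blocks = 7,
                            truth = ground_truth(),
                            rt_model = default_rt_model(),
                            scalp_channels = default_scalp_channels(),
                            srate = 500, epoch_ms = c(-100, 500),
                            baseline_ms = c(-100, 0),
                            criteria = rejection_criteria(),
                            filter = filter_spec(),
                            amp_window_ms = c(200, 300),
                            area_window_ms = c(150, 300),
                            onset_threshold_uv = -0.75, area_fraction = 0.5,
                            n_perm = 500, n_cluster_perm = 1000,
                            n_boot = 2000, n_folds = 3, n_iterations = 10,
                            alpha = 0.05, p_2afc = 0.5, seed = 1) {
  stopifnot(n_participants >= 2, n_blocks >= 1, srate > 0,
            alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full simulated-experiment analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> lateralized waveforms and
#' component measures ([n2pc()]) -> signed-area permutation test ->
#' time-resolved decoding with cluster-mass permutation -> bootstrapped SME
#' with RMS aggregation -> behavioral and 2AFC summaries.  Every random
#' stage derives its seed from `config$seed`, so a fixed config reproduces
#' the report bit-for-bit.
#'
#' @param config An [analysis_config()].
#' @return A list of class `laterp_report` with elements `fit` (the
#'   [n2pc()] object), `permutation`, `decoding` (per trial type: window
#'   stats and cluster results), `sme` (per-measure RMS table),
#'   `behavior`, `afc`, `retention`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- simulate_study(
    n_participants = config$n_participants, n_blocks = config$n_blocks,
    truth = config$truth, rt_model = config$rt_model,
    p_2afc = config$p_2afc, seed = config$seed,
    scalp_channels = config$scalp_channels, include_eog = TRUE,
    include_earlobes = TRUE, srate = config$srate,
    epoch_ms = config$epoch_ms)

  pre <- lapply(cohort, function(p) {
    preprocess(p$epochs, spec = config$filter, criteria = config$criteria,
               baseline_window_ms = config$baseline_ms)
  })
  clean <- lapply(pre, `[[`, "epochs")
  retention <- vapply(pre, `[[`, numeric(1), "retention")

  fit <- n2pc(clean, amp_window_ms = config$amp_window_ms,
              area_window_ms = config$area_window_ms,
              onset_threshold_uv = config$onset_threshold_uv,
              area_fraction = config$area_fraction)

  perm <- signed_area_permutation_test(
    diffs = lapply(clean, lateral_trial_diffs),
    labels = lapply(clean, function(e) e$trials$symbol_position),
    trial_types = lapply(clean, function(e) e$trials$trial_type),
    time = clean[[1]]$time, window_ms = config$area_window_ms,
    n_permutations = config$n_perm, seed = derive_seed(config$seed, 4000))

  decoding <- stats::setNames(lapply(c("exemplar_match", "foil"),
                                     function(ty) {
    tcs <- lapply(seq_along(clean), function(i) {
      e <- clean[[i]]
      sel <- e$trials$trial_type == ty
      decode_timecourse(subset_trials(e, sel),
                        e$trials$symbol_position[sel],
                        n_folds = config$n_folds,
                        n_iterations = config$n_iterations,
                        window_ms = config$area_window_ms,
                        seed = derive_seed(config$seed, 5000 + i))
    })
    acc <- do.call(rbind, lapply(tcs, `[[`, "accuracy"))
    clus <- cluster_permutation_null(
      acc, tcs[[1]]$time, alpha = config$alpha,
      n_permutations = config$n_cluster_perm,
      n_attempts = tcs[[1]]$n_attempts_per_point,
      seed = derive_seed(config$seed, 6000))
    list(timecourses = tcs,
         window = window_mean_accuracy(tcs, config$area_window_ms),
         clusters = clus)
  }), c("exemplar_match", "foil"))

  conds <- n2pc_conditions()
  measures <- list(mean_amplitude = mean_amplitude,
                   signed_negative_area = signed_negative_area,
                   fractional_area_latency = fractional_area_latency)
  sme <- do.call(rbind, lapply(seq_len(nrow(conds)), function(j) {
    do.call(rbind, lapply(names(measures), function(mn) {
      bsmes <- vapply(seq_along(clean), function(i) {
        e <- clean[[i]]
        sel <- e$trials$symbol_position == conds$symbol_position[j] &
          e$trials$trial_type == conds$trial_type[j]
        win <- if (mn == "mean_amplitude") config$amp_window_ms
               else config$area_window_ms
        bootstrap_sme(lateral_trial_diffs(subset_trials(e, sel)),
                      e$time, measures[[mn]], n_bootstrap = config$n_boot,
                      seed = derive_seed(config$seed, 7000 + 100 * j + i),
                      window_ms = win)$bsme
      }, numeric(1))
      ok <- !is.na(bsmes)
      data.frame(symbol_position = conds$symbol_position[j],
                 trial_type = conds$trial_type[j], measure = mn,
                 rms = rms_aggregate(bsmes[ok]), n = sum(ok))
    }))
  }))

  behavior <- behavioral_summaries(do.call(rbind, lapply(cohort, function(p) {
    cbind(p$schedule, participant = p$id)
  })))
  afc <- score_2afc(do.call(rbind, lapply(cohort, function(p) {
    cbind(p$afc, participant = p$id)
  })))

  structure(
    list(fit = fit, permutation = perm, decoding = decoding, sme = sme,
         behavior = behavior, afc = afc, retention = retention,
         config = config),
    class = "laterp_report"
  )
}

#' @export
print.laterp_report <- function(x, ...) {
  cat("== laterp pipeline report ==\n")
  cat("participants:", x$config$n_participants,
      " blocks:", x$config$n_blocks,
      " mean retention:", signif(mean(x$retention), 3), "\n\n")
  print(x$fit)
  cat("\nSigned-area permutation test:\n")
  print(x$permutation)
  for (ty in names(x$decoding)) {
    w <- x$decoding[[ty]]$window
    cat("\nDecoding (", ty, "): window mean = ", signif(w$mean, 3),
        ", t(", w$df, ") = ", signif(w$t, 3), ", p = ",
        signif(w$p_value, 3), "\n", sep = "")
  }
  cat("\nSME (RMS across participants):\n")
  print(x$sme)
  invisible(x)
}

#' Within-subject 2 x 2 ANOVA
#'
#' Standard repeated-measures decomposition of a participant x 2 x 2 table
#' into two main effects and the interaction, each on 1 and n-1 degrees of
#' freedom, with partial eta squared.  Each effect is computed from its
#' contrast scores (the one-df within-subject formulation), which is
#' algebraically identical to the textbook sums-of-squares decomposition.
#' Rows with missing cells are excluded listwise (count reported).
#'
#' @param values Numeric array `[n, 2, 2]` (participant x factor A x
#'   factor B).
#' @return Data frame of class `rm_anova_2x2` with rows `A`, `B`, `A:B`
#'   and columns `F`, `df1`, `df2`, `p`, `pes`, plus attribute
#'   `n_excluded`.
#' @export
rm_anova_2x2 <- function(values) {
  stopifnot(length(dim(values)) == 3L, dim(values)[2] == 2L,
            dim(values)[3] == 2L)
  complete <- apply(!is.na(values), 1, all)
  n_excluded <- sum(!complete)
  v <- values[complete, , , drop = FALSE]
  n <- dim(v)[1]
  if (n < 3L) stop("need >= 3 complete participants")
  contrast_f <- function(score) {
    ss_eff <- n * mean(score)^2
    ss_err <- sum((score - mean(score))^2)
    if (ss_err == 0) {
      f <- if (ss_eff == 0) 0 else Inf
    } else {
      f <- ss_eff / (ss_err / (n - 1))
    }
    p <- if (is.infinite(f)) 0 else stats::pf(f, 1, n - 1, lower.tail = FALSE)
    pes <- if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)
    c(F = f, df1 = 1, df2 = n - 1, p = p, pes = pes)
  }
  eff_a <- (v[, 1, 1] + v[, 1, 2] - v[, 2, 1] - v[, 2, 2]) / 2
  eff_b <- (v[, 1, 1] + v[, 2, 1] - v[, 1, 2] - v[, 2, 2]) / 2
  eff_ab <- (v[, 1, 1] - v[, 1, 2] - v[, 2, 1] + v[, 2, 2]) / 2
  out <- as.data.frame(rbind(A = contrast_f(eff_a), B = contrast_f(eff_b),
                             `A:B` = contrast_f(eff_ab)))
  dn <- dimnames(values)
  attr(out, "factors") <- list(A = dn[[2]], B = dn[[3]])
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("rm_anova_2x2", "data.frame")
  out
}

#' Behavioral summaries for the 2 x 2 design
#'
#' Per-condition (symbol position x trial type) mean and SD of reaction
#' time on correct trials, and accuracy, per participant, with Target
#' Absent trials excluded; plus the within-subject 2 x 2 ANOVAs on RT and
#' accuracy when several participants are present.
#'
#' @param schedule Schedule data frame with filled behavior (see
#'   [simulate_behavior()]); a `participant` column separates participants
#'   (a single participant is assumed otherwise).
#' @return List with `table` (per participant x condition summaries) and,
#'   when >= 3 participants, `anova_rt` and `anova_accuracy`.
#' @export
behavioral_summaries <- function(schedule) {
  if (is.null(schedule$participant)) schedule$participant <- 1L
  s <- schedule[schedule$trial_type != "target_absent", ]
  if (is.null(s$symbol_position)) {
    s$symbol_position <- ifelse(s$item_side == s$pattern_side,
                                "patterned", "random")
  }
  tab <- do.call(rbind, lapply(split(
    s, list(s$participant, s$symbol_position, s$trial_type), drop = TRUE),
    function(g) {
      ok <- !is.na(g$correct) & g$correct & !is.na(g$rt_ms)
      data.frame(participant = g$participant[1],
                 symbol_position = g$symbol_position[1],
                 trial_type = g$trial_type[1],
                 n_trials = nrow(g),
                 accuracy = mean(g$correct, na.rm = TRUE),
                 rt_mean = if (any(ok)) mean(g$rt_ms[ok]) else NA_real_,
                 rt_sd = if (sum(ok) > 1) stats::sd(g$rt_ms[ok]) else NA_real_)
    }))
  rownames(tab) <- NULL
  out <- list(table = tab)
  parts <- sort(unique(tab$participant))
  if (length(parts) >= 3L) {
    cube <- function(col) {
      v <- array(NA_real_, dim = c(length(parts), 2, 2),
                 dimnames = list(NULL, c("patterned", "random"),
                                 c("exemplar_match", "foil")))
      for (r in seq_len(nrow(tab))) {
        v[match(tab$participant[r], parts), tab$symbol_position[r],
          tab$trial_type[r]] <- tab[[col]][r]
      }
      v
    }
    out$anova_rt <- rm_anova_2x2(cube("rt_mean"))
    out$anova_accuracy <- rm_anova_2x2(cube("accuracy"))
  }
  out
}

#' Score the 2AFC recognition test
#'
#' Proportion of true-triplet choices per participant, a group one-sample t
#' test against chance (0.5) and the mean confidence rating.  A null result
#' indicates no explicit knowledge of the patterns.
#'
#' @param responses Data frame with `choice_correct`, `confidence` and
#'   optionally `participant` (single participant assumed otherwise).
#' @return List with `proportion` (group mean), `per_participant`, `t`,
#'   `df`, `p_value`, `mean_confidence`.
#' @export
score_2afc <- function(responses) {
  if (nrow(responses) < 2L) stop("need >= 2 responses")
  if (is.null(responses$participant)) responses$participant <- 1L
  per <- vapply(split(responses$choice_correct, responses$participant),
                mean, numeric(1))
  out <- list(proportion = mean(per), per_participant = per,
              t = NA_real_, df = length(per) - 1L, p_value = NA_real_,
              mean_confidence = mean(responses$confidence))
  if (length(per) >= 3L && stats::sd(per) > 0) {
    tt <- stats::t.test(per, mu = 0.5)
    out$t <- unname(tt$statistic)
    out$p_value <- tt$p.value
  }
  out
}
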