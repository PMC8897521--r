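test_that("earlobe re-referencing subtracts the earlobe mean everywhere", {
  time <- std_time()
  zero_ref <- epochs_from_traces(rep(3, 301), rep(-1, 301),
                                 extra = list(A1 = rep(0, 301),
                                              A2 = rep(0, 301)))
  out <- rereference_to_earlobes(zero_ref)
  expect_equal(out$channels, c("PO7", "PO8"))
  expect_equal(out$data[1, 1, ], rep(3, 301))       # zero earlobes: unchanged

  set.seed(1)
  a1 <- rnorm(301); a2 <- rnorm(301)
  po7 <- rnorm(301); po8 <- rnorm(301)
  ep <- epochs_from_traces(po7, po8, extra = list(A1 = a1, A2 = a2))
  out <- rereference_to_earlobes(ep)
  expect_equal(out$data[1, 1, ], po7 - (a1 + a2) / 2)  # arithmetic oracle
  expect_equal(out$data[1, 2, ], po8 - (a1 + a2) / 2)

  # channels equal to the earlobe mean become exactly zero
  m <- (a1 + a2) / 2
  ep2 <- epochs_from_traces(m, m, extra = list(A1 = a1, A2 = a2))
  out2 <- rereference_to_earlobes(ep2)
  expect_true(all(abs(out2$data) < 1e-12))

  expect_error(rereference_to_earlobes(epochs_from_traces(po7, po8)),
               "not found")
})

test_that("filtering is zero-phase and shapes the spectrum as specified", {
  time <- std_time()
  imp <- numeric(301); imp[150] <- 1
  f <- filter_epochs(epochs_from_traces(imp, imp))
  expect_equal(which.max(abs(f$data[1, 1, ])), 150)  # no group delay

  mid <- 100:200                                     # avoid epoch edges
  s5 <- sin(2 * pi * 5 * time / 1000)
  f5 <- filter_epochs(epochs_from_traces(s5, s5),
                      filter_spec(highpass_hz = NULL))
  expect_equal(max(abs(f5$data[1, 1, mid])) / max(abs(s5[mid])), 1,
               tolerance = 0.01)                     # 5 Hz passband intact

  s60 <- sin(2 * pi * 60 * time / 1000)
  f60 <- filter_epochs(epochs_from_traces(s60, s60),
                       filter_spec(lowpass_hz = NULL, highpass_hz = NULL))
  atten <- max(abs(s60[mid])) / max(abs(f60$data[1, 1, mid]))
  expect_gte(atten, 20)                              # notch kills 60 Hz

  expect_error(filter_epochs(epochs_from_traces(s5, s5),
                             filter_spec(lowpass_hz = 260)),
               "Nyquist")
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  time <- std_time()
  const <- epochs_from_traces(rep(3, 301), rep(3, 301))
  out <- baseline_correct(const)
  expect_true(all(out$data == 0))

  two_seg <- ifelse(time <= 0, 1, 4)
  ep <- epochs_from_traces(two_seg, two_seg)
  out <- baseline_correct(ep)
  expect_equal(out$data[1, 1, time > 0], rep(3, sum(time > 0)))

  set.seed(2)
  noisy <- epochs_from_traces(rnorm(301, 5), rnorm(301, -5))
  out <- baseline_correct(noisy)
  bl <- time >= -100 & time <= 0
  expect_lt(abs(mean(out$data[1, 1, bl])), 1e-9)
  expect_lt(abs(mean(out$data[1, 2, bl])), 1e-9)
  expect_equal(baseline_correct(out)$data, out$data)  # idempotent
})

test_that("artifact rejection applies class thresholds within their windows", {
  time <- std_time()
  mk <- function(heog) {
    epochs_from_traces(rep(0, 301), rep(0, 301),
                       extra = list(HEOG = heog, VEOG = rep(0, 301)))
  }
  clean <- reject_artifacts(mk(rep(0, 301)))
  expect_equal(sum(clean$rejected), 0L)

  inside <- rep(0, 301); inside[time == 100] <- 30
  hit <- reject_artifacts(mk(inside))
  expect_true(hit$rejected[1])
  expect_equal(unname(hit$counts["heog"]), 1L)

  outside <- rep(0, 301); outside[time == -50] <- 30
  miss <- reject_artifacts(mk(outside))
  expect_false(miss$rejected[1])                 # outside the 0-300 window

  # VEOG tolerates 30 uV but not 70 uV; scalp tolerates 70 but not 90
  mk2 <- function(veog, po7) {
    epochs_from_traces(po7, rep(0, 301),
                       extra = list(HEOG = rep(0, 301), VEOG = veog))
  }
  spike <- function(amp, at = 100) { v <- rep(0, 301); v[time == at] <- amp; v }
  expect_false(reject_artifacts(mk2(spike(30), rep(0, 301)))$rejected[1])
  expect_true(reject_artifacts(mk2(spike(70), rep(0, 301)))$rejected[1])
  expect_false(reject_artifacts(mk2(rep(0, 301), spike(70)))$rejected[1])
  expect_true(reject_artifacts(mk2(rep(0, 301), spike(90, -50)))$rejected[1])
})

test_that("rejection is monotone in thresholds", {
  sched <- generate_design(1, pattern_side = "left", seed = 1)
  ep <- simulate_epochs(sched, ground_truth(noise_sd_uv = 20,
                                            artifact_rate = 0.2),
                        seed = 2, scalp_channels = c("PO7", "PO8"))
  tight <- reject_artifacts(ep, rejection_criteria())
  loose <- reject_artifacts(ep, rejection_criteria(heog_abs_uv = 50,
                                                   veog_abs_uv = 120,
                                                   other_abs_uv = 160))
  expect_true(all(tight$rejected | !loose$rejected))  # loose subset of tight
  expect_lte(sum(loose$rejected), sum(tight$rejected))
})

test_that("analysis selection keeps correct item-present trials only", {
  time <- std_time()
  tr <- trial_meta(
    trial_type = c("exemplar_match", "exemplar_match", "exemplar_match",
                   "exemplar_match", "target_absent", "target_absent"),
    item_side = c("left", "left", "right", "right", "none", "none"),
    correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  traces <- replicate(6, list(list(rep(0, 301), rep(0, 301))))
  ep <- epochs_from_matrix(traces, c("PO7", "PO8"), trials = tr)
  out <- select_analysis_trials(ep)
  expect_equal(dim(out$data)[1], 3L)
  expect_equal(attr(out, "retention"), 0.5)

  only_ta <- subset_trials(ep, tr$trial_type == "target_absent")
  expect_warning(res <- select_analysis_trials(only_ta), "no trials")
  expect_equal(dim(res$data)[1], 0L)
})

test_that("the full chain runs in order and reports retention", {
  sched <- generate_design(1, pattern_side = "left", seed = 5)
  sched <- simulate_behavior(sched, seed = 6)
  ep <- simulate_epochs(sched, ground_truth(noise_sd_uv = 5,
                                            artifact_rate = 0.1),
                        seed = 7, scalp_channels = c("PO7", "PO8"),
                        include_earlobes = TRUE)
  out <- preprocess(ep)
  expect_false(any(c("A1", "A2") %in% out$epochs$channels))
  expect_true(all(out$epochs$trials$trial_type != "target_absent"))
  expect_true(all(out$epochs$trials$correct))
  expect_true(out$retention > 0 && out$retention <= 1)
  bl <- out$epochs$time <= 0
  expect_lt(max(abs(apply(out$epochs$data[, , bl, drop = FALSE],
                          c(1, 2), mean))), 1e-8)
})
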