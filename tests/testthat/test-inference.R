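test_that("percentile criterion follows the nearest-rank and add-one rules", {
  set.seed(1)
  null <- runif(500)
  top <- percentile_criterion(max(null) + 1e-9, null)
  expect_true(top$significant)
  expect_equal(top$p_value, 1 / 501)

  mid <- percentile_criterion(median(null), null)
  expect_false(mid$significant)
  expect_equal(mid$p_value, 0.5, tolerance = 0.01)

  # nearest-rank oracle for the boundary decision
  crit <- sort(null)[ceiling(0.95 * 500)]
  at <- percentile_criterion(crit, null)
  expect_false(at$significant)                     # must exceed, not equal
  just <- percentile_criterion(crit + 1e-12, null)
  expect_true(just$significant)
  expect_error(percentile_criterion(1, c(0.1, NA)), "NaN/NA")
})

test_that("an extreme observed area beats every permutation (p = 1/501)", {
  time <- seq(-100, 500, by = 2)
  set.seed(2)
  # 3 participants, strong patterned-only negativity, mild noise
  mk_part <- function() {
    n <- 24
    lab <- rep(c("patterned", "random"), each = n / 2)
    d <- matrix(rnorm(n * length(time), 0, 0.3), n, length(time))
    pulse <- raised_cosine_pulse(time, -5, 180, 120)
    d[lab == "patterned", ] <-
      d[lab == "patterned", ] + rep(pulse, each = n / 2)
    list(d = d, lab = lab)
  }
  parts <- lapply(1:3, function(i) mk_part())
  res <- signed_area_permutation_test(
    diffs = lapply(parts, `[[`, "d"), labels = lapply(parts, `[[`, "lab"),
    time = time, n_permutations = 500, seed = 3)
  expect_equal(unname(res$p_value["patterned.all"]), 1 / 501)
  expect_true(res$significant[match("patterned.all", names(res$observed))])
  expect_equal(dim(res$null_distribution), c(500L, 2L))
})

test_that("the permutation null is reproducible and stratified shuffles run", {
  time <- seq(-100, 500, by = 2)
  set.seed(4)
  diffs <- lapply(1:3, function(i) matrix(rnorm(40 * length(time)), 40,
                                          length(time)))
  labels <- lapply(1:3, function(i) rep(c("patterned", "random"), 20))
  types <- lapply(1:3, function(i) rep(c("exemplar_match", "foil"),
                                       each = 20))
  a <- signed_area_permutation_test(diffs, labels, types, time = time,
                                    n_permutations = 120, seed = 9)
  b <- signed_area_permutation_test(diffs, labels, types, time = time,
                                    n_permutations = 120, seed = 9)
  expect_identical(a$null_distribution, b$null_distribution)
  expect_equal(names(a$observed),
               c("patterned.exemplar_match", "random.exemplar_match",
                 "patterned.foil", "random.foil"))
  expect_warning(
    signed_area_permutation_test(diffs, labels, types, time = time,
                                 n_permutations = 50, seed = 1),
    "fewer than 100")
  # a participant with only one label is dropped with a warning
  labels[[3]] <- rep("patterned", 40)
  expect_warning(
    signed_area_permutation_test(diffs, labels, types, time = time,
                                 n_permutations = 120, seed = 9),
    "excluded")
})

test_that("cluster t masses match per-point t tests summed over runs", {
  time <- seq(150, 300, by = 2)
  n_t <- length(time)
  set.seed(5)
  # baseline slightly below chance so only the two injected runs can form
  # clusters under the one-sided test
  acc <- matrix(0.45 + rnorm(12 * n_t, 0, 0.002), 12, n_t)
  acc[, 11:20] <- acc[, 11:20] + 0.35
  acc[, 41:45] <- acc[, 41:45] + 0.25
  res <- cluster_t_mass(acc, time)
  expect_equal(nrow(res$clusters), 2L)
  # independent oracle: stats::t.test per point
  tvals <- vapply(seq_len(n_t), function(j) {
    unname(t.test(acc[, j], mu = 0.5)$statistic)
  }, numeric(1))
  expect_equal(res$clusters$t_mass[1], sum(tvals[11:20]), tolerance = 1e-8)
  expect_equal(res$clusters$t_mass[2], sum(tvals[41:45]), tolerance = 1e-8)
  expect_equal(res$clusters$start_ms, time[c(11, 41)])
  expect_equal(res$clusters$end_ms, time[c(20, 45)])
})

test_that("degenerate accuracy series are handled as flagged cases", {
  time <- seq(150, 300, by = 2)
  at_chance <- matrix(0.5, 5, length(time))
  expect_warning(res <- cluster_t_mass(at_chance, time), "zero variance")
  expect_equal(nrow(res$clusters), 0L)

  perfect <- matrix(1, 5, length(time))
  res2 <- cluster_t_mass(perfect, time)
  expect_equal(nrow(res2$clusters), 1L)            # one cluster spanning all
  expect_equal(res2$clusters$start_ms, 150)
  expect_equal(res2$clusters$end_ms, 300)
})

test_that("cluster permutation null scores clusters against max masses", {
  time <- seq(150, 300, by = 2)
  set.seed(6)
  acc <- matrix(rbinom(10 * length(time), 60, 0.5) / 60, 10)
  acc[, 20:40] <- acc[, 20:40] + 0.25
  res <- cluster_permutation_null(acc, time, n_permutations = 300, seed = 7)
  big <- which.max(res$clusters$t_mass)
  expect_true(res$cluster_significant[big])
  expect_equal(res$p_values[big], 1 / 301)
  res_b <- cluster_permutation_null(acc, time, n_permutations = 300, seed = 7)
  expect_identical(res$null_t_mass, res_b$null_t_mass)  # same seed, same null
})

test_that("label-permutation nulls re-run the decoder", {
  set.seed(8)
  n <- 6; nch <- 4; ns <- 5
  time <- seq(0, 8, by = 2)
  inputs <- lapply(1:3, function(i) {
    list(x = array(rnorm(2 * n * nch * ns), c(2 * n, nch, ns)),
         labels = rep(c("patterned", "random"), each = n),
         time = time, n_iterations = 1)
  })
  acc <- t(vapply(inputs, function(di) {
    decode_timecourse(di$x, di$labels, time = di$time,
                      n_iterations = di$n_iterations, seed = 1)$accuracy
  }, numeric(ns)))
  expect_warning(
    res <- cluster_permutation_null(acc, time, n_permutations = 8,
                                    n_attempts = 6,
                                    method = "label_permutation",
                                    decode_inputs = inputs, seed = 9),
    "fewer than 100")
  expect_length(res$null_t_mass, 8L)
  expect_true(all(res$null_t_mass >= 0))
})

test_that("bootstrapped SME tracks the sampling error of the measure", {
  time <- std_time()
  same <- matrix(rep(sin(time / 50), each = 20), 20)   # identical trials
  z <- bootstrap_sme(same, time, mean_amplitude, n_bootstrap = 200, seed = 1)
  expect_identical(z$bsme, 0)

  set.seed(2)
  sigma <- 5
  tr_small <- matrix(rnorm(50 * 301, 0, sigma), 50)
  tr_big <- matrix(rnorm(200 * 301, 0, sigma), 200)
  s_small <- bootstrap_sme(tr_small, time, mean_amplitude,
                           n_bootstrap = 800, seed = 3)
  s_big <- bootstrap_sme(tr_big, time, mean_amplitude,
                         n_bootstrap = 800, seed = 4)
  expect_lt(abs(s_big$bsme / s_small$bsme - 0.5), 0.1)

  # undefined iterations are dropped and counted: a mostly-positive wave
  # makes fractional-area latency undefined in some resamples
  pos <- matrix(rnorm(10 * 301, 0.8, 0.1), 10)
  s_und <- bootstrap_sme(pos, time, fractional_area_latency,
                         n_bootstrap = 100, seed = 5)
  expect_true(s_und$n_undefined > 0 || s_und$defined)
})

test_that("RMS aggregation follows the root-mean-square formula", {
  expect_equal(rms_aggregate(rep(2.5, 19)), 2.5)
  expect_equal(rms_aggregate(c(3, 4)), sqrt(12.5))
  set.seed(3)
  v <- abs(rnorm(19))
  expect_equal(rms_aggregate(v), sqrt(mean(v^2)))
  expect_gte(rms_aggregate(v), mean(v))            # RMS >= mean
  expect_lte(rms_aggregate(v), max(v))             # RMS <= max
  expect_error(rms_aggregate(numeric(0)), "empty")
})
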