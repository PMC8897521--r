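test_that("mean amplitude averages the closed measurement window", {
  time <- std_time()
  expect_equal(mean_amplitude(wave_of(rep(-2, 301)))$value, -2)

  # +1 before / -1 after the window midpoint averages to ~0
  v <- ifelse(time <= 250, 1, -1)
  v[!(time >= 200 & time <= 300)] <- 99      # outside window must not matter
  expect_equal(mean_amplitude(wave_of(v))$value, mean(v[time >= 200 &
                                                        time <= 300]))
  expect_lt(abs(mean_amplitude(wave_of(v))$value), 0.05)

  # raised-cosine pulse spanning exactly the window: mean ~ half the peak
  pulse <- raised_cosine_pulse(time, -2, 200, 100)
  expect_equal(mean_amplitude(wave_of(pulse))$value, -1, tolerance = 0.03)
  expect_error(mean_amplitude(wave_of(pulse), c(600, 700)), "no samples")
})

test_that("mean amplitude is linear in the wave", {
  set.seed(1)
  a <- random_smooth_wave(); b <- random_smooth_wave()
  ma <- function(v) mean_amplitude(wave_of(v))$value
  expect_equal(ma(2 * a + 3 * b), 2 * ma(a) + 3 * ma(b))
})

test_that("signed negative area integrates only the negative lobe", {
  time <- std_time()
  expect_equal(signed_negative_area(wave_of(abs(sin(time))))$value, 0)

  # constant -1 uV across the whole 150 ms window: rectangle of 150 uV*ms
  expect_equal(signed_negative_area(wave_of(rep(-1, 301)))$value, 150)

  # adding -c over the window grows the area by exactly c * width
  set.seed(2)
  v <- random_smooth_wave()
  base <- signed_negative_area(wave_of(v - 10))$value   # all-negative wave
  shift <- signed_negative_area(wave_of(v - 12))$value
  expect_equal(shift - base, 2 * 150)
})

test_that("area and latency measures match 10x-oversampled oracles", {
  # brute-force quadrature / scanning on a 10x-refined grid
  time <- std_time()
  fine_oracle <- function(v) {
    ft <- seq(150, 300, by = 0.2)
    fv <- approx(time, v, ft)$y
    neg <- -pmin(fv, 0)
    d <- diff(ft)
    area <- sum((neg[-1] + neg[-length(neg)]) / 2 * d)
    cum <- c(0, cumsum((neg[-1] + neg[-length(neg)]) / 2 * d))
    fal <- if (area > 0) ft[which(cum >= area / 2)[1]] else NA_real_
    onset <- {
      k <- which(fv <= -0.75)
      if (length(k) == 0) NA_real_ else ft[k[1]]
    }
    list(area = area, fal = fal, onset = onset)
  }
  set.seed(3)
  n_checked <- 0L
  for (i in 1:100) {
    v <- random_smooth_wave(sd = 1.2)
    o <- fine_oracle(v)
    a <- signed_negative_area(wave_of(v))$value
    expect_equal(a, o$area, tolerance = 0.005)
    f <- fractional_area_latency(wave_of(v))
    if (!is.na(o$fal) && f$defined) {
      expect_equal(f$value, o$fal, tolerance = 0.005)
      n_checked <- n_checked + 1L
    }
    on <- onset_threshold_crossing(wave_of(v))
    if (!is.na(o$onset) && on$defined) {
      expect_equal(on$value, o$onset, tolerance = 0.005)
    }
    expect_equal(on$defined, !is.na(o$onset))
  }
  expect_gt(n_checked, 50L)           # most random waves exercise the path
})

test_that("fractional-area latency splits the negative area as requested", {
  time <- std_time()
  # symmetric pulse centered at 225 ms inside the window
  pulse <- raised_cosine_pulse(time, -2, 175, 100)
  expect_equal(fractional_area_latency(wave_of(pulse))$value, 225)

  pos <- fractional_area_latency(wave_of(abs(cos(time)) + 0.1))
  expect_false(pos$defined)
  expect_true(is.na(pos$value))

  # two-rectangle wave: -2 uV on 150-200, -1 uV on 200-300; the half-area
  # point sits at the rectangle boundary
  v <- numeric(301)
  v[time >= 150 & time < 200] <- -2
  v[time >= 200 & time <= 300] <- -1
  expect_equal(fractional_area_latency(wave_of(v))$value, 200,
               tolerance = 1.5)

  # asymmetric fraction
  q <- fractional_area_latency(wave_of(rep(-1, 301)), fraction = 0.25)
  expect_equal(q$value, 150 + 0.25 * 150, tolerance = 0.5)
})

test_that("threshold-crossing onset interpolates linearly", {
  time <- std_time()
  ramp <- approx(c(-100, 150, 300, 500), c(0, 0, -1.5, -1.5), time)$y
  expect_equal(onset_threshold_crossing(wave_of(ramp))$value, 225,
               tolerance = 0.01)

  shallow <- wave_of(rep(-0.4, 301))
  res <- onset_threshold_crossing(shallow)
  expect_false(res$defined)

  # steep noiseless pulse: recovered within one sample of the closed form
  pulse <- raised_cosine_pulse(time, -2, 180, 120)
  analytic <- 180 + 120 * acos(1 - 0.75) / (2 * pi)
  expect_equal(onset_threshold_crossing(wave_of(pulse))$value, analytic,
               tolerance = 2)
  expect_error(onset_threshold_crossing(wave_of(pulse), threshold_uv = 0.5),
               "negative")
})

test_that("jackknife latency retrieves scores and flags degenerate input", {
  time <- std_time()
  # equal-slope ramps: latency is linear in the intercept, so the
  # back-transformation identity holds exactly
  slope <- -0.02                           # uV per ms
  mk <- function(b) wave_of(pmin(0, slope * (time - 150)) + b)
  waves <- lapply(c(0.1, 0, -0.1, 0.05), mk)
  loo <- jackknife_grand_averages(waves)
  res <- jackknife_latency_analysis(loo)
  expect_true(res$a$defined)
  expect_equal(mean(res$a$scores), res$a$grand_latency, tolerance = 1e-6)

  # identical participants: zero variance among subsample latencies
  same <- rep(list(mk(0)), 4)
  res2 <- jackknife_latency_analysis(jackknife_grand_averages(same),
                                     jackknife_grand_averages(same))
  expect_true(is.na(res2$contrast$t_corrected))
  expect_match(res2$contrast$note, "zero variance")

  # a condition that never reaches threshold is excluded from the contrast
  flat <- rep(list(wave_of(rep(-0.1, 301))), 4)
  res3 <- jackknife_latency_analysis(jackknife_grand_averages(waves),
                                     jackknife_grand_averages(flat))
  expect_false(res3$b$defined)
  expect_match(res3$contrast$note, "excluded")
})

test_that("jackknife contrast detects a clear onset shift", {
  time <- std_time()
  set.seed(6)
  early <- lapply(1:8, function(i) {
    wave_of(raised_cosine_pulse(time, -2, 160, 120) +
              random_smooth_wave(sd = 0.05))
  })
  late <- lapply(1:8, function(i) {
    wave_of(raised_cosine_pulse(time, -2, 220, 80) +
              random_smooth_wave(sd = 0.05))
  })
  res <- jackknife_latency_analysis(jackknife_grand_averages(early),
                                    jackknife_grand_averages(late))
  expect_lt(res$contrast$mean_difference, -40)
  expect_lt(res$contrast$p_value, 0.05)
})
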