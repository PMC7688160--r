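test_that("cycles are half-open R-peak intervals covering the peak span", {
  time <- seq(0, 0.26, by = 0.001)
  tr <- velocity_trace(time, rep(100, length(time)),
                       r_peaks = c(0, 0.13, 0.26))
  cys <- segment_cycles(tr)
  expect_length(cys, 2)
  expect_equal(cys[[1]]$start, 0); expect_equal(cys[[1]]$end, 0.13)
  # half-open: the sample at 0.13 belongs to the second cycle only
  expect_false(0.13 %in% cys[[1]]$time)
  expect_true(min(cys[[2]]$time) == 0.13)
  # partition: every in-span sample appears exactly once
  n_in <- sum(time >= 0 & time < 0.26)
  expect_equal(length(cys[[1]]$time) + length(cys[[2]]$time), n_in)
})

test_that("gating fails below two R-peaks", {
  time <- seq(0, 0.2, by = 0.001)
  tr <- velocity_trace(time, rep(1, length(time)), r_peaks = 0.1)
  expect_error(segment_cycles(tr), "gating")
})

test_that("trace invariants are enforced at construction", {
  expect_error(velocity_trace(c(0, 0.1, 0.05), c(1, 1, 1), 0), "increasing")
  expect_error(velocity_trace(c(0, 0.1, 0.2), c(1, -1, 1), 0), "non-negative")
  expect_error(velocity_trace(c(0, 0.001, 0.5), c(1, 1, 1), 0), "uniform")
  expect_error(velocity_trace(c(0, 0.1, 0.2), c(1, 1, 1), 0.3), "within")
})

test_that("ejection window matches the analytic sin^2 crossing points", {
  tr <- simulate_doppler(1200, n_cycles = 1)
  cy <- segment_cycles(tr)[[1]]
  t_ej <- 0.35 * 60 / 465
  w <- detect_ejection_window(cy, extend_to_baseline = FALSE)
  # oracle: sin^2(pi t / T) > 0.1 on a fraction 1 - 2 asin(sqrt(.1))/pi
  frac_oracle <- 1 - 2 * asin(sqrt(0.1)) / pi
  expect_equal((w$end - w$start) / t_ej, frac_oracle, tolerance = 0.02)
  # extension to baseline recovers the full ejection pulse
  we <- detect_ejection_window(cy)
  expect_equal((we$end - we$start) / t_ej, 1, tolerance = 0.02)
})

test_that("degenerate cycles are handled per contract", {
  expect_equal(with(detect_ejection_window(make_cycle(rep(500, 100))),
                    to - from + 1), 100)   # constant: whole cycle
  expect_error(detect_ejection_window(make_cycle(rep(0, 100))), "empty ejection")
  expect_error(detect_ejection_window(make_cycle(c(0, 1))), "3 samples")
  expect_equal(peak_systolic_velocity(make_cycle(rep(0, 50))), 0)
})

test_that("noise-free peak recovery is exact to sample resolution", {
  tr <- simulate_doppler(1000, heart_rate = 480,
                         ejection_fraction_of_cycle = 0.4, n_cycles = 3)
  cy <- segment_cycles(tr)[[1]]
  expect_equal(peak_systolic_velocity(cy, smooth_window = 1), 1000)
  # default smoothing flattens the peak by well under 0.5%
  expect_equal(peak_systolic_velocity(cy), 1000, tolerance = 5e-3)
})

test_that("noisy peak recovery is unbiased within 3% across seeds", {
  est <- vapply(1:20, function(s) {
    tr <- simulate_doppler(1200, n_cycles = 20, noise_sd = 60, seed = s)
    summarize_image(analyze_trace(tr))$peak_velocity
  }, 0)
  expect_equal(mean(est), 1200, tolerance = 0.03)
})

test_that("mean gradient follows the simplified Bernoulli convention", {
  expect_equal(mean_pressure_gradient(make_cycle(rep(1000, 200))), 4.0)
  tr <- simulate_doppler(1200, n_cycles = 1)
  cy <- segment_cycles(tr)[[1]]
  expect_equal(mean_pressure_gradient(cy), 2.16, tolerance = 0.05)
})

test_that("gradient scales quadratically with velocity and ignores time origin", {
  tr <- simulate_doppler(800, n_cycles = 1)
  cy <- segment_cycles(tr)[[1]]
  g1 <- mean_pressure_gradient(cy)
  cy_scaled <- cy; cy_scaled$velocity <- 3 * cy$velocity
  expect_equal(mean_pressure_gradient(cy_scaled), 9 * g1, tolerance = 1e-12)
  cy_shift <- cy; cy_shift$time <- cy$time + 11.5
  expect_equal(mean_pressure_gradient(cy_shift), g1)
})

test_that("aggregation is two-stage unweighted averaging", {
  imgs <- lapply(c(1000, 1100, 1200), function(p)
    structure(list(peak_velocity = p, mean_gradient = 4 * (p / 1000)^2,
                   n_cycles = 30, level = "image"), class = "hemo_summary"))
  ms <- summarize_mouse(imgs)
  expect_equal(ms$peak_velocity, 1100)
  expect_equal(ms$n_cycles, 90)
  expect_equal(ms$level, "mouse")
  # single cycle: the summary is that cycle's metrics
  one <- data.frame(cycle = 1, start = 0, peak_velocity = 950,
                    mean_gradient = 3.61)
  expect_equal(summarize_image(one)$peak_velocity, 950)
  expect_equal(summarize_image(one)$mean_gradient, 3.61)
})

test_that("identical noise-free cycles average to the single-cycle metric", {
  tr <- simulate_doppler(1000, heart_rate = 480,
                         ejection_fraction_of_cycle = 0.4, n_cycles = 20)
  per <- analyze_trace(tr, smooth_window = 1)
  expect_equal(max(per$peak_velocity) - min(per$peak_velocity), 0,
               tolerance = 1e-9)
  expect_equal(summarize_image(per)$peak_velocity, per$peak_velocity[1])
})

test_that("severity is a strict threshold at 1320 mm/s", {
  expect_true(classify_severe(1400))
  expect_false(classify_severe(1000))
  expect_false(classify_severe(1320))  # tie is not severe
  ms <- structure(list(peak_velocity = 1321, mean_gradient = 7,
                       n_cycles = 90, level = "mouse"), class = "hemo_summary")
  expect_true(classify_severe(ms))
  expect_false(classify_severe(ms, threshold = 1500))
})
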