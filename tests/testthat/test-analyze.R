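test_that("window extraction is half-open, re-timed, and validated", {
  tr <- signal_trace(function(t) t, duration = 120)
  win <- extract_window(tr, 55, 115)
  expect_length(win$output, 6000)
  expect_equal(win$time[1], 0)
  expect_equal(win$output[1], 55)           # first retained sample is t = 55
  expect_equal(win$output[6000], 114.99)    # 115 s itself is excluded
  # full-span window is the identity on samples (final fence-post dropped)
  full <- extract_window(tr, 0, 120)
  expect_equal(full$output, tr$output[1:12000])
  expect_error(extract_window(tr, 55, 116), "multiple of the cycle")
  expect_error(extract_window(tr, 55, 125, 10), "outside")
  expect_error(extract_window(tr, 55.003, 115.003), "grid")
})

test_that("cycle segmentation reshapes exactly and reconstructs the window", {
  tr <- signal_trace(function(t) sin(t), duration = 120)
  win <- extract_window(tr, 55, 115)
  cyc <- segment_cycles(win, 10, expected_n = 6)
  expect_equal(dim(cyc$cycles), c(6, 1000))
  expect_identical(as.numeric(t(cyc$cycles)), win$output)  # bit-exact
  one <- segment_cycles(extract_window(tr, 0, 10), 10)
  expect_equal(dim(one$cycles), c(1, 1000))
  expect_error(segment_cycles(win, 7), "cycles")

  # a 10 s-periodic sawtooth yields identical rows (built index-wise so the
  # waveform is exactly periodic in floating point)
  saw <- signal_trace(function(t) (round(t * 100) %% 1000) / 100,
                      duration = 120)
  rows <- segment_cycles(extract_window(saw, 55, 115), 10)$cycles
  for (k in 2:6) expect_identical(rows[k, ], rows[1, ])
})

test_that("baseline correction zeroes cycle starts, is idempotent, keeps slopes", {
  cyc <- segment_cycles(signal_trace(function(t) t %% 10 + 3,
                                     duration = 60) |> extract_window(0, 60), 10)
  cor1 <- baseline_correct(cyc)
  expect_true(all(cor1$cycles[, 1] == 0))
  expect_equal(cor1$cycles[1, 1:3], c(0, 0.01, 0.02))
  expect_identical(baseline_correct(cor1)$cycles, cor1$cycles)

  # pure linear drift: correction removes the per-cycle offset, keeps the ramp
  drift <- signal_trace(function(t) 0.2 * t, duration = 60)
  cd <- baseline_correct(segment_cycles(extract_window(drift, 0, 60), 10))
  for (k in 2:6) expect_equal(cd$cycles[k, ], cd$cycles[1, ])
  expect_equal(unname(cd$cycles[1, ]), 0.2 * (0:999) / 100)
})

test_that("cycle averaging is the pointwise mean and commutes with linear maps", {
  m <- matrix(c(0, 2, 0, 4), nrow = 2, byrow = TRUE)
  cyc <- structure(list(cycles = m, time = c(0, 0.01), cycle_duration = 0.02,
                        sampling_rate = 100, channel = "ch",
                        baseline_corrected = TRUE), class = "cycle_set")
  expect_equal(average_cycles(cyc)$output, c(0, 3))
  # mean of identical cycles is that cycle
  cyc$cycles <- rbind(c(1, 5), c(1, 5), c(1, 5))
  expect_equal(average_cycles(cyc)$output, c(1, 5))
  # linearity: average(a*X + Y) = a*average(X) + average(Y)
  X <- matrix(rnorm(20, 0, 1), 4, 5); Y <- matrix(rnorm(20), 4, 5)
  mk <- function(mm) structure(list(cycles = mm, time = (0:4) / 100,
                                    cycle_duration = 0.05, sampling_rate = 100,
                                    channel = "ch", baseline_corrected = TRUE),
                               class = "cycle_set")
  expect_equal(average_cycles(mk(2 * X + Y))$output,
               2 * average_cycles(mk(X))$output + average_cycles(mk(Y))$output)
})

test_that("averaging 6 noisy copies reduces the noise level by about sqrt(6)", {
  clean <- periodic_signal(seq(0, 60, by = 0.01))
  tr <- sensor_trace(seq(0, 60, by = 0.01), clean)
  noisy <- add_noise_and_drift(tr, noise_model(1, 0, seed = 11))
  cyc <- baseline_correct(segment_cycles(extract_window(noisy, 0, 60), 10))
  navg <- noise_level(average_cycles(cyc))
  expect_gt(navg, 0.35)
  expect_lt(navg, 0.47)
})

test_that("noise level is the residual RMS of a straight-line fit", {
  # exact line: zero noise
  t <- seq(0, 10, by = 0.01)
  line <- sensor_trace(t, 2 + 0.5 * t)
  expect_lt(noise_level(line), 1e-10)
  # the 3-point worked example: residuals (-1/3, 2/3, -1/3), RMS = sqrt(2/9)
  expect_equal(noise_level(c(0, 1, 0), time = 0:2, fit_window = c(0, 3)),
               sqrt(2 / 9), tolerance = 1e-12)
  # brute-force oracle: direct SSE minimisation over (intercept, slope)
  y <- c(0.3, -1.2, 0.7, 2.0, -0.5); tt <- seq(0, 0.04, by = 0.01)
  sse <- function(par) sum((y - par[1] - par[2] * tt)^2)
  opt <- optim(c(0, 0), sse, method = "BFGS")
  expect_equal(noise_level(y, time = tt, fit_window = c(0, 1)),
               sqrt(opt$value / length(y)), tolerance = 1e-6)
  expect_error(noise_level(c(1, 2), time = 0:1, fit_window = c(0, 2)),
               "fewer than 3")
})

test_that("noise level estimator matches OLS residual expectation and divisor option", {
  n <- 100; sigma <- 2
  ests <- vapply(1:300, function(s) {
    y <- local({set.seed(s); rnorm(n, sd = sigma)})
    noise_level(y, time = seq(0, 0.99, by = 0.01), fit_window = c(0, 1))
  }, 0)
  expect_rel_equal(mean(ests), sigma * sqrt((n - 2) / n), 0.03)
  # n-2 divisor removes the OLS bias
  y <- local({set.seed(1); rnorm(n)})
  tt <- seq(0, 0.99, by = 0.01)
  expect_equal(noise_level(y, time = tt, fit_window = c(0, 1), divisor = "n-2"),
               noise_level(y, time = tt, fit_window = c(0, 1)) * sqrt(n / (n - 2)))
})

test_that("noise level ignores constant offsets and linear ramps", {
  y <- local({set.seed(5); rnorm(200)})
  t <- seq(9, 10.99, by = 0.01)
  base <- noise_level(y, time = t, fit_window = c(9, 10))
  expect_equal(noise_level(y + 7, time = t, fit_window = c(9, 10)), base)
  expect_equal(noise_level(y + 3 * t, time = t, fit_window = c(9, 10)), base)
})

test_that("signal intensity is the 5 s sample of a corrected cycle", {
  t <- seq(0, 9.99, by = 0.01)
  y <- numeric(1000); y[501] <- 10.6   # value at exactly 5 s
  cycle <- sensor_trace(t, y)
  expect_equal(signal_intensity(cycle), 10.6)
  expect_equal(signal_intensity(sensor_trace(t, rep(0, 1000))), 0)
  # invariance to constant offsets applied before baseline correction
  shifted <- sensor_trace(seq(0, 59.99, by = 0.01),
                          periodic_signal(seq(0, 59.99, by = 0.01)) + 123)
  plain <- sensor_trace(seq(0, 59.99, by = 0.01),
                        periodic_signal(seq(0, 59.99, by = 0.01)))
  i1 <- signal_intensity(average_cycles(baseline_correct(segment_cycles(shifted))))
  i2 <- signal_intensity(average_cycles(baseline_correct(segment_cycles(plain))))
  expect_equal(i1, i2)
  # off-grid peak time is rejected
  coarse <- sensor_trace(seq(0, 9, by = 3), rep(0, 4))
  expect_error(signal_intensity(coarse), "grid")
})

test_that("theoretical noise scales as 1/sqrt(N) and differences add in quadrature", {
  expect_equal(theoretical_noise(1.5, 1), 1.5)
  expect_equal(theoretical_noise(1.2, 4), 0.6)
  expect_equal(theoretical_noise(2, 6), 2 / sqrt(6))
  expect_error(theoretical_noise(1, 0), ">= 1")
  expect_equal(propagate_difference_noise(3, 4), 5)
  expect_equal(propagate_difference_noise(2.5, 0), 2.5)
})

test_that("trace differencing is pointwise and grid-checked", {
  t <- seq(0, 10, by = 0.01)
  a <- sensor_trace(t, sin(t)); b <- sensor_trace(t, cos(t))
  expect_equal(difference_trace(a, b)$output, sin(t) - cos(t))
  expect_equal(difference_trace(a, a)$output, rep(0, length(t)))
  zero <- sensor_trace(t, rep(0, length(t)))
  expect_equal(difference_trace(a, zero)$output, a$output)
  short <- sensor_trace(t[1:500], sin(t[1:500]))
  expect_error(difference_trace(a, short), "grid")
})

test_that("measured noise of a differenced pair follows error propagation", {
  t <- seq(0, 9.99, by = 0.01)
  meas <- vapply(1:100, function(s) {
    a <- add_noise_and_drift(sensor_trace(t, numeric(1000)),
                             noise_model(1, 0, seed = 2 * s))
    b <- add_noise_and_drift(sensor_trace(t, numeric(1000)),
                             noise_model(1, 0, seed = 2 * s + 1))
    noise_level(difference_trace(a, b), fit_window = c(9, 10))
  }, 0)
  expect_gt(mean(meas), 1.30)
  expect_lt(mean(meas), 1.53)
})

test_that("replicate aggregation computes per-measurement S/N before averaging", {
  mk <- function(int, navg, type = "rdc") {
    structure(list(channel = "ch", type = type, n_cycles = 6, intensity = int,
                   noise_raw = navg * sqrt(6), noise_avg = navg,
                   noise_theory = navg, snr = abs(int) / navg,
                   noise_floor = FALSE, avg_cycle = NULL),
              class = "measurement_summary")
  }
  tab <- snr_summary(list(mk(5, 1), mk(5, 1), mk(5, 1)))
  expect_equal(tab$snr_mean, 5); expect_equal(tab$snr_sd, 0)
  tab2 <- snr_summary(list(mk(4, 1), mk(6, 1)))
  expect_equal(tab2$snr_mean, 5)
  expect_equal(tab2$snr_sd, sqrt(2))
  # mean-of-ratios, not ratio-of-means
  tab3 <- snr_summary(list(mk(10, 1), mk(2, 2)))
  expect_equal(tab3$snr_mean, mean(c(10, 1)))
  expect_false(isTRUE(all.equal(tab3$snr_mean,
                                mean(c(10, 2)) / mean(c(1, 2)))))
  expect_error(snr_summary(list(mk(1, 1))), "at least 2")
})

test_that("steady-state detector fires when cycle changes fall below tolerance", {
  tau <- 5
  tr <- simulate_measurement(list(one_comp_source(conc = 1)),
                             one_comp_film(tau = tau, g = -5e-6),
                             build_protocol("normal", "A", 5, 120, 100))
  k <- detect_steady_state(tr, 10)
  expect_false(is.na(k))
  expect_lte(k, ceiling(3 * tau / 10))
  # a trace that is periodic from the start reports zero transient cycles
  per <- signal_trace(periodic_signal, duration = 60)
  expect_equal(detect_steady_state(per, 10), 0L)
})

test_that("the full pipeline summary is internally consistent", {
  d <- fast_design(sigma = 0.5, drift = 0.02, seed = 3)
  tr <- simulate_measurement(d$sources, d$films[[1]],
                             build_protocol("rdc", c("A", "B")), d$bridge,
                             noise_model(0.5, 0.02, seed = 9))
  s <- analyze_measurement(tr, type = "rdc")
  expect_equal(s$n_cycles, 6)
  expect_equal(s$noise_theory, s$noise_raw / sqrt(6))
  expect_equal(s$snr, abs(s$intensity) / s$noise_avg)
  expect_false(s$noise_floor)
  expect_equal(s$avg_cycle$output[1], 0)   # baseline-corrected cycle start
  # noise-free flat run flags the zero noise floor instead of an infinite S/N
  s0 <- analyze_measurement(simulate_measurement(list(odor_source("A"),
                                                      odor_source("B")),
                                                 d$films[[1]],
                                                 build_protocol("rdc", c("A", "B")),
                                                 d$bridge), type = "rdc")
  expect_true(s0$noise_floor)
  expect_true(is.na(s0$snr))
})
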