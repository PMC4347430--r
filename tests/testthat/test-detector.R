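test_that("firing-rate series normalizes and averages trailing windows", {
  params <- detector_params(max_count = 7)
  # no spikes: identically zero after burn-in
  ser0 <- firing_rate_series(list(numeric(0)), 1, params, t_end = 2000)
  expect_true(all(ser0$p[ser0$valid] == 0))
  expect_true(all(is.na(ser0$p[!ser0$valid])))
  expect_equal(ser0$burn_in, 274)
  # regular train, period m/k: every window holds exactly k spikes
  k <- 5
  sp <- seq(25, 5000, by = 250 / k)
  ser1 <- firing_rate_series(list(sp), 1, params, t_end = 5000)
  settled <- ser1$valid & ser1$times >= 600 & ser1$times <= 4800
  expect_true(all(abs(ser1$p[settled] - k / params$max_count) < 1e-9))
  # max_count = k: normalized rate is exactly one
  params2 <- detector_params(max_count = k)
  ser2 <- firing_rate_series(list(sp), 1, params2, t_end = 5000)
  expect_true(all(abs(ser2$p[settled] - 1) < 1e-12))
  expect_false(any(ser2$over_unity[settled]))
})

test_that("firing-rate series matches the brute-force window oracle", {
  set.seed(8)
  sp <- sort(stats::runif(400, 0, 6000))
  params <- detector_params(max_count = 7)
  ser <- firing_rate_series(list(sp), 1, params, t_end = 6000)
  idx <- which(ser$valid)[seq(1, sum(ser$valid), by = 97)]
  for (i in idx) {
    t <- ser$times[i]
    wins <- vapply(t - (params$n - 1):0 * params$grid_dt,
                   function(tt) oracle_window_count(sp, tt, params$m), 0)
    expect_equal(ser$p[i], mean(wins) / params$max_count, tolerance = 1e-12)
  }
})

test_that("max-count calibration finds the densest window", {
  # direct check of the window scan against a hand-built train whose
  # densest 250 ms window holds exactly 7 spikes
  sp <- c(100, 300, 500, 510, 520, 530, 540, 600, 640, 900, 1500)
  times <- seq(250, 2000, by = 1)
  counts <- fragilenet:::window_counts(sp, times, 250)
  oracle <- vapply(times, function(t) oracle_window_count(sp, t, 250), 0)
  expect_equal(counts, oracle)
  expect_equal(max(counts), 7)
})

test_that("max-count calibration is reproducible and monotone in duration", {
  w <- default_world()
  params <- detector_params()
  m1 <- calibrate_max_count(w$cfg, params, node = 4, duration = 5000,
                            seed = 5)
  m1b <- calibrate_max_count(w$cfg, params, node = 4, duration = 5000,
                             seed = 5)
  expect_identical(m1, m1b)
  expect_gte(m1, 1)
  # a longer run with the same seed extends the same trajectory scan
  m2 <- calibrate_max_count(w$cfg, params, node = 4, duration = 20000,
                            seed = 5)
  expect_gte(m2, m1)
  # degenerate network: no spikes at all
  silent <- network_config(matrix(0, 2, 2), h = c(-1, -1),
                           f_params = response_params(f_max = 0))
  expect_error(calibrate_max_count(silent, params, node = 1,
                                   duration = 1000, seed = 1),
               "degenerate")
})

test_that("emission MLE uses sample mean and biased variance", {
  em <- fit_emissions(c(0.2, 0.4), c(0.1, 0.3))
  expect_equal(em$q1$mean, 0.3)
  expect_equal(em$q1$var, 0.01)
  expect_equal(em$q2$mean, 0.2)
  expect_equal(em$q2$var, 0.01)
  # identical samples in both modes give identical densities
  x <- c(0.1, 0.5, 0.4)
  em2 <- fit_emissions(x, x)
  expect_equal(em2$q1, em2$q2)
  expect_error(fit_emissions(c(0.1), c(0.1, 0.2)), "at least 2")
  expect_error(fit_emissions(c(0.2, 0.2), c(0.1, 0.3)), "zero variance")
})

test_that("emission MLE recovers synthetic Gaussian parameters", {
  set.seed(99)
  n <- 1e4
  mu <- c(0.45, 0.1); sigma <- c(0.1, 0.05)
  s1 <- stats::rnorm(n, mu[1], sigma[1])
  s2 <- stats::rnorm(n, mu[2], sigma[2])
  em <- fit_emissions(s1, s2)
  se_mean <- sigma / sqrt(n)
  se_var <- sigma^2 * sqrt(2 / n)
  expect_lt(abs(em$q1$mean - mu[1]), 3 * se_mean[1])
  expect_lt(abs(em$q2$mean - mu[2]), 3 * se_mean[2])
  expect_lt(abs(em$q1$var - sigma[1]^2), 3 * se_var[1])
  expect_lt(abs(em$q2$var - sigma[2]^2), 3 * se_var[2])
})

test_that("likelihood ratio behaves as a ratio of Gaussian densities", {
  em_eq <- fit_emissions(c(0.2, 0.4, 0.3), c(0.2, 0.4, 0.3))
  expect_equal(likelihood_ratio(seq(-1, 2, by = 0.1), em_eq),
               rep(1, 31))
  em <- structure(list(q1 = list(mean = 0.4, var = 0.01),
                       q2 = list(mean = 0.1, var = 0.01)),
                  class = "emission_model")
  expect_equal(likelihood_ratio(0.25, em), 1) # midpoint, equal variances
  expect_gt(likelihood_ratio(0.1, em), 1)
  expect_lt(likelihood_ratio(0.4, em), 1)
  expect_true(all(likelihood_ratio(c(-50, 0, 50), em) >= 0))
})

test_that("cumulative statistic is increasing with derivative LR/dt", {
  set.seed(12)
  params <- detector_params(max_count = 25, threshold = NULL)
  sp <- sort(stats::runif(300, 0, 5000))
  ser <- firing_rate_series(list(sp), 1, params, t_end = 5000)
  em <- structure(list(q1 = list(mean = 0.4, var = 0.01),
                       q2 = list(mean = 0.1, var = 0.01)),
                  class = "emission_model")
  st <- instability_statistic(ser, em, params)
  expect_true(all(st$LR > 0))
  expect_true(all(diff(st$gr) >= 0)) # strictly positive increments can
  expect_equal(st$dgr, st$LR / params$grid_dt) # underflow the running sum
  expect_true(is.na(st$detection_time)) # no threshold configured
})

test_that("a step change in rate is detected after, not before, the step", {
  # synthetic series: stable-mode rate, then a drop to the unstable mean
  params <- detector_params(max_count = 10, threshold = 50)
  t_star <- 3000
  times <- seq(0, 6000, by = 1)
  p <- ifelse(times < t_star, 0.45, 0.08)
  ser <- structure(list(times = times, p = p,
                        valid = times >= 274,
                        over_unity = rep(FALSE, length(times)),
                        burn_in = 274),
                   class = "firing_rate_series")
  em <- structure(list(q1 = list(mean = 0.45, var = 0.01),
                       q2 = list(mean = 0.08, var = 0.005)),
                  class = "emission_model")
  st <- instability_statistic(ser, em, params)
  expect_false(is.na(st$detection_time))
  expect_gte(st$detection_time, t_star)
  expect_lt(st$detection_time, t_star + 50)
})

test_that("threshold calibration pools symmetrically and rejects constants", {
  w <- default_world()
  cfgs_u <- lapply(w$modes$perturbed, function(Wu) {
    network_config(Wu, w$cfg$h, w$cfg$alpha, w$cfg$f_params)
  })
  params <- w$calib$params
  th_ab <- calibrate_threshold(cfgs_u, w$calib$em, params, node = 4,
                               duration = 5000, seeds = c(1, 2))
  th_ba <- calibrate_threshold(rev(cfgs_u), w$calib$em, params, node = 4,
                               duration = 5000, seeds = c(2, 1))
  expect_equal(th_ab, th_ba)
  # q1 == q2 makes LR constant: degenerate calibration must error
  em_flat <- fit_emissions(c(0.2, 0.4, 0.3), c(0.2, 0.4, 0.3))
  expect_error(calibrate_threshold(cfgs_u[1], em_flat, params, node = 4,
                                   duration = 3000, seeds = 3),
               "degenerate")
})

test_that("stable-mode re-detection requires an uninterrupted hold", {
  em <- structure(list(q1 = list(mean = 0.4, var = 0.0025),
                       q2 = list(mean = 0.1, var = 0.0025)),
                  class = "emission_model")
  params <- detector_params(max_count = 10)
  mk <- function(p) {
    times <- seq(0, length(p) - 1)
    structure(list(times = times, p = p, valid = rep(TRUE, length(p)),
                   over_unity = rep(FALSE, length(p)), burn_in = 0),
              class = "firing_rate_series")
  }
  # constant at the stable mean: detected one hold after entry
  d1 <- detect_stability(mk(rep(0.4, 1000)), em, params)
  expect_equal(d1$first_in_band_time, 0)
  expect_equal(d1$detection_time, 500)
  # constantly out of band (3 SD above): never detected
  d2 <- detect_stability(mk(rep(0.4 + 3 * 0.05, 1000)), em, params)
  expect_true(is.na(d2$detection_time))
  expect_true(is.na(d2$first_in_band_time))
  # exit at 499 ms resets the hold timer
  p3 <- rep(0.4, 1200)
  p3[500] <- 0.9 # in-band run of 499 ms, then exit, then re-entry
  d3 <- detect_stability(mk(p3), em, params)
  expect_equal(d3$first_in_band_time, 0)
  expect_equal(d3$detection_time, 500 + 500)
  # band endpoints are inclusive (computed identically to the detector)
  hi <- em$q1$mean + params$band_halfwidth_sd * sqrt(em$q1$var)
  d4 <- detect_stability(mk(rep(hi, 1000)), em, params)
  expect_equal(d4$detection_time, 500)
})

test_that("onset delays are geometric with mean 1/rho steps", {
  set.seed(4)
  rho <- 0.002
  draws <- replicate(2000, fragilenet:::draw_onset_delay(rho, 1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1 / rho), 3 * se)
  expect_true(all(draws >= 1))
  expect_identical(fragilenet:::draw_onset_delay(0, 1), Inf)
})
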