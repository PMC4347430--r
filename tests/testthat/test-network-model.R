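test_that("response function is clamped, saturating and monotone", {
  p <- response_params(f_max = 0.1, gain = 2, threshold = 0.3)
  expect_equal(response_function(p$threshold, p), 0)
  expect_equal(response_function(1e6, p), p$f_max)
  expect_equal(response_function(p$threshold - 2, p), 0)
  s <- seq(-3, 3, by = 0.01)
  f <- response_function(s, p)
  expect_true(all(f >= 0 & f <= p$f_max))
  expect_true(all(diff(f) >= 0))
  # derivative matches central differences away from the clamp kink
  s_in <- seq(0.5, 3, by = 0.1)
  fd <- (response_function(s_in + 1e-6, p) -
           response_function(s_in - 1e-6, p)) / 2e-6
  expect_equal(response_derivative(s_in, p), fd, tolerance = 1e-6)
  expect_error(response_params(gain = 0))
  expect_error(response_params(f_max = -1))
})

test_that("synaptic input sums weighted activity plus external input", {
  u <- c(0.5, -0.2, 0)
  expect_equal(synaptic_input(matrix(0, 3, 3), c(1, 0, 1), u), u)
  W <- matrix(rnorm(9), 3, 3)
  expect_equal(synaptic_input(W, c(0, 0, 0), u), u)
  # hand evaluation of one row of the sum
  W <- rbind(c(0, 1, -2), c(0, 0, 0), c(0, 0, 0))
  s <- synaptic_input(W, x = c(0, 1, 1), u = c(0.5, 0, 0))
  expect_equal(s[1], -0.5)
  expect_error(synaptic_input(W, c(1, 0), u), "dimension mismatch")
})

test_that("transition rates follow alpha*x + f(s)*(1-x)", {
  p <- response_params()
  tr <- transition_rates(x = c(1, 0, 0), s = c(5, -1, 0.5), alpha = 0.1, p)
  expect_equal(tr$tr[1], 0.1)           # active node decays at alpha
  expect_equal(tr$tr[2], 0)             # quiescent below threshold
  expect_equal(tr$tr[3], response_function(0.5, p))
  expect_equal(tr$tr_net, sum(tr$tr))
  allon <- transition_rates(rep(1, 5), rep(0, 5), alpha = 0.1, p)
  expect_equal(allon$tr_net, 5 * 0.1)
})

test_that("silent network produces no events and fast-forwards", {
  cfg <- network_config(matrix(0, 3, 3), h = rep(-1, 3),
                        f_params = response_params(f_max = 0))
  tr <- gillespie_simulate(cfg, T_ms = 100, seed = 1)
  expect_length(tr$event_times, 0)
  expect_equal(unlist(lapply(spike_times(tr), length)), rep(0L, 3),
               ignore_attr = TRUE)
})

test_that("traces are reproducible for a fixed seed and differ otherwise", {
  cfg <- toy_cfg()
  a <- gillespie_simulate(cfg, T_ms = 2000, seed = 11)
  b <- gillespie_simulate(cfg, T_ms = 2000, seed = 11)
  c <- gillespie_simulate(cfg, T_ms = 2000, seed = 12)
  expect_identical(a$event_times, b$event_times)
  expect_identical(a$node, b$node)
  expect_false(identical(a$event_times, c$event_times))
})

test_that("consecutive states differ in exactly one node", {
  tr <- gillespie_simulate(toy_cfg(), T_ms = 5000, seed = 3)
  st <- trace_states(tr)
  flips <- rowSums(abs(st[-1, , drop = FALSE] - st[-nrow(st), , drop = FALSE]))
  expect_true(all(flips == 1))
  expect_true(all(diff(tr$event_times) > 0))
})

test_that("inter-event times are exponential at constant network rate", {
  cfg <- constant_rate_cfg(N = 6, alpha = 0.1)
  tr <- gillespie_simulate(cfg, T_ms = 25000, seed = 99)
  gaps <- diff(tr$event_times)
  expect_gt(length(gaps), 1e4)
  ks <- stats::ks.test(gaps, "pexp", rate = 6 * 0.1)
  expect_gt(ks$p.value, 0.01)
})

test_that("isolated node matches its two-state stationary distribution", {
  u <- 0.8
  cfg <- single_node_cfg(u = u)
  f <- response_function(u, cfg$f_params)
  expected <- f / (cfg$alpha + f)
  tr <- gillespie_simulate(cfg, T_ms = 2e5, seed = 21)
  est <- active_fraction(tr, 1)
  expect_lt(abs(est$mean - expected), 3 * est$se)
})

test_that("weakly coupled network's activity matches the mean-field fixed point", {
  # mean-field neglects correlations, so the comparison is made where the
  # approximation is controlled (weak coupling)
  cfg <- toy_cfg(scale = 0.15)
  fp <- solve_fixed_point(cfg)
  tr <- gillespie_simulate(cfg, T_ms = 1e5, seed = 31)
  for (i in 1:3) {
    est <- active_fraction(tr, i)
    expect_lt(abs(est$mean - fp$r[i]), 3 * est$se)
  }
})

test_that("non-finite rates are reported with the offending node", {
  cfg <- toy_cfg()
  cfg$W[2, 1] <- NaN
  # NaN weight only corrupts rates once node 1 activates
  expect_error(gillespie_simulate(cfg, T_ms = 5000, seed = 1),
               "node 2")
})

test_that("recorded inputs match the applied input function", {
  cfg <- toy_cfg()
  tr <- gillespie_simulate(cfg, T_ms = 500, seed = 5, record_inputs = TRUE)
  expect_equal(nrow(tr$inputs), length(tr$event_times))
  expect_true(all(tr$inputs == rep(cfg$h, each = nrow(tr$inputs))))
})
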