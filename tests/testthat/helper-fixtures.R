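# Shared fixtures. The default "world" (generated network + calibrated
# detector) is expensive (~10 s), so it is built once per test run and
# memoized; every consumer gets the same object.

.fixture_env <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.fixture_env$world)) {
    gen <- generate_network(seed = 42)
    calib <- calibrate_detector(gen$cfg, gen$modes, seed = 1042)
    .fixture_env$world <- list(gen = gen, cfg = gen$cfg, modes = gen$modes,
                               calib = calib)
  }
  .fixture_env$world
}

# Single isolated node: W = 0, constant background input.
single_node_cfg <- function(u = 0.8, alpha = 0.1,
                            f_params = response_params()) {
  network_config(matrix(0, 1, 1), h = u, alpha = alpha, f_params = f_params)
}

# Constant-rate configuration: the response is saturated at f_max = alpha
# for every input, so tr_i = alpha regardless of state and tr_net = N*alpha.
constant_rate_cfg <- function(N = 6, alpha = 0.1) {
  network_config(matrix(0, N, N), h = rep(0, N), alpha = alpha,
                 f_params = response_params(f_max = alpha, gain = 1,
                                            threshold = -1e6))
}

# A small coupled network used where generation would be overkill.
toy_cfg <- function(scale = 1) {
  W <- scale * matrix(c(0, 0.6, -0.8,
                        0.5, 0, 0.4,
                        0.7, -0.3, 0), 3, 3, byrow = TRUE)
  network_config(W, h = c(0.5, 0.7, 0.6))
}

# Independent oracle for min_row_perturbation: for random unit directions d,
# det(A - target*I + t e_row d^T) is linear in t, so the feasible magnitude
# along d comes from two determinant evaluations; the minimum over many
# directions brackets the true minimum-norm solution. Uses only base::det.
oracle_min_energy <- function(A, row, target, n_dirs = 6000) {
  N <- nrow(A)
  M <- A - diag(target, N)
  e <- numeric(N)
  e[row] <- 1
  g0 <- det(M)
  best <- Inf
  for (k in seq_len(n_dirs)) {
    d <- stats::rnorm(N)
    d <- d / sqrt(sum(d * d))
    g1 <- det(M + e %*% t(d))
    tt <- -g0 / (g1 - g0)
    if (is.finite(tt)) best <- min(best, abs(tt))
  }
  best
}

# Brute-force window counter: number of spikes in (t - m, t], by direct
# comparison (quadratic; oracle only).
oracle_window_count <- function(spikes, t, m) {
  sum(spikes > t - m & spikes <= t)
}

# Batch-means standard error of the time-average active fraction of one
# node, from a trace (handles autocorrelation).
active_fraction <- function(trace, node, n_batches = 20) {
  edges <- seq(0, trace$T_ms, length.out = n_batches + 1)
  ev_t <- c(0, trace$event_times)
  states <- trace_states(trace)[, node]
  fracs <- vapply(seq_len(n_batches), function(b) {
    a <- edges[b]
    z <- edges[b + 1]
    idx <- which(ev_t < z)
    tt <- pmax(ev_t[idx], a)
    tn <- c(ev_t[idx][-1], z)
    tn <- pmax(tn, a)
    sum((tn - tt) * states[idx]) / (z - a)
  }, 0)
  list(mean = mean(fracs), se = stats::sd(fracs) / sqrt(n_batches))
}
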