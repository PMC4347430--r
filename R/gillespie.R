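#' Event-driven simulation of the stochastic binary-neuron network
#'
#' Exact Gillespie simulation of the continuous-time Markov jump process in
#' which each node flips between quiescent (0) and active (1). At each step
#' the per-node transition rates are evaluated
#' (`tr_i = alpha * x_i + f(s_i) * (1 - x_i)`), the waiting time to the next
#' event is drawn as `dt = -log(U) / tr_net` with `U ~ Uniform(0, 1)`
#' (i.e. Exponential(`tr_net`)), and a single node `i` flips with
#' probability `tr_i / tr_net`. A spike is a 0 -> 1 transition.
#'
#' The external input `u` is re-evaluated at every event time and held
#' piecewise constant between events. For a constant `u` the simulation is
#' exact; for time-varying inputs this is a zero-order-hold approximation at
#' event resolution.
#'
#' @param cfg A [network_config()].
#' @param input_fn Either `NULL` (use the background input `cfg$h`
#'   throughout), a numeric vector of length `N` (constant input), or a
#'   function `time -> length-N input vector`.
#' @param T_ms Duration of the simulation in ms.
#' @param x0 Initial binary state vector (default: all quiescent).
#' @param seed Optional integer seed for reproducibility.
#' @param record_inputs If `TRUE`, store the input vector applied at each
#'   event (an events x N matrix) for audit.
#' @return An object of class `network_trace` with fields `event_times`
#'   (strictly increasing, ms), `node` (index flipped at each event),
#'   `new_state` (0/1 after the flip), `x0`, `x_final`, `T_ms`, `N`, and
#'   optionally `inputs`. Use [spike_times()] and [trace_states()] to
#'   derive per-node spike trains and the full state sequence.
#' @export
gillespie_simulate <- function(cfg, input_fn = NULL, T_ms, x0 = NULL,
                               seed = NULL, record_inputs = FALSE) {
  stopifnot(inherits(cfg, "network_config"), T_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$N
  if (is.null(x0)) x0 <- integer(N)
  x0 <- as.integer(x0)
  stopifnot(length(x0) == N, all(x0 %in% c(0L, 1L)))
  ufun <- make_input_fn(input_fn, cfg)

  alpha <- cfg$alpha
  p <- cfg$f_params
  W <- cfg$W
  x <- x0
  sx <- as.vector(W %*% x) # network part of the synaptic input

  cap <- 1024L
  ev_t <- numeric(cap)
  ev_node <- integer(cap)
  ev_state <- integer(cap)
  ev_u <- if (record_inputs) matrix(0, cap, N) else NULL
  n_ev <- 0L

  t <- 0
  repeat {
    u <- ufun(t)
    f <- response_function(sx + u, p)
    tr <- ifelse(x == 1L, alpha, f)
    if (!all(is.finite(tr))) {
      stop("non-finite transition rate at node ", which(!is.finite(tr))[1],
           " (t = ", t, " ms)")
    }
    tr_net <- sum(tr)
    if (tr_net <= 0) break # absorbing: fast-forward to T_ms with no events
    dt <- -log(stats::runif(1)) / tr_net
    t <- t + dt
    if (t > T_ms) break
    i <- pick_index(tr, tr_net)
    x[i] <- 1L - x[i]
    sx <- if (x[i] == 1L) sx + W[, i] else sx - W[, i]

    n_ev <- n_ev + 1L
    if (n_ev > cap) {
      cap <- cap * 2L
      ev_t <- c(ev_t, numeric(cap / 2L))
      ev_node <- c(ev_node, integer(cap / 2L))
      ev_state <- c(ev_state, integer(cap / 2L))
      if (record_inputs) ev_u <- rbind(ev_u, matrix(0, cap / 2L, N))
    }
    ev_t[n_ev] <- t
    ev_node[n_ev] <- i
    ev_state[n_ev] <- x[i]
    if (record_inputs) ev_u[n_ev, ] <- u
  }

  structure(
    list(
      event_times = ev_t[seq_len(n_ev)],
      node = ev_node[seq_len(n_ev)],
      new_state = ev_state[seq_len(n_ev)],
      x0 = x0, x_final = x, T_ms = T_ms, N = N,
      inputs = if (record_inputs) ev_u[seq_len(n_ev), , drop = FALSE] else NULL
    ),
    class = "network_trace"
  )
}

# Normalize the input argument to a function of time.
make_input_fn <- function(input_fn, cfg) {
  if (is.null(input_fn)) {
    h <- cfg$h
    function(t) h
  } else if (is.function(input_fn)) {
    input_fn
  } else {
    u <- as.numeric(input_fn)
    stopifnot(length(u) == cfg$N)
    function(t) u
  }
}

# Inverse-CDF draw of the flipping node; faster than sample.int for tiny N.
pick_index <- function(tr, tr_net) {
  r <- stats::runif(1) * tr_net
  cs <- cumsum(tr)
  i <- findInterval(r, cs) + 1L
  if (i > length(tr)) i <- length(tr) # guard against rounding at the edge
  i
}

#' @export
print.network_trace <- function(x, ...) {
  cat("<network_trace>", length(x$event_times), "events over", x$T_ms,
      "ms;", x$N, "nodes;", sum(x$new_state == 1L), "spikes\n")
  invisible(x)
}

#' Per-node spike times of a trace
#'
#' A spike is a quiescent-to-active (0 -> 1) transition.
#'
#' @param trace A `network_trace`.
#' @return List of length `N`; element `i` holds node `i`'s activation
#'   times in ms (possibly empty).
#' @export
spike_times <- function(trace) {
  stopifnot(inherits(trace, "network_trace"))
  on <- trace$new_state == 1L
  split(trace$event_times[on],
        factor(trace$node[on], levels = seq_len(trace$N)))
}

#' State sequence of a trace
#'
#' Reconstructs the binary state vector after every event. Consecutive rows
#' differ in exactly one node (the single-flip property of the jump
#' process).
#'
#' @param trace A `network_trace`.
#' @return Integer matrix with `length(event_times) + 1` rows (the first is
#'   the initial condition) and `N` columns.
#' @export
trace_states <- function(trace) {
  stopifnot(inherits(trace, "network_trace"))
  n <- length(trace$event_times)
  out <- matrix(rep(trace$x0, n + 1L), n + 1L, trace$N, byrow = TRUE)
  x <- trace$x0
  for (k in seq_len(n)) {
    x[trace$node[k]] <- trace$new_state[k]
    out[k + 1L, ] <- x
  }
  out
}
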