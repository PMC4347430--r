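#' Network configuration
#'
#' Bundles the structural connectivity matrix `W`, per-node background
#' inputs `h`, the decay rate `alpha` and the response-function parameters
#' into a validated configuration object. Entry `W[i, j]` is the effect of
#' node `j` on node `i` (synaptic-input units per active node): positive
#' values are excitatory, negative inhibitory, zero means no connection.
#'
#' All internal time units are milliseconds; `alpha = 0.1` ms^-1 is the
#' 100 Hz decay rate, so a neuron is active (action potential plus
#' refractory period) for `1/alpha = 10` ms on average.
#'
#' @param W Square numeric matrix of synaptic weights.
#' @param h Numeric vector of background inputs, length `nrow(W)`.
#' @param alpha Decay rate in ms^-1 (default 0.1 = 100 Hz).
#' @param f_params A [response_params()] object.
#' @return An object of class `network_config` with fields `N`, `alpha`,
#'   `W`, `h`, `f_params`.
#' @export
network_config <- function(W, h, alpha = 0.1, f_params = response_params()) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) {
    stop("weight matrix must be square, got ", nrow(W), "x", ncol(W))
  }
  if (!all(is.finite(W))) stop("weight matrix contains non-finite entries")
  N <- nrow(W)
  h <- as.numeric(h)
  if (length(h) != N) {
    stop("background input h has length ", length(h), ", expected ", N)
  }
  if (!all(is.finite(h))) stop("background input h contains non-finite entries")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0)
  if (!inherits(f_params, "response_params")) {
    f_params <- do.call(response_params, as.list(f_params))
  }
  structure(
    list(N = N, alpha = alpha, W = unname(W), h = h, f_params = f_params),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config> N =", x$N,
      "| alpha =", x$alpha, "ms^-1 (", x$alpha * 1000, "Hz )",
      "| connections =", sum(x$W != 0), "\n")
  invisible(x)
}

#' Total synaptic input
#'
#' Computes `s_i = sum_j W[i, j] x_j + u_i`: the weighted sum of presynaptic
#' activity plus the external input (background plus any control input).
#'
#' @param W Square weight matrix (or a `network_config`, whose `W` is used).
#' @param x Binary state vector (1 = active, 0 = quiescent).
#' @param u External input vector, same length as `x`.
#' @return Numeric vector of synaptic inputs.
#' @export
synaptic_input <- function(W, x, u) {
  if (inherits(W, "network_config")) W <- W$W
  N <- nrow(W)
  if (length(x) != N || length(u) != N) {
    stop("dimension mismatch: W is ", N, "x", ncol(W),
         ", x has length ", length(x), ", u has length ", length(u))
  }
  as.vector(W %*% x) + u
}

#' Per-node transition rates
#'
#' An active node deactivates at the constant rate `alpha`; a quiescent node
#' activates at the input-dependent rate `f(s_i)`:
#' `tr_i = alpha * x_i + f(s_i) * (1 - x_i)`.
#'
#' @param x Binary state vector.
#' @param s Synaptic-input vector from [synaptic_input()].
#' @param alpha Decay rate (ms^-1).
#' @param p A [response_params()] object.
#' @return List with `tr` (per-node rates, ms^-1) and `tr_net` (their sum).
#' @export
transition_rates <- function(x, s, alpha, p) {
  if (length(x) != length(s)) {
    stop("dimension mismatch: x has length ", length(x),
         ", s has length ", length(s))
  }
  f <- response_function(s, p)
  tr <- ifelse(x == 1, alpha, f)
  list(tr = tr, tr_net = sum(tr))
}
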