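#' Linear-model state-feedback gain
#'
#' Gain designed on the linearized dynamics: `K = -B^-1 Delta`, so that
#' `A + Delta + B K = A` exactly and the closed-loop linear system recovers
#' the stable spectrum. Because `B` is diagonal and `Delta` has a single
#' non-zero row, `K` is non-zero only on the fragile row.
#'
#' @param B An [input_matrix()] object (or a diagonal matrix).
#' @param delta A [min_row_perturbation()] result.
#' @return An object of class `gain_matrix`: `K`, `variant = "linear"`,
#'   `fragile_row`.
#' @section Errors: a zero diagonal entry of `B` on a perturbed column
#'   means the response function is saturated at the fixed point and the
#'   linear gain does not exist; an error naming the node is signalled.
#' @export
linear_gain <- function(B, delta) {
  Bm <- if (inherits(B, "input_matrix")) B$B else as.matrix(B)
  b <- diag(Bm)
  zero <- which(b == 0)
  if (length(zero)) {
    stop("linear gain unavailable: input matrix B has zero diagonal at node ",
         paste(zero, collapse = ", "), " (saturated response at fixed point)")
  }
  K <- -(1 / b) * delta$delta # row-wise scaling: -B^-1 %*% Delta
  structure(list(K = K, variant = "linear", fragile_row = delta$row_index),
            class = "gain_matrix")
}

#' Nonlinear-model state-feedback gain
#'
#' Gain designed directly on the stochastic model: `K = -Delta`. During the
#' unstable mode the structure is `W_s + Delta`, so the control input
#' `u = K x + h` cancels the perturbation term inside the synaptic input
#' exactly: `(W_s + Delta) x + (-Delta x + h) = W_s x + h`.
#'
#' @param delta A [min_row_perturbation()] result.
#' @return An object of class `gain_matrix`: `K`, `variant = "nonlinear"`,
#'   `fragile_row`.
#' @export
nonlinear_gain <- function(delta) {
  structure(list(K = -delta$delta, variant = "nonlinear",
                 fragile_row = delta$row_index),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat("<gain_matrix>", x$variant, "| non-zero row:", x$fragile_row,
      "| row:", paste(signif(x$K[x$fragile_row, ], 4), collapse = " "), "\n")
  invisible(x)
}

#' Control input
#'
#' `u = sigma * K x + h`. With the switch open (`sigma = 0`) the input is
#' exactly the background `h`; with it closed, only the fragile node's
#' component can differ from `h`.
#'
#' @param K A `gain_matrix` (or plain matrix).
#' @param x Binary state vector.
#' @param h Background-input vector.
#' @param sigma Switch signal, 0 or 1.
#' @return Numeric input vector `u`.
#' @export
control_input <- function(K, x, h, sigma) {
  Km <- if (inherits(K, "gain_matrix")) K$K else as.matrix(K)
  if (length(x) != ncol(Km) || length(h) != nrow(Km)) {
    stop("dimension mismatch: K is ", nrow(Km), "x", ncol(Km),
         ", x has length ", length(x), ", h has length ", length(h))
  }
  stopifnot(sigma %in% c(0, 1))
  if (sigma == 0) return(as.numeric(h))
  as.vector(Km %*% x) + h
}
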