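#' Response-function parameters
#'
#' Parameters of the saturating (clamped hyperbolic tangent) response
#' function that maps total synaptic input to the activation rate of a
#' quiescent neuron,
#' \deqn{f(s) = f_{max} \cdot \mathrm{clamp}(\tanh(g (s - \theta)), 0, 1).}
#' The clamp at zero makes the function one-sided: inputs at or below the
#' threshold produce no activation. The ceiling `f_max` caps the firing
#' rate; with the default `f_max = 0.1` ms^-1 (100 Hz) it matches the decay
#' rate `alpha`, so no node can sustain rates above 100 Hz.
#'
#' @param f_max Rate ceiling in ms^-1 (default 0.1, i.e. 100 Hz).
#' @param gain Slope of the hyperbolic tangent (dimensionless per unit
#'   synaptic input); must be positive.
#' @param threshold Input offset in synaptic-input units.
#' @return An object of class `response_params`.
#' @export
#' @examples
#' p <- response_params()
#' response_function(c(-1, 0, 1, 10), p)
response_params <- function(f_max = 0.1, gain = 1, threshold = 0) {
  stopifnot(
    is.numeric(f_max), length(f_max) == 1L, is.finite(f_max), f_max >= 0,
    is.numeric(gain), length(gain) == 1L, is.finite(gain), gain > 0,
    is.numeric(threshold), length(threshold) == 1L, is.finite(threshold)
  )
  structure(list(f_max = f_max, gain = gain, threshold = threshold),
            class = "response_params")
}

#' Saturating neuronal response function
#'
#' Evaluates `f(s) = f_max * clamp(tanh(gain * (s - threshold)), 0, 1)`.
#' Total, nonnegative, nondecreasing in `s` and bounded by `f_max`.
#'
#' @param s Numeric vector of synaptic inputs.
#' @param p A [response_params()] object.
#' @return Activation rates in ms^-1, same length as `s`.
#' @export
response_function <- function(s, p) {
  z <- tanh(p$gain * (s - p$threshold))
  p$f_max * pmin(pmax(z, 0), 1)
}

#' Derivative of the response function
#'
#' One-sided derivative of [response_function()] with respect to `s`. At the
#' clamp kink (`s = threshold`) the left derivative (zero) is returned, so
#' the linearization of a network sitting exactly at threshold is
#' conservative (no coupling through that node).
#'
#' @inheritParams response_function
#' @return Derivative values in ms^-1 per synaptic-input unit.
#' @export
response_derivative <- function(s, p) {
  z <- tanh(p$gain * (s - p$threshold))
  out <- p$f_max * p$gain * (1 - z * z)
  out[z <= 0] <- 0
  out
}
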