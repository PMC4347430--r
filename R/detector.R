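#' Detector parameters
#'
#' Configuration of the firing-rate estimator and the two-mode HMM
#' instability detector. The firing rate of the monitored (most fragile)
#' node is estimated by counting spikes in a trailing window of `m` ms,
#' dividing by the calibrated maximum count `max_count` for that window
#' length, and averaging the `n` most recent window values (windows shifted
#' by `grid_dt`). All detector statistics live on a fixed uniform grid of
#' step `grid_dt` ms; the estimate is undefined during the initial fill of
#' `m + (n - 1) * grid_dt` ms (the detector burn-in).
#'
#' @param m Window length in ms (default 250).
#' @param n Number of averaged windows (default 25).
#' @param grid_dt Evaluation grid step in ms (default 1).
#' @param max_count Normalization spike count per `m`-window; calibrate
#'   with [calibrate_max_count()].
#' @param rho Per-grid-step stable-to-unstable transition probability of
#'   the HMM (default 2e-4).
#' @param threshold Detection threshold on the cumulative likelihood-ratio
#'   derivative (per ms); calibrate with [calibrate_threshold()].
#' @param stable_hold Required uninterrupted in-band duration for
#'   stable-mode re-detection, in ms (default 500).
#' @param band_halfwidth_sd Half-width of the stable band in stable-mode
#'   standard deviations (default 2).
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(m = 250, n = 25, grid_dt = 1, max_count = NULL,
                            rho = 2e-4, threshold = NULL, stable_hold = 500,
                            band_halfwidth_sd = 2) {
  stopifnot(m > 0, n >= 1, grid_dt > 0, rho > 0, rho < 1,
            stable_hold >= 0, band_halfwidth_sd > 0)
  if (!is.null(max_count)) stopifnot(max_count >= 1)
  structure(
    list(m = m, n = as.integer(n), grid_dt = grid_dt, max_count = max_count,
         rho = rho, threshold = threshold, stable_hold = stable_hold,
         band_halfwidth_sd = band_halfwidth_sd),
    class = "detector_params"
  )
}

#' Detector burn-in duration
#'
#' Time from the start of observation until the windowed, `n`-averaged
#' firing-rate estimate is first defined: `m + (n - 1) * grid_dt` ms
#' (274 ms at the defaults). This is the initial delay of the detector.
#'
#' @param params A [detector_params()] object.
#' @return Burn-in in ms.
#' @export
detector_burn_in <- function(params) {
  params$m + (params$n - 1L) * params$grid_dt
}

# Spike counts of one node in trailing (t - m, t] windows at grid times.
# `sp` must be sorted ascending.
window_counts <- function(sp, grid_times, m) {
  findInterval(grid_times, sp) - findInterval(grid_times - m, sp)
}

#' Normalized, window-averaged firing-rate series
#'
#' Computes the detector's observable `p_k` for one node on the uniform
#' grid: spike count in the trailing `(t - m, t]` window, divided by
#' `max_count`, then averaged over the `n` most recent windows. Values
#' before the burn-in are `NA` and flagged invalid. Values may exceed 1 if
#' an observed count exceeds the calibrated maximum; they are flagged in
#' `over_unity` but never clipped.
#'
#' @param spikes Either a `network_trace` or a list of per-node spike-time
#'   vectors (ms).
#' @param node 1-based index of the monitored node.
#' @param params A [detector_params()] with `max_count` set.
#' @param t_start,t_end Observation interval in ms. Defaults: 0 and, for a
#'   trace input, the trace duration.
#' @return An object of class `firing_rate_series`: `times` (grid, ms),
#'   `p` (`NA` before burn-in), `valid` (logical), `over_unity` (logical),
#'   `burn_in` (ms).
#' @export
firing_rate_series <- function(spikes, node, params, t_start = 0,
                               t_end = NULL) {
  stopifnot(inherits(params, "detector_params"))
  if (is.null(params$max_count)) {
    stop("max_count is not calibrated; run calibrate_max_count() first")
  }
  if (inherits(spikes, "network_trace")) {
    if (is.null(t_end)) t_end <- spikes$T_ms
    spikes <- spike_times(spikes)
  }
  if (is.null(t_end)) stop("t_end is required when passing raw spike lists")
  sp <- sort(as.numeric(spikes[[node]]))
  dtg <- params$grid_dt
  times <- seq(t_start, t_end, by = dtg)
  w <- window_counts(sp, times, params$m) / params$max_count
  # rolling mean of the n most recent windows via cumulative sums
  n <- params$n
  cw <- cumsum(w)
  p <- rep(NA_real_, length(w))
  if (length(w) >= n) {
    idx <- n:length(w)
    p[idx] <- (cw[idx] - c(0, cw)[idx - n + 1L]) / n
  }
  # a value is valid only when its oldest contributing window is full
  valid <- !is.na(p) & (times >= t_start + detector_burn_in(params))
  p[!valid] <- NA_real_
  structure(
    list(times = times, p = p, valid = valid,
         over_unity = !is.na(p) & p > 1,
         burn_in = detector_burn_in(params)),
    class = "firing_rate_series"
  )
}

#' Calibrate the window normalization count
#'
#' Maximum number of spikes of the monitored node observed in any
#' grid-aligned window of length `m` over a stable-mode simulation
#' (default 100 s), used to normalize window counts to a rate in `[0, 1]`.
#'
#' @param cfg Stable-mode [network_config()].
#' @param params A [detector_params()].
#' @param node Monitored node index.
#' @param duration Calibration simulation length in ms (default 1e5).
#' @param seed Optional seed.
#' @param x0 Optional initial state for the calibration run.
#' @return Integer `max_count >= 1`.
#' @export
calibrate_max_count <- function(cfg, params, node, duration = 1e5,
                                seed = NULL, x0 = NULL) {
  trace <- gillespie_simulate(cfg, T_ms = duration, x0 = x0, seed = seed)
  sp <- spike_times(trace)[[node]]
  if (length(sp) == 0) {
    stop("degenerate network: no spikes of node ", node,
         " in the calibration run")
  }
  times <- seq(params$m, duration, by = params$grid_dt)
  max(window_counts(sort(sp), times, params$m))
}

#' Fit Gaussian emission densities by maximum likelihood
#'
#' Gaussian MLE (sample mean, biased 1/N variance) of the monitored node's
#' normalized firing rate in each mode, from samples collected in
#' stable-mode and unstable-mode simulations.
#'
#' @param stable_rates,unstable_rates Numeric sample vectors (at least two
#'   values each, non-degenerate).
#' @return An object of class `emission_model` with fields `q1`, `q2`,
#'   each a list `(mean, var)`.
#' @export
fit_emissions <- function(stable_rates, unstable_rates) {
  mle <- function(xs, label) {
    xs <- xs[!is.na(xs)]
    if (length(xs) < 2) stop("need at least 2 ", label, " samples")
    v <- mean((xs - mean(xs))^2) # biased MLE variance
    if (v <= 0) stop("zero variance in ", label, " samples")
    list(mean = mean(xs), var = v)
  }
  structure(list(q1 = mle(stable_rates, "stable-mode"),
                 q2 = mle(unstable_rates, "unstable-mode")),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat("<emission_model> q1: N(", signif(x$q1$mean, 4), ",",
      signif(x$q1$var, 4), ") | q2: N(", signif(x$q2$mean, 4), ",",
      signif(x$q2$var, 4), ")\n")
  invisible(x)
}

# Cap on the likelihood ratio so cumulative sums over long runs stay finite.
.LR_CAP <- 1e100

#' Likelihood ratio of the two emission densities
#'
#' `LR = q2(p) / q1(p)`, evaluated in log space for numerical range and
#' capped at 1e100. Strictly positive for finite `p`.
#'
#' @param p Normalized firing-rate value(s).
#' @param em An [fit_emissions()] model.
#' @return Likelihood ratio(s), same length as `p`.
#' @export
likelihood_ratio <- function(p, em) {
  lr <- exp(stats::dnorm(p, em$q2$mean, sqrt(em$q2$var), log = TRUE) -
            stats::dnorm(p, em$q1$mean, sqrt(em$q1$var), log = TRUE))
  pmin(lr, .LR_CAP)
}

#' Cumulative likelihood-ratio statistic and instability detection
#'
#' On the valid portion of the firing-rate series computes the per-step
#' likelihood ratio `LR_k`, its running sum `gr_k`, and the derivative
#' `dgr_k = (gr_k - gr_{k-1}) / grid_dt = LR_k / grid_dt`. If
#' `params$threshold` is set, the instability detection time is the first
#' grid time with `dgr_k > threshold`.
#'
#' @param series A [firing_rate_series()].
#' @param em An [fit_emissions()] model.
#' @param params A [detector_params()].
#' @return An object of class `detector_state`: `times`, `p`, `LR`, `gr`,
#'   `dgr` (all on the valid grid), `threshold`, `detection_time` (`NA` if
#'   no crossing or no threshold configured).
#' @export
instability_statistic <- function(series, em, params) {
  keep <- series$valid
  times <- series$times[keep]
  p <- series$p[keep]
  LR <- likelihood_ratio(p, em)
  gr <- cumsum(LR)
  dgr <- LR / params$grid_dt
  det_t <- NA_real_
  if (!is.null(params$threshold)) {
    hit <- which(dgr > params$threshold)
    if (length(hit)) det_t <- times[hit[1]]
  }
  structure(
    list(times = times, p = p, LR = LR, gr = gr, dgr = dgr,
         threshold = params$threshold, detection_time = det_t),
    class = "detector_state"
  )
}

#' Calibrate the detection threshold
#'
#' The threshold on `dgr = LR / grid_dt` is the mean of `dgr` over
#' unstable-mode simulations (default 60 s each) of every supplied
#' destabilized network, pooled sample-wise across runs (or averaged per
#' run with `pooling = "per_run"`). The detector burn-in of each run is
#' excluded.
#'
#' @param cfgs_unstable List of unstable-mode [network_config()] objects
#'   (e.g. built from [build_mode_matrices()]`$perturbed`).
#' @param em An [fit_emissions()] model.
#' @param params A [detector_params()] with `max_count` set.
#' @param node Monitored node index.
#' @param duration Simulation length per run in ms (default 6e4).
#' @param seeds Optional vector of seeds, one per run.
#' @param pooling `"pooled"` (default): mean over all samples of all runs;
#'   `"per_run"`: mean of per-run means.
#' @return Threshold (per ms).
#' @export
calibrate_threshold <- function(cfgs_unstable, em, params, node,
                                duration = 6e4, seeds = NULL,
                                pooling = c("pooled", "per_run")) {
  pooling <- match.arg(pooling)
  dgr_runs <- lapply(seq_along(cfgs_unstable), function(i) {
    tr <- gillespie_simulate(cfgs_unstable[[i]], T_ms = duration,
                             seed = if (!is.null(seeds)) seeds[i])
    ser <- firing_rate_series(tr, node, params)
    instability_statistic(ser, em, params)$dgr
  })
  all_dgr <- unlist(dgr_runs)
  if (length(all_dgr) == 0 || stats::sd(all_dgr) == 0) {
    stop("degenerate calibration: constant likelihood-ratio derivative")
  }
  if (pooling == "pooled") mean(all_dgr) else mean(vapply(dgr_runs, mean, 0))
}

#' Detect the return to the stable mode
#'
#' After the controller is activated the detector watches for the monitored
#' node's firing rate to re-enter the stable band
#' `q1$mean +/- band_halfwidth_sd * sqrt(q1$var)` (endpoints inclusive) and
#' stay there, uninterrupted, for `stable_hold` ms. Any exit resets the
#' hold timer.
#'
#' @param series A [firing_rate_series()].
#' @param em An [fit_emissions()] model.
#' @param params A [detector_params()].
#' @param from Only grid times `>= from` are considered (default: start of
#'   the valid series).
#' @return List with `detection_time` (first grid time at which the rate
#'   has been in band for the full hold; `NA` if never) and
#'   `first_in_band_time` (first in-band grid time; `NA` if never).
#' @export
detect_stability <- function(series, em, params, from = NULL) {
  keep <- series$valid
  times <- series$times[keep]
  p <- series$p[keep]
  if (!is.null(from)) {
    sel <- times >= from
    times <- times[sel]
    p <- p[sel]
  }
  halfw <- params$band_halfwidth_sd * sqrt(em$q1$var)
  in_band <- p >= em$q1$mean - halfw & p <= em$q1$mean + halfw
  if (!length(in_band) || !any(in_band)) {
    return(list(detection_time = NA_real_, first_in_band_time = NA_real_))
  }
  first_in <- times[which(in_band)[1]]
  need <- as.integer(round(params$stable_hold / params$grid_dt)) + 1L
  r <- rle(in_band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  det <- NA_real_
  for (j in seq_along(r$lengths)) {
    if (r$values[j] && r$lengths[j] >= need) {
      det <- times[starts[j] + need - 1L]
      break
    }
  }
  list(detection_time = det, first_in_band_time = first_in)
}
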