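#' Specification for the synthetic network generator
#'
#' Describes the family of fragile epileptic-network fixtures the generator
#' samples from: `N` single-neuron nodes, `E` directed connections with
#' mixed excitation and inhibition obeying Dale's rule (every outgoing
#' weight of an inhibitory node is non-positive, of an excitatory node
#' non-negative), uniform background inputs, and a globally rescaled weight
#' matrix whose linearization sits just below instability (the network is
#' "on the brink").
#'
#' @param N Node count (default 6).
#' @param E Number of directed connections (default 14).
#' @param n_inhibitory Number of inhibitory nodes, including the intended
#'   fragile node (default 2).
#' @param w_range Magnitude range for connection weights
#'   (default `c(0.5, 2)`, synaptic-input units).
#' @param h_range Range for background inputs (default `c(0.3, 1)`).
#' @param alpha Decay rate in ms^-1 (default 0.1 = 100 Hz).
#' @param f_params A [response_params()] object.
#' @param self_loops Allow self-connections (default `FALSE`).
#' @param lambda_band Target band for `Re(lambda_1(A))` of the accepted
#'   network, in ms^-1 (default `c(-0.05, -0.005)`).
#' @param fragile_position Node label given to the most fragile node after
#'   generation (default 4, so reports read "node 4"). Set `NA` to keep
#'   the sampled labelling.
#' @param targets Eigenvalue targets (ms^-1) for the destabilized matrices
#'   (default `c(0, 0.2)`).
#' @param verify_dynamics Require the destabilized network to show the
#'   disinhibition signature in simulation (see [generate_network()]).
#' @param max_rejections Candidate cap before giving up (default 200).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(N = 6, E = 14, n_inhibitory = 2,
                           w_range = c(0.5, 2), h_range = c(0.3, 1),
                           alpha = 0.1, f_params = response_params(),
                           self_loops = FALSE,
                           lambda_band = c(-0.05, -0.005),
                           fragile_position = 4,
                           targets = c(0, 0.2),
                           verify_dynamics = TRUE,
                           max_rejections = 200) {
  max_edges <- if (self_loops) N * N else N * (N - 1)
  stopifnot(N >= 1, E >= 0, E <= max_edges,
            n_inhibitory >= 1, n_inhibitory < N,
            length(w_range) == 2, w_range[1] > 0, diff(w_range) >= 0,
            length(h_range) == 2, diff(h_range) >= 0,
            length(lambda_band) == 2, lambda_band[1] < lambda_band[2],
            lambda_band[2] < 0, max_rejections >= 1)
  structure(
    list(N = N, E = E, n_inhibitory = n_inhibitory, w_range = w_range,
         h_range = h_range, alpha = alpha, f_params = f_params,
         self_loops = self_loops, lambda_band = lambda_band,
         fragile_position = fragile_position, targets = targets,
         verify_dynamics = verify_dynamics,
         max_rejections = max_rejections),
    class = "generator_spec"
  )
}

# One raw candidate: weights (Dale-signed), inputs, inhibitory set.
sample_candidate <- function(spec) {
  N <- spec$N
  inhib <- sort(sample.int(N, spec$n_inhibitory))
  pairs <- expand.grid(i = seq_len(N), j = seq_len(N))
  if (!spec$self_loops) pairs <- pairs[pairs$i != pairs$j, ]
  pick <- pairs[sample.int(nrow(pairs), spec$E), ]
  W <- matrix(0, N, N)
  mag <- stats::runif(spec$E, spec$w_range[1], spec$w_range[2])
  sgn <- ifelse(pick$j %in% inhib, -1, 1)
  W[cbind(pick$i, pick$j)] <- sgn * mag
  h <- stats::runif(N, spec$h_range[1], spec$h_range[2])
  list(W = W, h = h, inhibitory = inhib)
}

# Leading eigenvalue real part of the linearization at scale `sc`, or NA if
# the fixed point cannot be found.
lambda1_at_scale <- function(W, h, sc, spec) {
  cfg <- network_config(sc * W, h, spec$alpha, spec$f_params)
  tryCatch({
    fp <- solve_fixed_point(cfg, max_iter = 4000) # cap: rejection must be cheap
    Re(linearize(cfg, fp)$eigenvalues[1])
  }, error = function(e) NA_real_)
}

# Bisection on a global weight scale so that Re(lambda_1(A)) lands in the
# marginal band. Returns the scale or NA.
rescale_to_band <- function(W, h, spec) {
  lo_b <- spec$lambda_band[1]
  hi_b <- spec$lambda_band[2]
  sc_lo <- NA_real_
  sc_hi <- NA_real_
  sc <- 1
  for (k in 1:14) {
    l1 <- lambda1_at_scale(W, h, sc, spec)
    if (is.na(l1)) return(NA_real_)
    if (l1 >= lo_b && l1 <= hi_b) return(sc)
    if (l1 < lo_b) {
      sc_lo <- sc
      if (!is.na(sc_hi)) break
      sc <- sc * 1.6
    } else {
      sc_hi <- sc
      if (!is.na(sc_lo)) break
      sc <- sc / 1.6
    }
  }
  if (is.na(sc_lo) || is.na(sc_hi)) return(NA_real_)
  for (k in 1:60) {
    sc <- 0.5 * (sc_lo + sc_hi)
    l1 <- lambda1_at_scale(W, h, sc, spec)
    if (is.na(l1)) return(NA_real_)
    if (l1 >= lo_b && l1 <= hi_b) return(sc)
    if (l1 < lo_b) sc_lo <- sc else sc_hi <- sc
  }
  NA_real_
}

# Window-averaged firing statistics of one node: spike counts in trailing
# m-ms windows on a 1-ms grid, smoothed with the detector's n-window rolling
# mean. This is (up to the max-count normalization) the detector observable.
node_window_stats <- function(trace, node, m = 250, n = 25, from = 0) {
  sp <- sort(spike_times(trace)[[node]])
  times <- seq(from + m, trace$T_ms, by = 1)
  cnt <- window_counts(sp, times, m)
  cs <- cumsum(cnt)
  idx <- n:length(cnt)
  avg <- (cs[idx] - c(0, cs)[idx - n + 1L]) / n
  list(mean = mean(avg), sd = stats::sd(avg))
}

#' Generate a fragile epileptic-network fixture
#'
#' Rejection-samples networks from a [generator_spec()] until a candidate
#' satisfies all of:
#' \enumerate{
#'   \item the mean-field fixed point converges and all
#'     `Re(lambda_i(A)) < 0` after a global weight rescaling places
#'     `Re(lambda_1(A))` in the marginal band (the network is stable but
#'     on the brink of instability);
#'   \item every node has finite fragility energy at the marginal target
#'     and the most fragile node is inhibitory;
#'   \item (if `verify_dynamics`) simulating each destabilized structure
#'     `W_s + functional_scale * Delta(target)` reproduces the
#'     disinhibition mechanism: the fragile node's window-averaged firing
#'     rate (the detector observable) drops at least two stable-mode
#'     standard deviations below its stable-mode mean while the mean rate
#'     of the remaining nodes increases. Every seizure matrix the closed
#'     loop consumes must behave like a seizure.
#' }
#' The accepted network is relabelled so the fragile node sits at
#' `spec$fragile_position` (node 4 by default).
#'
#' @param spec A [generator_spec()].
#' @param seed Optional integer seed; fixtures are reproducible for a
#'   fixed seed.
#' @return A list of class `generated_network`: `cfg`
#'   ([network_config()]), `modes` ([build_mode_matrices()] result at
#'   `spec$targets`), `fragility` (the marginal-target
#'   [fragility_ranking()]), `inhibitory` (1-based indices),
#'   `fragile_node`, `rejections`.
#' @export
generate_network <- function(spec = generator_spec(), seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(seed)) set.seed(seed)
  diag_msgs <- character(0)
  for (attempt in seq_len(spec$max_rejections)) {
    cand <- sample_candidate(spec)
    sc <- rescale_to_band(cand$W, cand$h, spec)
    if (is.na(sc)) {
      diag_msgs <- c(diag_msgs, "no scale put Re(lambda_1) in the band")
      next
    }
    W <- sc * cand$W
    cfg <- network_config(W, cand$h, spec$alpha, spec$f_params)
    modes <- tryCatch(build_mode_matrices(cfg, target_res = spec$targets,
                                          check = FALSE),
                      error = function(e) NULL)
    if (is.null(modes)) {
      diag_msgs <- c(diag_msgs, "fragility analysis failed")
      next
    }
    if (!all(is.finite(modes$ranking$energies))) {
      diag_msgs <- c(diag_msgs, "some rows have infinite fragility energy")
      next
    }
    if (!(modes$fragile_node %in% cand$inhibitory)) {
      diag_msgs <- c(diag_msgs, "most fragile node is not inhibitory")
      next
    }
    if (spec$verify_dynamics &&
        !check_disinhibition(cfg, modes, duration = 2e4)) {
      diag_msgs <- c(diag_msgs, "no disinhibition signature in simulation")
      next
    }
    out <- relabel_network(cfg, cand$inhibitory, modes$fragile_node, spec)
    modes <- build_mode_matrices(out$cfg, target_res = spec$targets,
                                 check = FALSE)
    return(structure(
      list(cfg = out$cfg, modes = modes, fragility = modes$ranking,
           inhibitory = out$inhibitory, fragile_node = modes$fragile_node,
           rejections = attempt - 1L),
      class = "generated_network"
    ))
  }
  tab <- sort(table(diag_msgs), decreasing = TRUE)
  stop("generate_network: no acceptable network in ", spec$max_rejections,
       " candidates; rejection reasons: ",
       paste(names(tab), "(", as.integer(tab), ")", collapse = "; "))
}

# Disinhibition check by simulation: in every destabilized network the
# fragile node's rate drops below (stable mean - 2 SD of the stable-mode
# observable) and the other nodes' pooled spike rate increases. Every
# seizure matrix the closed loop consumes must behave like a seizure.
check_disinhibition <- function(cfg, modes, duration = 2e4, m = 250) {
  frag <- modes$fragile_node
  tr_s <- gillespie_simulate(cfg, T_ms = duration,
                             seed = sample.int(.Machine$integer.max - 1L, 1))
  st_s <- node_window_stats(tr_s, frag, m, from = duration / 4)
  if (!is.finite(st_s$sd) || st_s$sd == 0) return(FALSE)
  other <- setdiff(seq_len(cfg$N), frag)
  rate_other <- function(trace) {
    sp <- spike_times(trace)
    sum(lengths(sp[other])) / trace$T_ms
  }
  for (Wu in modes$perturbed) {
    cfg_u <- network_config(Wu, cfg$h, cfg$alpha, cfg$f_params)
    tr_u <- gillespie_simulate(cfg_u, T_ms = duration,
                               seed = sample.int(.Machine$integer.max - 1L,
                                                 1))
    st_u <- node_window_stats(tr_u, frag, m, from = duration / 4)
    if (!(st_u$mean < st_s$mean - 2 * st_s$sd &&
            rate_other(tr_u) > rate_other(tr_s))) {
      return(FALSE)
    }
  }
  TRUE
}

# Swap node labels so the fragile node sits at the requested position.
relabel_network <- function(cfg, inhibitory, fragile, spec) {
  pos <- spec$fragile_position
  if (is.na(pos) || pos == fragile || pos > cfg$N) {
    return(list(cfg = cfg, inhibitory = inhibitory))
  }
  perm <- seq_len(cfg$N)
  perm[c(fragile, pos)] <- c(pos, fragile)
  W <- cfg$W[perm, perm]
  h <- cfg$h[perm]
  inhib <- sort(match(inhibitory, perm))
  list(cfg = network_config(W, h, cfg$alpha, cfg$f_params),
       inhibitory = inhib)
}

#' @export
print.generated_network <- function(x, ...) {
  cat("<generated_network> N =", x$cfg$N,
      "| connections =", sum(x$cfg$W != 0),
      "| inhibitory:", paste(x$inhibitory, collapse = ", "),
      "| fragile node:", x$fragile_node,
      "| Re(lambda_1(A)) =", signif(Re(x$modes$A$eigenvalues[1]), 4),
      "ms^-1\n")
  invisible(x)
}
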