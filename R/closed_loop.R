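#' Calibrate the full detector pipeline
#'
#' Runs the calibration protocol against a stable network and its
#' destabilized variants: (i) the window normalization `max_count` from a
#' stable-mode simulation (default 100 s); (ii) Gaussian emission densities
#' `q1`/`q2` fit by MLE to the monitored node's normalized firing rate in a
#' stable-mode simulation and in unstable-mode simulations (one per
#' destabilized matrix, pooled); (iii) the detection threshold as the mean
#' likelihood-ratio derivative over unstable-mode simulations (default
#' 60 s each). All runs use independent seeds derived from `seed`.
#'
#' @param cfg Stable-mode [network_config()].
#' @param modes A [build_mode_matrices()] result.
#' @param params A [detector_params()] (its `max_count`/`threshold` are
#'   filled in).
#' @param seed Optional integer seed.
#' @param node Monitored node (default: the fragile node).
#' @param maxcount_duration,emission_duration,threshold_duration Lengths of
#'   the calibration simulations in ms (defaults 1e5, 1e5, 6e4).
#' @param emission_settle Initial span of each emission run discarded
#'   before fitting, in ms (default 2000). Calibration runs start from the
#'   all-quiescent state, so their first moments are not mode-typical
#'   samples; for the unstable runs the first window values additionally
#'   mix in pre-transition dynamics. If discarding leaves a degenerate
#'   (zero-variance) sample the full run is used instead.
#' @param pooling Threshold pooling mode, see [calibrate_threshold()].
#' @return An object of class `detector_calibration`: `params` (with
#'   `max_count` and `threshold` set), `em`, `node`.
#' @export
calibrate_detector <- function(cfg, modes, params = detector_params(),
                               seed = NULL, node = modes$fragile_node,
                               maxcount_duration = 1e5,
                               emission_duration = 1e5,
                               threshold_duration = 6e4,
                               emission_settle = 2000,
                               pooling = "pooled") {
  stopifnot(inherits(modes, "mode_matrices"))
  if (!is.null(seed)) set.seed(seed)
  n_u <- length(modes$perturbed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L + 2L * n_u)

  params$max_count <- calibrate_max_count(cfg, params, node,
                                          duration = maxcount_duration,
                                          seed = seeds[1])

  settled <- function(ser) {
    keep <- ser$valid & ser$times >= emission_settle
    out <- ser$p[keep]
    if (length(out) < 2 || stats::var(out) == 0) out <- ser$p[ser$valid]
    out
  }
  stable_tr <- gillespie_simulate(cfg, T_ms = emission_duration,
                                  seed = seeds[2])
  stable_p <- settled(firing_rate_series(stable_tr, node, params))
  cfgs_u <- lapply(modes$perturbed, function(Wu) {
    network_config(Wu, cfg$h, cfg$alpha, cfg$f_params)
  })
  unstable_p <- unlist(lapply(seq_len(n_u), function(i) {
    tr <- gillespie_simulate(cfgs_u[[i]], T_ms = emission_duration,
                             seed = seeds[2L + i])
    settled(firing_rate_series(tr, node, params))
  }))
  if (length(unstable_p) < 2 || stats::var(unstable_p) == 0) {
    stop("degenerate unstable-mode calibration: constant firing rate")
  }
  em <- fit_emissions(stable_p, unstable_p)

  params$threshold <- calibrate_threshold(
    cfgs_u, em, params, node, duration = threshold_duration,
    seeds = seeds[(2L + n_u + 1L):(2L + 2L * n_u)], pooling = pooling
  )
  structure(list(params = params, em = em, node = node),
            class = "detector_calibration")
}

#' @export
print.detector_calibration <- function(x, ...) {
  cat("<detector_calibration> node", x$node,
      "| max_count =", x$params$max_count,
      "| threshold =", signif(x$params$threshold, 4), "per ms\n  ")
  print(x$em)
  invisible(x)
}

#' Run the closed-loop control system
#'
#' Simulates the full feedback loop on a fixed evaluation grid
#' (`grid_dt` ms): the network evolves by exact event-driven simulation
#' within each grid step; at grid boundaries the detector updates the
#' windowed firing rate of the monitored node and its cumulative
#' likelihood-ratio statistic. The network starts stable (`W_s`); seizure
#' onsets arrive with probability `rho` per grid step (equivalently, a
#' geometric onset delay), at which point the structural matrix is swapped
#' for `W_s + Delta` of the episode's eigenvalue target. When the
#' likelihood-ratio derivative crosses the calibrated threshold the switch
#' `sigma` closes and the state-feedback gain of the requested variant is
#' applied; when the monitored rate has stayed within the stable band for
#' `stable_hold` ms, `sigma` opens, `W_s` is restored, the HMM belief is
#' reset to stable, and a refractory period of one detector burn-in
#' elapses before the next onset may be scheduled. An episode whose
#' detection or recovery exceeds `episode_horizon` is recorded as
#' unresolved and the network is forcibly restored.
#'
#' @param cfg Stable-mode [network_config()].
#' @param modes A [build_mode_matrices()] result.
#' @param calib A [calibrate_detector()] result.
#' @param variant Controller variant: `"nonlinear"` (`K = -Delta`) or
#'   `"linear"` (`K = -B^-1 Delta`).
#' @param n_episodes Stop after this many concluded onset episodes
#'   (default `Inf`).
#' @param detections_per_target Alternatively, stop once every target has
#'   this many true-positive detections.
#' @param targets Names of entries of `modes$perturbed` to cycle through
#'   (one per episode, round robin).
#' @param rho Onset probability per grid step (default from `calib`); 0
#'   disables onsets.
#' @param total_T Hard wall on simulated time in ms.
#' @param episode_horizon Per-episode resolution horizon in ms
#'   (default 6e4).
#' @param seed Optional integer seed.
#' @param record_trace If `TRUE`, keep the per-grid-step detector trace
#'   (time, p, dgr, sigma, z, u applied to the fragile node).
#' @return An object of class `closed_loop_result`: `episodes` (one row
#'   per concluded episode or false-positive detection), `n_false_positive`,
#'   `variant`, and optionally `trace` (data frame).
#' @export
closed_loop_run <- function(cfg, modes, calib,
                            variant = c("nonlinear", "linear"),
                            n_episodes = Inf, detections_per_target = NULL,
                            targets = names(modes$perturbed),
                            rho = calib$params$rho,
                            total_T = NULL, episode_horizon = 6e4,
                            seed = NULL, record_trace = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(modes, "mode_matrices"),
            inherits(calib, "detector_calibration"))
  if (!is.null(seed)) set.seed(seed)
  pars <- calib$params
  if (is.null(pars$max_count) || is.null(pars$threshold)) {
    stop("detector is not calibrated (max_count / threshold missing)")
  }
  if (is.infinite(n_episodes) && is.null(detections_per_target)) {
    stop("set n_episodes or detections_per_target")
  }
  n_tg <- length(targets)
  if (is.null(total_T)) {
    want <- if (!is.null(detections_per_target)) {
      detections_per_target * n_tg
    } else {
      n_episodes
    }
    mean_wait <- if (rho > 0) pars$grid_dt / rho else 0
    total_T <- (want + 5) * (mean_wait + episode_horizon)
  }

  N <- cfg$N
  frag <- calib$node
  alpha <- cfg$alpha
  fmax <- cfg$f_params$f_max
  gain <- cfg$f_params$gain
  th_f <- cfg$f_params$threshold
  h <- cfg$h
  dtg <- pars$grid_dt
  m_win <- pars$m
  n_win <- pars$n
  maxc <- pars$max_count
  thr <- pars$threshold
  burn <- detector_burn_in(pars)
  need_hold <- as.integer(round(pars$stable_hold / dtg)) + 1L
  halfw <- pars$band_halfwidth_sd * sqrt(calib$em$q1$var)
  band_lo <- calib$em$q1$mean - halfw
  band_hi <- calib$em$q1$mean + halfw
  # log-likelihood-ratio as a quadratic in p (both emissions Gaussian)
  v1 <- calib$em$q1$var; v2 <- calib$em$q2$var
  m1 <- calib$em$q1$mean; m2 <- calib$em$q2$mean
  qa <- -0.5 * (1 / v2 - 1 / v1)
  qb <- m2 / v2 - m1 / v1
  qc <- -0.5 * (m2^2 / v2 - m1^2 / v1) - 0.5 * log(v2 / v1)
  log_cap <- log(.LR_CAP)

  # per-target gain rows (only the fragile row of K is non-zero)
  gain_rows <- lapply(targets, function(nm) {
    delta <- modes$deltas[[nm]]
    if (is.null(delta)) stop("unknown target: ", nm)
    K <- if (variant == "nonlinear") nonlinear_gain(delta)
         else linear_gain(modes$B, delta)
    K$K[frag, ]
  })
  Wu_list <- lapply(targets, function(nm) modes$perturbed[[nm]])

  # --- mutable loop state -------------------------------------------------
  W_act <- cfg$W
  x <- integer(N)
  sx <- numeric(N) # W_act %*% x
  sigma <- 0L
  z <- 1L # HMM belief
  onset_active <- FALSE
  onset_time <- NA_real_
  onset_t_next <- Inf
  det_time <- NA_real_
  det_tp <- FALSE
  first_band <- NA_real_
  in_band_run <- 0L
  refractory_until <- burn
  tg_idx <- 1L # round-robin pointer into targets
  cur_gain_row <- NULL
  tp_counts <- integer(n_tg)
  episodes_done <- 0L
  n_fp <- 0L

  # spike ring buffer (monitored node) for the trailing m-window count
  SPCAP <- 4096L
  sp_buf <- numeric(SPCAP)
  sp_start <- 0L # number consumed
  sp_len <- 0L
  # window-value ring for the n-window average
  wbuf <- numeric(n_win)
  wlen <- 0L
  widx <- 0L
  wsum <- 0

  rows <- list()
  trace_rows <- if (record_trace) {
    n_steps <- ceiling(total_T / dtg)
    list(time = numeric(n_steps), p = numeric(n_steps),
         dgr = numeric(n_steps), sigma = integer(n_steps),
         z = integer(n_steps), u_frag = numeric(n_steps))
  } else NULL

  schedule_onset <- function(now) now + draw_onset_delay(rho, dtg)
  onset_t_next <- schedule_onset(refractory_until)

  finish_episode <- function(stable_t, resolved) {
    rows[[length(rows) + 1L]] <<- data.frame(
      episode = length(rows) + 1L, variant = variant,
      target = targets[tg_idx],
      onset_time = onset_time,
      detection_time = det_time,
      detection_delay = det_time - onset_time,
      stable_detection_time = stable_t,
      stable_mode_delay = stable_t - det_time,
      first_stable_fr = first_band - det_time,
      onset_to_stable = stable_t - onset_time,
      resolved = resolved, true_positive = det_tp,
      stringsAsFactors = FALSE
    )
  }

  reset_to_stable <- function(now) {
    W_act <<- cfg$W
    sx <<- as.vector(W_act %*% x)
    sigma <<- 0L
    z <<- 1L
    onset_active <<- FALSE
    onset_time <<- NA_real_
    det_time <<- NA_real_
    det_tp <<- FALSE
    first_band <<- NA_real_
    in_band_run <<- 0L
    cur_gain_row <<- NULL
    refractory_until <<- now + burn
    tg_idx <<- if (tg_idx == n_tg) 1L else tg_idx + 1L
    onset_t_next <<- schedule_onset(now + burn)
  }

  done <- function() {
    if (!is.null(detections_per_target)) {
      all(tp_counts >= detections_per_target)
    } else {
      episodes_done >= n_episodes
    }
  }

  n_steps <- ceiling(total_T / dtg)
  k <- 0L
  while (k < n_steps) {
    k <- k + 1L
    t0 <- (k - 1L) * dtg
    t1 <- k * dtg

    # seizure onset at the grid boundary
    if (!onset_active && sigma == 0L && t0 >= onset_t_next) {
      onset_active <- TRUE
      onset_time <- t0 # belief z stays 1 until detection
      W_act <- Wu_list[[tg_idx]]
      sx <- as.vector(W_act %*% x)
      onset_t_next <- Inf
    }

    # ---- exact event-driven simulation over (t0, t1] --------------------
    tc <- t0
    repeat {
      if (sigma == 1L) {
        u_frag <- h[frag] + sum(cur_gain_row * x)
      } else {
        u_frag <- h[frag]
      }
      s <- sx + h
      s[frag] <- sx[frag] + u_frag
      zt <- tanh(gain * (s - th_f))
      f <- fmax * (zt * (zt > 0))
      tr <- alpha * x + f * (1 - x)
      tr_net <- sum(tr)
      if (tr_net <= 0) break
      dt_e <- -log(stats::runif(1)) / tr_net
      tc <- tc + dt_e
      if (tc > t1) break
      i <- pick_index(tr, tr_net)
      if (x[i] == 1L) {
        x[i] <- 0L
        sx <- sx - W_act[, i]
      } else {
        x[i] <- 1L
        sx <- sx + W_act[, i]
        if (i == frag) { # record a spike of the monitored node
          if (sp_len == SPCAP) stop("spike buffer overflow")
          sp_buf[((sp_start + sp_len) %% SPCAP) + 1L] <- tc
          sp_len <- sp_len + 1L
        }
      }
    }

    # ---- detector update at t1 ------------------------------------------
    while (sp_len > 0L && sp_buf[(sp_start %% SPCAP) + 1L] <= t1 - m_win) {
      sp_start <- sp_start + 1L
      sp_len <- sp_len - 1L
    }
    p_k <- NA_real_
    dgr_k <- NA_real_
    if (t1 >= m_win) {
      wv <- sp_len / maxc
      if (wlen == n_win) {
        wsum <- wsum - wbuf[widx + 1L]
      } else {
        wlen <- wlen + 1L
      }
      wbuf[widx + 1L] <- wv
      wsum <- wsum + wv
      widx <- (widx + 1L) %% n_win
      if (wlen == n_win) p_k <- wsum / n_win
    }

    if (!is.na(p_k)) {
      if (sigma == 0L) {
        llr <- qa * p_k * p_k + qb * p_k + qc
        dgr_k <- exp(min(llr, log_cap)) / dtg
        if (dgr_k > thr) { # instability detected
          sigma <- 1L
          z <- 2L
          det_time <- t1
          det_tp <- onset_active
          cur_gain_row <- gain_rows[[tg_idx]]
          first_band <- NA_real_
          in_band_run <- 0L
          if (!det_tp) n_fp <- n_fp + 1L
        }
      } else {
        if (p_k >= band_lo && p_k <= band_hi) {
          in_band_run <- in_band_run + 1L
          if (is.na(first_band)) first_band <- t1
          if (in_band_run >= need_hold) { # stable mode re-detected
            if (onset_active) {
              finish_episode(t1, resolved = TRUE)
              episodes_done <- episodes_done + 1L
              if (det_tp) tp_counts[tg_idx] <- tp_counts[tg_idx] + 1L
            }
            reset_to_stable(t1)
          }
        } else {
          in_band_run <- 0L
        }
      }
    }

    # ---- horizon safeguards ---------------------------------------------
    if (onset_active && t1 - onset_time > episode_horizon &&
        (sigma == 0L || t1 - det_time > episode_horizon)) {
      finish_episode(NA_real_, resolved = FALSE)
      episodes_done <- episodes_done + 1L
      reset_to_stable(t1)
    } else if (!onset_active && sigma == 1L &&
               t1 - det_time > episode_horizon) {
      # false positive that never re-enters the band: force release
      reset_to_stable(t1)
    }

    if (record_trace) {
      trace_rows$time[k] <- t1
      trace_rows$p[k] <- p_k
      trace_rows$dgr[k] <- dgr_k
      trace_rows$sigma[k] <- sigma
      trace_rows$z[k] <- z
      trace_rows$u_frag[k] <- if (sigma == 1L) {
        h[frag] + sum(cur_gain_row * x)
      } else {
        h[frag]
      }
    }
    if (done()) break
  }

  episodes <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(episode = integer(0), variant = character(0),
               target = character(0), onset_time = numeric(0),
               detection_time = numeric(0), detection_delay = numeric(0),
               stable_detection_time = numeric(0),
               stable_mode_delay = numeric(0), first_stable_fr = numeric(0),
               onset_to_stable = numeric(0), resolved = logical(0),
               true_positive = logical(0), stringsAsFactors = FALSE)
  }
  out <- list(episodes = episodes, n_false_positive = n_fp,
              variant = variant, simulated_ms = k * dtg)
  if (record_trace) {
    keep <- seq_len(k)
    out$trace <- data.frame(lapply(trace_rows, function(v) v[keep]))
  }
  structure(out, class = "closed_loop_result")
}

#' @export
print.closed_loop_result <- function(x, ...) {
  cat("<closed_loop_result>", x$variant, "|", nrow(x$episodes),
      "episode rows |", x$n_false_positive, "false positives |",
      signif(x$simulated_ms / 1000, 4), "s simulated\n")
  invisible(x)
}

#' Run a single seizure episode
#'
#' Convenience wrapper around [closed_loop_run()]: simulates until one
#' onset episode concludes (stable-mode re-detection or horizon) and
#' returns its metrics together with the detector trace.
#'
#' @inheritParams closed_loop_run
#' @param target Name of the destabilized matrix to use for the onset.
#' @return A `closed_loop_result` with a single-row `episodes` table and a
#'   `trace` data frame.
#' @export
run_episode <- function(cfg, modes, calib, variant = c("nonlinear", "linear"),
                        target = names(modes$perturbed)[1], seed = NULL,
                        rho = calib$params$rho, episode_horizon = 6e4,
                        record_trace = TRUE) {
  closed_loop_run(cfg, modes, calib, variant = variant, n_episodes = 1,
                  targets = target, rho = rho,
                  episode_horizon = episode_horizon, seed = seed,
                  record_trace = record_trace)
}

#' Benchmark the feedback controllers
#'
#' Repeats closed-loop episodes until the requested number of
#' true-positive detections has accumulated for every destabilized matrix,
#' for each controller variant, and summarizes the performance metrics
#' (mean and SD of detection delay, stable-mode delay and time to first
#' stable firing rate) alongside true/false-positive and unresolved
#' counts.
#'
#' @inheritParams closed_loop_run
#' @param detections_per_matrix Detections required per destabilized
#'   matrix per variant (default 100).
#' @param variants Controller variants to benchmark.
#' @param seed Optional integer seed (per-variant seeds are derived from
#'   it).
#' @return An object of class `experiment_report`: `episodes` (all episode
#'   rows), `summary` (per-variant mean/SD table), `counts` (per-variant
#'   true/false positives and unresolved episodes).
#' @export
run_benchmark <- function(cfg, modes, calib, detections_per_matrix = 100,
                          variants = c("linear", "nonlinear"), seed = NULL,
                          rho = calib$params$rho, episode_horizon = 6e4) {
  if (!is.null(seed)) set.seed(seed)
  vseeds <- sample.int(.Machine$integer.max - 1L, length(variants))
  runs <- list()
  counts <- list()
  for (vi in seq_along(variants)) {
    if (detections_per_matrix == 0) next
    res <- closed_loop_run(cfg, modes, calib, variant = variants[vi],
                           detections_per_target = detections_per_matrix,
                           rho = rho, episode_horizon = episode_horizon,
                           seed = vseeds[vi])
    runs[[variants[vi]]] <- res$episodes
    counts[[variants[vi]]] <- data.frame(
      variant = variants[vi],
      true_positives = sum(res$episodes$true_positive &
                             res$episodes$resolved),
      false_positives = res$n_false_positive,
      unresolved = sum(!res$episodes$resolved),
      stringsAsFactors = FALSE
    )
  }
  episodes <- if (length(runs)) do.call(rbind, runs) else
    closed_loop_run(cfg, modes, calib, n_episodes = 0, total_T = 1,
                    record_trace = FALSE)$episodes
  rownames(episodes) <- NULL
  structure(
    list(episodes = episodes,
         summary = summarize_episodes(episodes),
         counts = if (length(counts)) do.call(rbind, counts) else
           data.frame(variant = character(0), true_positives = integer(0),
                      false_positives = integer(0), unresolved = integer(0)),
         detections_per_matrix = detections_per_matrix),
    class = "experiment_report"
  )
}

# Time until the next spontaneous stable-to-unstable transition: the HMM
# leaves the stable mode with probability rho per grid step, so the delay
# is geometric with mean grid_dt / rho.
draw_onset_delay <- function(rho, grid_dt) {
  if (rho <= 0) return(Inf)
  (stats::rgeom(1, rho) + 1) * grid_dt
}

#' Summarize episode metrics per controller variant
#'
#' Mean and standard deviation of the per-episode performance metrics,
#' computed over resolved true-positive episodes only (unresolved episodes
#' are counted but excluded, as are false-positive detections).
#'
#' @param episodes Episode table from [closed_loop_run()] or
#'   [run_benchmark()].
#' @return Data frame with one row per variant and metric.
#' @export
summarize_episodes <- function(episodes) {
  keep <- episodes$resolved & episodes$true_positive
  ep <- episodes[keep, , drop = FALSE]
  metrics <- c("detection_delay", "stable_mode_delay", "first_stable_fr",
               "onset_to_stable")
  out <- list()
  for (v in unique(ep$variant)) {
    sub <- ep[ep$variant == v, , drop = FALSE]
    for (mt in metrics) {
      vals <- sub[[mt]]
      out[[length(out) + 1L]] <- data.frame(
        variant = v, metric = mt, n = sum(!is.na(vals)),
        mean_ms = mean(vals, na.rm = TRUE),
        sd_ms = stats::sd(vals, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(variant = character(0), metric = character(0),
                      n = integer(0), mean_ms = numeric(0),
                      sd_ms = numeric(0)))
  }
  do.call(rbind, out)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", nrow(x$episodes), "episode rows\n")
  print(x$summary)
  print(x$counts)
  invisible(x)
}
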