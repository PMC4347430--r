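#' Write a network descriptor to JSON
#'
#' Serializes a [network_config()] as a JSON descriptor
#' `{N, alpha_hz, weights, h, f_params}`. Rates appear in Hz in the file
#' (the I/O convention); internally everything is ms^-1.
#'
#' @param cfg A [network_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(cfg, path) {
  stopifnot(inherits(cfg, "network_config"))
  obj <- list(
    N = cfg$N,
    alpha_hz = cfg$alpha * 1000,
    weights = cfg$W,
    h = cfg$h,
    f_params = list(f_max_hz = cfg$f_params$f_max * 1000,
                    gain = cfg$f_params$gain,
                    threshold = cfg$f_params$threshold)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network descriptor from JSON
#'
#' Inverse of [write_network()]; validates the schema and reports every
#' offending field at once.
#'
#' @param path Path to a JSON network descriptor.
#' @return A [network_config()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  problems <- character(0)
  for (fld in c("N", "alpha_hz", "weights", "h", "f_params")) {
    if (is.null(obj[[fld]])) problems <- c(problems, paste("missing", fld))
  }
  if (!is.null(obj$weights)) {
    W <- as.matrix(obj$weights)
    if (nrow(W) != ncol(W)) {
      problems <- c(problems, "weights is not square")
    } else if (!is.null(obj$N) && nrow(W) != obj$N) {
      problems <- c(problems, "weights dimension disagrees with N")
    }
  }
  if (!is.null(obj$h) && !is.null(obj$N) && length(obj$h) != obj$N) {
    problems <- c(problems, "h length disagrees with N")
  }
  if (length(problems)) {
    stop("invalid network descriptor ", path, ": ",
         paste(problems, collapse = "; "))
  }
  fp <- obj$f_params
  network_config(as.matrix(obj$weights), as.numeric(obj$h),
                 alpha = obj$alpha_hz / 1000,
                 f_params = response_params(f_max = fp$f_max_hz / 1000,
                                            gain = fp$gain,
                                            threshold = fp$threshold))
}

#' Write a matrix as dense CSV
#'
#' Dense CSV with a header row of 1-based node labels (`node_1`, ...).
#'
#' @param M Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  M <- as.matrix(M)
  colnames(M) <- paste0("node_", seq_len(ncol(M)))
  utils::write.csv(M, path, row.names = FALSE)
  invisible(path)
}

#' Read a dense CSV matrix
#'
#' @param path Path written by [write_matrix_csv()].
#' @return Unnamed numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  unname(as.matrix(utils::read.csv(path, check.names = FALSE)))
}

#' Write spike times to CSV
#'
#' Two-column CSV `(time_ms, node_id)`, sorted by time, with 1-based node
#' ids. Times are written at full double precision (lossless well past
#' microsecond resolution). An empty trace produces a header-only file.
#'
#' @param trace A `network_trace` (or a per-node list of spike times).
#' @param path Output file path.
#' @param T_ms Required duration when passing a raw spike list.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(trace, path, T_ms = NULL) {
  if (inherits(trace, "network_trace")) {
    sp <- spike_times(trace)
  } else {
    sp <- trace
    if (is.null(T_ms)) stop("T_ms is required for raw spike lists")
  }
  df <- data.frame(
    time_ms = unlist(sp, use.names = FALSE),
    node_id = rep(seq_along(sp), lengths(sp))
  )
  df <- df[order(df$time_ms), , drop = FALSE]
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike times from CSV
#'
#' @param path Path written by [write_spikes()].
#' @param N Number of nodes (defaults to the largest node id present).
#' @return A per-node list of spike-time vectors.
#' @export
read_spikes <- function(path, N = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "node_id") %in% names(df))) {
    stop("spike file ", path, " must have columns time_ms, node_id")
  }
  if (is.null(N)) N <- if (nrow(df)) max(df$node_id) else 0L
  split(df$time_ms, factor(df$node_id, levels = seq_len(N)))
}

#' Write a full detector or closed-loop trace to CSV
#'
#' @param df Data frame (e.g. the `trace` of [closed_loop_run()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a detector calibration to JSON
#'
#' Stores the emission model, threshold and detector parameters so a
#' calibrated detector can be reloaded without re-simulating.
#'
#' @param calib A [calibrate_detector()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "detector_calibration"))
  obj <- list(node = calib$node,
              emissions = calib$em[c("q1", "q2")],
              params = calib$params[c("m", "n", "grid_dt", "max_count",
                                      "rho", "threshold", "stable_hold",
                                      "band_halfwidth_sd")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detector calibration from JSON
#'
#' @param path Path written by [write_calibration()].
#' @return A `detector_calibration` object.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- do.call(detector_params, obj$params)
  em <- structure(list(q1 = as.list(obj$emissions$q1),
                       q2 = as.list(obj$emissions$q2)),
                  class = "emission_model")
  structure(list(params = pars, em = em, node = obj$node),
            class = "detector_calibration")
}

#' Serialize a fragility report to JSON
#'
#' @param report A [fragility_ranking()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fragility_report <- function(report, path) {
  stopifnot(inherits(report, "fragility_report"))
  rows <- lapply(report$perturbations, function(p) {
    if (is.null(p)) NULL else p$delta[p$row_index, ]
  })
  obj <- list(target_re = report$target_re,
              energies = report$energies,
              fragile_node = report$fragile_node,
              delta_rows = rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' Configuration files drive the command-line interface. Recognized
#' top-level fields: `network` (path to a JSON descriptor) or `generator`
#' (a list of [generator_spec()] arguments), `detector` (a list of
#' [detector_params()] arguments), `variant`, `seed`, `duration_s`,
#' `out_dir`. Unknown fields are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("network", "generator", "detector", "variant", "seed",
             "duration_s", "out_dir")
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  }
  if (!is.null(obj$network) && !file.exists(obj$network)) {
    stop("config references missing network file: ", obj$network)
  }
  structure(obj, class = "run_config")
}

#' Write a run manifest
#'
#' Records the package version, seeds and input-file hashes of a CLI run so
#' it can be reproduced bit-for-bit.
#'
#' @param path Output JSON path.
#' @param seed Seed used.
#' @param inputs Character vector of input file paths (hashed with MD5).
#' @param extra Named list of extra fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, inputs = character(0), extra = list()) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    NULL
  }
  obj <- c(list(package = "fragilenet",
                version = as.character(utils::packageVersion("fragilenet")),
                seed = seed,
                input_md5 = hashes,
                r_version = R.version.string),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
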