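#' Mean-field rate equation
#'
#' Right-hand side of the mean-field activation-probability dynamics
#' `g(r)_i = -alpha * r_i + f(sbar_i) * (1 - r_i)` with
#' `sbar_i = sum_j W[i, j] r_j + u_i`. This replaces the binary states by
#' their activation probabilities; it is exact for a single node and an
#' approximation (correlations neglected) for coupled networks.
#'
#' @param r Activation-probability vector in `[0, 1]^N`.
#' @param cfg A [network_config()].
#' @param u Constant external input vector (default: background `cfg$h`).
#' @return The rate-of-change vector `g(r)` (ms^-1).
#' @export
mean_field_rhs <- function(r, cfg, u = cfg$h) {
  s <- as.vector(cfg$W %*% r) + u
  -cfg$alpha * r + response_function(s, cfg$f_params) * (1 - r)
}

# Jacobian of the mean-field rhs with respect to r (used by the fixed-point
# solver and by linearize()).
mean_field_jacobian <- function(r, cfg, u = cfg$h) {
  s <- as.vector(cfg$W %*% r) + u
  fp <- response_derivative(s, cfg$f_params)
  fv <- response_function(s, cfg$f_params)
  J <- (fp * (1 - r)) * cfg$W # row i scaled by f'(sbar_i)(1 - r_i)
  diag(J) <- diag(J) - cfg$alpha - fv
  J
}

#' Solve for the network's fixed point
#'
#' Finds steady-state activation probabilities `r` with `g(r; W) = 0` by
#' projected gradient descent on the cost `F(r) = 0.5 * ||g(r)||^2`,
#' starting from `r0` (default `0.5` everywhere), with iterates projected
#' onto `[0, 1]^N`. Steps use a Barzilai-Borwein length safeguarded by
#' Armijo backtracking.
#'
#' @param cfg A [network_config()].
#' @param u Constant external input (default background `cfg$h`).
#' @param r0 Starting point (default `rep(0.5, N)`).
#' @param tol Convergence tolerance on the residual norm `||g(r)||`
#'   (default `1e-10` ms^-1).
#' @param max_iter Iteration cap (default `1e5`).
#' @return An object of class `fixed_point`: `r`, `residual_norm`,
#'   `iterations`.
#' @section Errors: if the residual norm does not reach `tol`, an error of
#'   class `fragilenet_fp_error` is signalled carrying the last iterate
#'   (`$r`) and residual (`$residual_norm`).
#' @export
solve_fixed_point <- function(cfg, u = cfg$h, r0 = NULL, tol = 1e-10,
                              max_iter = 1e5) {
  stopifnot(inherits(cfg, "network_config"))
  N <- cfg$N
  if (is.null(r0)) r0 <- rep(0.5, N)
  r <- pmin(pmax(as.numeric(r0), 0), 1)

  cost <- function(r) {
    g <- mean_field_rhs(r, cfg, u)
    list(g = g, F = 0.5 * sum(g * g))
  }
  cur <- cost(r)
  grad <- function(r, g) as.vector(crossprod(mean_field_jacobian(r, cfg, u), g))
  gr <- grad(r, cur$g)
  step <- 1
  it <- 0L
  r_prev <- NULL
  gr_prev <- NULL

  while (it < max_iter) {
    res <- sqrt(2 * cur$F)
    if (res <= tol) {
      return(structure(list(r = r, residual_norm = res, iterations = it),
                       class = "fixed_point"))
    }
    it <- it + 1L
    # Barzilai-Borwein step from the previous iterate, safeguarded below.
    if (!is.null(r_prev)) {
      sv <- r - r_prev
      yv <- gr - gr_prev
      sy <- sum(sv * yv)
      if (is.finite(sy) && sy > 0) {
        step <- min(max(sum(sv * sv) / sy, 1e-12), 1e8)
      }
    }
    # Armijo backtracking with projection onto [0, 1]^N.
    ok <- FALSE
    st <- step
    for (bt in 1:60) {
      r_new <- pmin(pmax(r - st * gr, 0), 1)
      nxt <- cost(r_new)
      dvec <- r_new - r
      if (nxt$F <= cur$F + 1e-4 * sum(gr * dvec) || sum(dvec * dvec) == 0) {
        ok <- TRUE
        break
      }
      st <- st / 2
    }
    if (!ok || all(r_new == r)) {
      res <- sqrt(2 * cur$F)
      stop(errorCondition(
        paste0("fixed-point iteration stalled at residual ", signif(res, 4)),
        r = r, residual_norm = res,
        class = c("fragilenet_fp_error", "error", "condition")
      ))
    }
    r_prev <- r
    gr_prev <- gr
    r <- r_new
    cur <- nxt
    gr <- grad(r, cur$g)
  }
  res <- sqrt(2 * cur$F)
  stop(errorCondition(
    paste0("fixed point did not converge in ", max_iter,
           " iterations (residual ", signif(res, 4), ")"),
    r = r, residual_norm = res,
    class = c("fragilenet_fp_error", "error", "condition")
  ))
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed_point> r =", paste(signif(x$r, 4), collapse = " "),
      "| residual =", signif(x$residual_norm, 3),
      "| iterations =", x$iterations, "\n")
  invisible(x)
}
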