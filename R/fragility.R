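#' Sort eigenvalues by descending real part
#'
#' Deterministic ordering used throughout: descending real part, ties broken
#' by descending imaginary part, then original index.
#'
#' @param ev Complex (or numeric) eigenvalue vector.
#' @return The reordered vector.
#' @export
sort_eigenvalues <- function(ev) {
  ev[order(-Re(ev), -Im(ev), seq_along(ev))]
}

#' Linearize the mean-field dynamics: functional connectivity
#'
#' The Jacobian of the mean-field rate equation at the fixed point is the
#' functional connectivity matrix
#' `A[i, j] = f'(sbar_i) (1 - r_i) W[i, j] - (alpha + f(sbar_i)) [i == j]`.
#' Its leading eigenvalue's real part defines stability: for a stable
#' network `max Re(lambda(A)) < 0`.
#'
#' @param cfg A [network_config()].
#' @param fp A [solve_fixed_point()] result (or any list with an `r` field).
#' @param u Constant input used when solving the fixed point.
#' @return An object of class `functional_connectivity` with fields `A`
#'   (N x N, ms^-1) and `eigenvalues` (sorted by [sort_eigenvalues()]).
#' @export
linearize <- function(cfg, fp, u = cfg$h) {
  A <- mean_field_jacobian(fp$r, cfg, u)
  structure(
    list(A = A,
         eigenvalues = sort_eigenvalues(eigen(A, only.values = TRUE)$values)),
    class = "functional_connectivity"
  )
}

#' @export
print.functional_connectivity <- function(x, ...) {
  cat("<functional_connectivity>", nrow(x$A), "x", ncol(x$A),
      "| Re(lambda_1) =", signif(Re(x$eigenvalues[1]), 5), "ms^-1\n")
  invisible(x)
}

#' Input matrix of the linearized dynamics
#'
#' Derivative of the mean-field rate equation with respect to the external
#' input: `B = diag(f'(sbar_i) * (1 - r_i))`. Each input acts only on its
#' own node, so `B` is diagonal by construction.
#'
#' @inheritParams linearize
#' @return An object of class `input_matrix` with field `B` (N x N
#'   diagonal, ms^-1 per unit input).
#' @export
input_matrix <- function(cfg, fp, u = cfg$h) {
  r <- fp$r
  s <- as.vector(cfg$W %*% r) + u
  b <- response_derivative(s, cfg$f_params) * (1 - r)
  structure(list(B = diag(b, nrow = cfg$N)), class = "input_matrix")
}

#' Minimum-energy single-row destabilizing perturbation
#'
#' Finds the minimum-Euclidean-norm row vector `delta` such that adding the
#' rank-one matrix `Delta = e_row %*% t(delta)` to `A` places an eigenvalue
#' at `target_re`. The singularity condition
#' `det(A - target_re * I + e_row %*% t(delta)) = 0` is linear in `delta`
#' (`t(delta) %*% c = -1` with `c = solve(A - target_re * I, e_row)`), and
#' its least-squares solution is `delta = -c / ||c||^2` with energy
#' `1 / ||c||`. The placement is verified numerically on the eigenvalues of
#' `A + Delta`.
#'
#' @param A Functional connectivity: an N x N matrix or a
#'   `functional_connectivity` object.
#' @param row 1-based index of the perturbed row (the node whose inbound
#'   functional connections are altered).
#' @param target_re Intended leading-eigenvalue real part (ms^-1): `0` for
#'   marginal stability, positive for an unstable network.
#' @param tol Verification tolerance on `|Re(lambda_1(A + Delta)) -
#'   target_re|` (default `1e-6`).
#' @return An object of class `perturbation_matrix`: `delta` (N x N with a
#'   single non-zero row), `row_index`, `energy` (Euclidean norm of the
#'   row), `target_re`, `achieved_re`.
#' @section Errors: if `A - target_re * I` is numerically singular the
#'   target is already an eigenvalue and a zero perturbation (energy 0) is
#'   returned; if after perturbation the leading real part misses the
#'   target by more than `tol` (e.g. another eigenvalue overshoots it), an
#'   error reporting the achieved value is signalled.
#' @export
min_row_perturbation <- function(A, row, target_re, tol = 1e-6) {
  if (inherits(A, "functional_connectivity")) A <- A$A
  N <- nrow(A)
  stopifnot(ncol(A) == N, row >= 1, row <= N, is.finite(target_re))
  M <- A - diag(target_re, N)
  e_row <- numeric(N)
  e_row[row] <- 1
  cvec <- tryCatch(solve(M, e_row), error = function(e) NULL)
  delta_row <- if (is.null(cvec)) numeric(N) else -cvec / sum(cvec^2)
  Delta <- matrix(0, N, N)
  Delta[row, ] <- delta_row
  ev <- sort_eigenvalues(eigen(A + Delta, only.values = TRUE)$values)
  achieved <- Re(ev[1])
  if (abs(achieved - target_re) > tol) {
    stop(errorCondition(
      paste0("eigenvalue placement failed for row ", row, ": target ",
             target_re, ", achieved leading Re(lambda) = ",
             signif(achieved, 6)),
      achieved_re = achieved,
      class = c("fragilenet_perturbation_error", "error", "condition")
    ))
  }
  structure(
    list(delta = Delta, row_index = as.integer(row),
         energy = sqrt(sum(delta_row^2)),
         target_re = target_re, achieved_re = achieved),
    class = "perturbation_matrix"
  )
}

#' Nodal fragility ranking
#'
#' Runs [min_row_perturbation()] for every row of `A` and ranks nodes by the
#' energy of their minimum destabilizing perturbation. The most fragile
#' node is the one needing the least energy; ties are broken by lowest
#' index. Rows where placement fails are assigned infinite energy.
#'
#' @inheritParams min_row_perturbation
#' @return An object of class `fragility_report`: `energies` (length N),
#'   `fragile_node` (1-based argmin), `perturbations` (list of
#'   `perturbation_matrix` or `NULL` for failed rows), `target_re`.
#' @export
fragility_ranking <- function(A, target_re, tol = 1e-6) {
  if (inherits(A, "functional_connectivity")) A <- A$A
  N <- nrow(A)
  perts <- vector("list", N)
  energies <- rep(Inf, N)
  for (i in seq_len(N)) {
    res <- tryCatch(min_row_perturbation(A, i, target_re, tol),
                    fragilenet_perturbation_error = function(e) NULL)
    if (!is.null(res)) {
      perts[[i]] <- res
      energies[i] <- res$energy
    }
  }
  if (all(!is.finite(energies))) {
    stop("eigenvalue placement failed for every row (target ", target_re, ")")
  }
  structure(
    list(energies = energies,
         fragile_node = which.min(energies), # which.min takes lowest index on ties
         perturbations = perts,
         target_re = target_re),
    class = "fragility_report"
  )
}

#' @export
print.fragility_report <- function(x, ...) {
  cat("<fragility_report> target Re(lambda_1) =", x$target_re,
      "ms^-1 | energies:", paste(signif(x$energies, 4), collapse = " "),
      "| fragile node:", x$fragile_node, "\n")
  invisible(x)
}

#' Build the stable and destabilized structural matrices
#'
#' Full fragility pipeline for a stable network: solve the fixed point,
#' linearize to obtain `A` and `B`, rank rows at the marginal target
#' (`Re(lambda_1) = 0`) to identify the most fragile node, then, for each
#' requested eigenvalue target, compute that node's minimum-energy row
#' perturbation and add it directly to the structural matrix:
#' `W_u(target) = W_s + functional_scale * Delta(target)`.
#'
#' The perturbation is computed in functional space (on `A`, in ms^-1),
#' where the eigenvalue targets hold exactly. Adding a functional-space
#' object to the structural matrix is a deliberate unit abuse inherited
#' from the construction being reproduced; `functional_scale` fixes the
#' numerical convention. The default 1000 expresses `Delta` in s^-1
#' numerics (rates are reported in Hz), which is the scale at which the
#' destabilized matrices produce overt seizure dynamics: at pure ms^-1
#' numerics (`functional_scale = 1`) the added row is dominated by a
#' self-connection the binary dynamics cannot see (a node's self-weight
#' only enters its input while the node is already active, when its only
#' transition is decay), and the "seizure" mode is statistically
#' indistinguishable from the stable mode. The re-linearized leading real
#' part of each perturbed structure is reported in `functional_check`
#' (informative only: under strong destabilization the network settles on
#' a different, disinhibited attractor rather than an unstable
#' continuation of the stable fixed point).
#'
#' @param cfg A stable [network_config()] (this is `W_s`).
#' @param fp Optional precomputed [solve_fixed_point()] result.
#' @param target_res Eigenvalue targets in ms^-1 (default `c(0, 0.2)`:
#'   marginal stability and the strongly unstable seizure mode).
#' @param u Constant input (default background `cfg$h`).
#' @param functional_scale Numerical scale at which the functional-space
#'   perturbation is added to the structural matrix (default 1000 =
#'   entries taken in s^-1).
#' @param check If `TRUE` (default) re-solve and re-linearize each perturbed
#'   structure to fill `functional_check`.
#' @return An object of class `mode_matrices`: `W_s`, `perturbed` (named
#'   list of structural matrices, names `"target_<value>"`), `deltas`
#'   (matching list of `perturbation_matrix`), `fragile_node`, `fp`, `A`
#'   (`functional_connectivity`), `B` (`input_matrix`), `ranking`,
#'   `functional_check` (data frame: target, re_lambda1).
#' @export
build_mode_matrices <- function(cfg, fp = NULL, target_res = c(0, 0.2),
                                u = cfg$h, functional_scale = 1000,
                                check = TRUE) {
  stopifnot(inherits(cfg, "network_config"))
  if (is.null(fp)) fp <- solve_fixed_point(cfg, u)
  fc <- linearize(cfg, fp, u)
  B <- input_matrix(cfg, fp, u)
  ranking <- fragility_ranking(fc, 0)
  frag <- ranking$fragile_node

  perturbed <- list()
  deltas <- list()
  chk <- data.frame(target = numeric(0), re_lambda1 = numeric(0))
  for (tg in target_res) {
    pert <- min_row_perturbation(fc, frag, tg)
    nm <- paste0("target_", format(tg, trim = TRUE))
    # express the row perturbation at the structural numerical scale; this
    # is the matrix both the simulator and the gains consume
    pert$delta <- functional_scale * pert$delta
    pert$energy <- functional_scale * pert$energy
    pert$functional_scale <- functional_scale
    deltas[[nm]] <- pert
    perturbed[[nm]] <- cfg$W + pert$delta
    re1 <- NA_real_
    if (check) {
      re1 <- tryCatch({
        cfg_u <- network_config(perturbed[[nm]], cfg$h, cfg$alpha, cfg$f_params)
        fp_u <- solve_fixed_point(cfg_u, u, r0 = fp$r, tol = 1e-8)
        Re(linearize(cfg_u, fp_u, u)$eigenvalues[1])
      }, error = function(e) NA_real_)
    }
    chk <- rbind(chk, data.frame(target = tg, re_lambda1 = re1))
  }
  structure(
    list(W_s = cfg$W, perturbed = perturbed, deltas = deltas,
         fragile_node = frag, fp = fp, A = fc, B = B,
         ranking = ranking, functional_scale = functional_scale,
         functional_check = chk),
    class = "mode_matrices"
  )
}

#' @export
print.mode_matrices <- function(x, ...) {
  cat("<mode_matrices> fragile node", x$fragile_node, "| targets:",
      paste(names(x$perturbed), collapse = ", "),
      "| Re(lambda_1(A)) =", signif(Re(x$A$eigenvalues[1]), 4), "ms^-1\n")
  invisible(x)
}
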