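#' Uniform solver grid on the live interval
#'
#' Discretizes the live interval \eqn{[r_v, \lambda - r_v]} (positions at
#' which no target is yet detected) with uniform spacing `delta`.  The
#' spacing must divide the interval exactly so that the first and last
#' nodes sit on the detection thresholds, and must not exceed `rv` (the
#' natural resolution of detection).
#'
#' @param geometry A [search_geometry()].
#' @param delta Grid spacing; defaults to `rv`.
#' @return Object of class `"solver_grid"` with fields `nodes`, `delta`,
#'   `geometry`.
#' @export
solver_grid <- function(geometry, delta = geometry$rv) {
  stopifnot(is_search_geometry(geometry),
            is.numeric(delta), length(delta) == 1L, delta > 0)
  if (delta > geometry$rv * (1 + 1e-12))
    stop("'delta' must not exceed rv: the grid must resolve the detection scale")
  span <- geometry$lam - 2 * geometry$rv
  ncell <- span / delta
  if (abs(ncell - round(ncell)) > 1e-8)
    stop("'delta' must divide lam - 2*rv exactly (", span, " / ", delta,
         " is not an integer)")
  ncell <- round(ncell)
  nodes <- geometry$rv + delta * (0:ncell)
  nodes[length(nodes)] <- geometry$lam - geometry$rv  # exact endpoint
  structure(list(nodes = nodes, delta = delta, geometry = geometry),
            class = "solver_grid")
}

#' Single-step transition kernel with boundary absorption
#'
#' Matrix `K` whose entry `(i, j)` is the probability that one signed step
#' taken from node `i` lands in the grid cell of node `j` without being
#' truncated by target detection.  Cells are the intervals
#' \eqn{[x_j - \Delta/2,\; x_j + \Delta/2] \cap [r_v, \lambda - r_v]}
#' (half-cells at the two thresholds).  Cell masses are computed by exact
#' integration of the step-magnitude law over each cell via its survival
#' function — not by midpoint evaluation, which misrepresents the
#' \eqn{\ell^{-\mu}} singularity at the cutoff.  Row sums equal the
#' probability that a step from node `i` is *not* truncated; the missing
#' mass is absorbed by the boundary targets.
#'
#' For the fixed-step law the kernel places mass 1/2 on each of the two
#' landing nodes `x_i ± ell`; a landing at or beyond a threshold is
#' absorbed.
#'
#' @param grid A [solver_grid()].
#' @param d A `"step_distribution"`.
#' @return An `n x n` matrix, `n = length(grid$nodes)`.
#' @export
build_transition_kernel <- function(grid, d) {
  stopifnot(inherits(grid, "solver_grid"), inherits(d, "step_distribution"))
  x <- grid$nodes; n <- length(x); h <- grid$delta
  rv <- grid$geometry$rv; lam <- grid$geometry$lam

  if (inherits(d, "fixed_steps")) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (sgn in c(-1, 1)) {
        xl <- x[i] + sgn * d$ell
        if (xl <= rv + 1e-9 * h || xl >= lam - rv - 1e-9 * h) next  # absorbed
        j <- round((xl - rv) / h) + 1
        # off-lattice landings fall in the cell containing the landing point
        j <- min(max(j, 1L), n)
        K[i, j] <- K[i, j] + 0.5
      }
    }
    return(K)
  }

  # Continuous magnitude laws: the mass reaching a cell at |i - j| = k
  # spans magnitudes [(k - 1/2) h, (k + 1/2) h], so the kernel is Toeplitz
  # except in the two half-cells at the thresholds (columns 1 and n).
  S <- function(t) step_ccdf(d, t)
  k <- 0:(n - 1)
  s_half <- S((k + 0.5) * h)           # S((k + 1/2) h), k = 0 .. n-1
  s_full <- S(k * h)                   # S(k h)
  band <- 0.5 * (c(1, s_half[-n]) - s_half)  # one-direction mass at lag k
  band[1] <- 2 * band[1]               # diagonal collects both directions
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lags <- abs(i - seq_len(n))
    K[i, ] <- band[lags + 1]
  }
  # threshold half-cells: [rv, rv + h/2] and [lam - rv - h/2, lam - rv]
  i_int <- 2:(n - 1)
  K[i_int, 1] <- 0.5 * (s_half[i_int - 1] - s_full[i_int])
  K[i_int, n] <- 0.5 * (s_half[n - i_int] - s_full[n - i_int + 1])
  K[1, 1] <- 0.5 * (1 - s_half[1])     # only the right half of the own cell
  K[n, n] <- K[1, 1]
  K[1, n] <- 0.5 * (s_half[n - 1] - s_full[n])
  K[n, 1] <- K[1, n]
  K
}

#' Mean distance travelled between consecutive encounters
#'
#' Solves the discretized integral-operator equation
#' \eqn{D = m + K D} for the mean distance \eqn{\langle D(x_0)\rangle}
#' travelled by the searcher from start position \eqn{x_0} until a target
#' is detected.  Here `m` is the mean length of a single
#' boundary-truncated step at each node ([truncated_step_mean()]) and `K`
#' the survival transition kernel ([build_transition_kernel()]).  Because
#' absorption makes the spectral radius of `K` strictly less than 1, the
#' dense linear system has a unique positive solution.
#'
#' @param geometry A [search_geometry()].
#' @param d A `"step_distribution"`.
#' @param grid A [solver_grid()]; defaults to spacing `rv`.
#' @return Object of class `"mean_distance_profile"`: fields `nodes`, `D`,
#'   `geometry`, `step` (the step law), `mu` (its exponent, `NA` for
#'   non-Levy laws), `delta`.
#' @examples
#' g <- search_geometry(lam = 50, rv = 1)
#' prof <- solve_mean_distance(g, levy_steps(mu = 2, ell0 = 1))
#' @export
solve_mean_distance <- function(geometry, d, grid = solver_grid(geometry)) {
  stopifnot(is_search_geometry(geometry), inherits(d, "step_distribution"),
            inherits(grid, "solver_grid"))
  if (!same_geometry(geometry, grid$geometry))
    stop("'grid' was built for a different geometry")
  x <- grid$nodes
  m <- truncated_step_mean(x - geometry$rv, geometry$lam - geometry$rv - x, d)
  K <- build_transition_kernel(grid, d)
  D <- tryCatch(
    solve(diag(length(x)) - K, m),
    error = function(e) stop("singular discretized system: ", conditionMessage(e)))
  if (any(!is.finite(D)) || any(D <= 0))
    stop("solver produced a non-positive mean distance; check the geometry")
  structure(list(nodes = x, D = D, geometry = geometry, step = d,
                 mu = if (inherits(d, "levy_steps")) d$mu else NA_real_,
                 delta = grid$delta),
            class = "mean_distance_profile")
}

#' @export
print.mean_distance_profile <- function(x, ...) {
  cat("mean distance between encounters <D(x0)>\n")
  cat(sprintf("  step law: %s%s\n", x$step$family,
              if (!is.na(x$mu)) sprintf(" (mu = %g)", x$mu) else ""))
  cat(sprintf("  lam = %g, rv = %g, grid spacing %g (%d nodes)\n",
              x$geometry$lam, x$geometry$rv, x$delta, length(x$nodes)))
  cat(sprintf("  D(rv) = %.6g, D(lam/2) = %.6g\n",
              x$D[1], x$D[which.min(abs(x$nodes - x$geometry$lam / 2))]))
  invisible(x)
}

#' Interpolate a mean-distance profile at arbitrary positions
#'
#' Natural cubic spline in \eqn{x_0} through the solver nodes.
#'
#' @param profile A `"mean_distance_profile"`.
#' @param x0 Positions in \eqn{[r_v, \lambda - r_v]}.
#' @return Mean distances at `x0`.
#' @export
profile_at <- function(profile, x0) {
  stopifnot(inherits(profile, "mean_distance_profile"))
  g <- profile$geometry
  if (any(x0 < g$rv - 1e-9 * g$lam) || any(x0 > g$lam - g$rv + 1e-9 * g$lam))
    stop("positions outside the live interval [rv, lam - rv]")
  splinefun(profile$nodes, profile$D, method = "natural")(x0)
}

#' Grid-refinement convergence report
#'
#' Re-solves the mean-distance profile at a sequence of grid spacings and
#' reports the maximum relative change between successive refinements,
#' evaluated at the nodes the two grids share.  Non-monotone convergence
#' (a refinement step that increases the change) is flagged.
#'
#' @param geometry A [search_geometry()].
#' @param d A `"step_distribution"`.
#' @param deltas Decreasing vector of at least two spacings, each dividing
#'   `lam - 2*rv`.
#' @return A data frame with columns `delta_coarse`, `delta_fine`,
#'   `max_rel_change`, `monotone`; attribute `"profiles"` holds the
#'   per-spacing profiles.
#' @export
check_grid_convergence <- function(geometry, d, deltas) {
  stopifnot(length(deltas) >= 2)
  deltas <- sort(deltas, decreasing = TRUE)
  profs <- lapply(deltas, function(h)
    solve_mean_distance(geometry, d, solver_grid(geometry, h)))
  rel <- numeric(length(deltas) - 1)
  for (i in seq_along(rel)) {
    coarse <- profs[[i]]; fine <- profs[[i + 1]]
    idx <- match(round(coarse$nodes, 9), round(fine$nodes, 9))
    common <- !is.na(idx)
    rel[i] <- max(abs(fine$D[idx[common]] - coarse$D[common]) /
                    abs(fine$D[idx[common]]))
  }
  out <- data.frame(delta_coarse = deltas[-length(deltas)],
                    delta_fine = deltas[-1],
                    max_rel_change = rel,
                    monotone = c(TRUE, diff(rel) <= 0)[seq_along(rel)])
  attr(out, "profiles") <- profs
  out
}
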