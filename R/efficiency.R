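#' Fluctuation-averaged search efficiency
#'
#' Search efficiency is the number of targets found per unit distance
#' travelled; for a fixed start \eqn{x_0} it equals
#' \eqn{1/\langle D(x_0)\rangle}.  When the start position fluctuates with
#' density \eqn{\pi(x_0)}, the average efficiency is read as the
#' \eqn{\pi}-weighted average of the per-start efficiency,
#' \deqn{\langle\eta\rangle = \int_{r_v}^{\lambda/2}
#'   \frac{\pi(x_0)}{\langle D(x_0)\rangle}\, dx_0,}
#' evaluated by trapezoidal quadrature on the profile's own nodes
#' (`mode = "mean_inverse"`, the default).  The alternative reading
#' \eqn{1/\int \pi \langle D\rangle dx_0} — the long-run ratio of
#' encounters to total distance, which is what a single Monte Carlo run
#' with randomized restarts estimates — is available as
#' `mode = "inverse_mean"`.  The two coincide exactly for point-mass start
#' pdfs, where both reduce to \eqn{1/\langle D(\mathrm{atom})\rangle}.
#'
#' @param profile A `"mean_distance_profile"`.
#' @param p A [start_pdf()] sharing the profile's geometry.
#' @param mode `"mean_inverse"` (default) or `"inverse_mean"`; see above.
#' @return Efficiency (1/length), a single positive number.
#' @export
average_efficiency <- function(profile, p,
                               mode = c("mean_inverse", "inverse_mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "mean_distance_profile"), inherits(p, "start_pdf"))
  if (!same_geometry(profile$geometry, p$geometry))
    stop("profile and start pdf were built for different geometries")
  g <- profile$geometry
  if (is_delta_family(p)) {
    # exact point-mass reduction: both modes give 1/D(atom)
    return(1 / profile_at(profile, p$atom))
  }
  half <- g$lam / 2
  keep <- profile$nodes <= half + 1e-9 * g$lam
  xs <- profile$nodes[keep]
  Ds <- profile$D[keep]
  if (abs(xs[length(xs)] - half) > 1e-9 * g$lam) {
    # append the midpoint so the grid covers the full support
    xs <- c(xs, half)
    Ds <- c(Ds, profile_at(profile, half))
  }
  w <- quadrature_weights(p, xs)
  switch(mode,
    mean_inverse = sum(w / Ds),
    inverse_mean = 1 / sum(w * Ds))
}

#' Smooth surrogate for the mean-distance surface
#'
#' The optimizations over the Levy exponent need
#' \eqn{\langle D(x_0; \mu)\rangle} at arbitrary \eqn{\mu}, but each exact
#' solve is a dense linear system.  `fit_surrogate` takes profiles solved
#' on a common position grid at a grid of exponents and returns a smooth
#' evaluator: a tensor-product natural cubic interpolant of
#' \eqn{\log\langle D\rangle} in \eqn{(\mu, x_0)}.  It reproduces every
#' input node exactly and is continuous in both arguments, standing in for
#' a fitted closed-form regression of the surface (whose basis is not
#' uniquely determined) while remaining faithful to the exact solves.
#'
#' @param profiles List of `"mean_distance_profile"` objects on one
#'   geometry and grid, at (at least 5) distinct increasing `mu` values.
#' @return Object of class `"efficiency_surrogate"`.
#' @export
fit_surrogate <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 5)
  mus <- vapply(profiles, function(p) p$mu, numeric(1))
  if (any(is.na(mus))) stop("all profiles must use the Levy step family")
  o <- order(mus)
  profiles <- profiles[o]; mus <- mus[o]
  if (any(diff(mus) <= 0)) stop("'mu' values must be distinct")
  g <- profiles[[1]]$geometry
  nodes <- profiles[[1]]$nodes
  for (p in profiles[-1]) {
    if (!same_geometry(p$geometry, g) || length(p$nodes) != length(nodes) ||
        max(abs(p$nodes - nodes)) > 1e-9 * g$lam)
      stop("profiles must share one geometry and one position grid")
  }
  logD <- vapply(profiles, function(p) log(p$D), numeric(length(nodes)))
  # one natural cubic spline in mu per position node
  splines <- apply(logD, 1L, function(row)
    splinefun(mus, row, method = "natural"))
  structure(list(geometry = g, nodes = nodes, mu_grid = mus,
                 logD = logD, splines = splines,
                 delta = profiles[[1]]$delta,
                 step_template = profiles[[1]]$step),
            class = "efficiency_surrogate")
}

#' @export
print.efficiency_surrogate <- function(x, ...) {
  cat("mean-distance surrogate (tensor-product spline of log D)\n")
  cat(sprintf("  mu grid: %d nodes on [%g, %g]\n",
              length(x$mu_grid), min(x$mu_grid), max(x$mu_grid)))
  cat(sprintf("  position grid: %d nodes, lam = %g, rv = %g\n",
              length(x$nodes), x$geometry$lam, x$geometry$rv))
  invisible(x)
}

#' Evaluate the surrogate as a profile at one exponent
#'
#' @param s An `"efficiency_surrogate"`.
#' @param mu Exponent inside the surrogate's `mu` grid range.
#' @return A `"mean_distance_profile"` on the surrogate's position grid.
#' @export
surrogate_profile <- function(s, mu) {
  stopifnot(inherits(s, "efficiency_surrogate"), length(mu) == 1L)
  if (mu < min(s$mu_grid) - 1e-9 || mu > max(s$mu_grid) + 1e-9)
    stop("'mu' outside the surrogate's exponent grid [",
         min(s$mu_grid), ", ", max(s$mu_grid), "]")
  D <- exp(vapply(s$splines, function(f) f(mu), numeric(1)))
  structure(list(nodes = s$nodes, D = D, geometry = s$geometry,
                 step = levy_steps(min(max(mu, 1 + MU_EPS), 3),
                                   s$geometry$ell0),
                 mu = mu, delta = s$delta),
            class = "mean_distance_profile")
}

#' Evaluate the surrogate pointwise
#'
#' Spline in `mu` at each grid node followed by a spline in `x0`.
#'
#' @param s An `"efficiency_surrogate"`.
#' @param x0 Positions in the live interval.
#' @param mu Single exponent in the surrogate's range.
#' @return Mean distances at (`x0`, `mu`).
#' @export
surrogate_at <- function(s, x0, mu) {
  profile_at(surrogate_profile(s, mu), x0)
}

# Efficiency as a function of mu through the surrogate, vectorized over mu.
surrogate_efficiency <- function(s, p, mus, mode = "mean_inverse") {
  vapply(mus, function(m)
    average_efficiency(surrogate_profile(s, m), p, mode = mode),
    numeric(1))
}

#' Optimal Levy exponent for a start-position pdf
#'
#' Maximizes the fluctuation-averaged efficiency over the exponent by a
#' dense grid scan (step 0.01) followed by golden-section refinement when
#' the maximizer is interior.  Maximization is used instead of solving the
#' stationarity condition \eqn{\partial\langle\eta\rangle/\partial\mu = 0}
#' because for strong fluctuations the maximum sits on the lower clamp of
#' the admissible domain ([mu_domain()]), where the derivative does not
#' vanish; such an optimum is flagged `at_boundary` and identified with
#' the ballistic strategy.
#'
#' @param p A [start_pdf()].
#' @param s An `"efficiency_surrogate"` on the same geometry.
#' @param mu_bounds Search interval; defaults to the intersection of
#'   [mu_domain()] with the surrogate's exponent grid range.
#' @param mode Efficiency reading, see [average_efficiency()].
#' @return Object of class `"optimal_strategy"`: fields `family`, `alpha`,
#'   `beta`, `mu_opt`, `eta_max`, `at_boundary`.
#' @export
optimal_mu <- function(p, s, mu_bounds = NULL, mode = "mean_inverse") {
  stopifnot(inherits(p, "start_pdf"), inherits(s, "efficiency_surrogate"))
  dom <- mu_domain()
  if (is.null(mu_bounds))
    mu_bounds <- c(max(dom[1], min(s$mu_grid)), min(dom[2], max(s$mu_grid)))
  stopifnot(length(mu_bounds) == 2L, mu_bounds[1] < mu_bounds[2])
  mus <- seq(mu_bounds[1], mu_bounds[2], by = 0.01)
  if (mus[length(mus)] < mu_bounds[2]) mus <- c(mus, mu_bounds[2])
  eta <- surrogate_efficiency(s, p, mus, mode = mode)
  i <- which.max(eta)
  if (i == 1L) {
    res <- list(mu_opt = mus[1], eta_max = eta[1], at_boundary = TRUE)
  } else if (i == length(mus)) {
    res <- list(mu_opt = mus[i], eta_max = eta[i], at_boundary = FALSE)
  } else {
    opt <- optimize(function(m) surrogate_efficiency(s, p, m, mode = mode),
                    lower = mus[i - 1], upper = mus[i + 1], maximum = TRUE,
                    tol = 1e-4)
    res <- list(mu_opt = opt$maximum, eta_max = opt$objective,
                at_boundary = FALSE)
  }
  structure(c(list(family = p$family, alpha = p$alpha, beta = p$beta,
                   mode = mode), res),
            class = "optimal_strategy")
}

#' @export
print.optimal_strategy <- function(x, ...) {
  cat(sprintf("optimal Levy exponent for start pdf '%s'%s\n", x$family,
              if (!is.null(x$alpha)) sprintf(" (alpha = %g)", x$alpha) else ""))
  cat(sprintf("  mu_opt = %.4g   eta_max = %.6g   %s\n", x$mu_opt, x$eta_max,
              if (x$at_boundary) "[on the lower clamp: ballistic]" else "[interior optimum]"))
  invisible(x)
}

#' Optimal exponent as a function of the fluctuation strength
#'
#' Sweeps [optimal_mu()] over a vector of `alpha` values for a Poisson-like
#' start family.  For fluctuations in the distance to the nearby target
#' (`poisson_asymmetric`) the optimum shifts to faster, more superdiffusive
#' strategies (lower `mu_opt`) as `alpha` grows, eventually reaching the
#' ballistic clamp.
#'
#' @param family `"poisson_asymmetric"` or `"poisson_symmetric"`.
#' @param alphas Increasing vector of positive fluctuation parameters.
#' @param s An `"efficiency_surrogate"`.
#' @param mode Efficiency reading, see [average_efficiency()].
#' @return Data frame with one row per `alpha`: `alpha`, `mu_opt`,
#'   `eta_max`, `at_boundary`.
#' @export
optimal_mu_curve <- function(family, alphas, s, mode = "mean_inverse") {
  stopifnot(family %in% c("poisson_asymmetric", "poisson_symmetric"),
            all(alphas > 0), !is.unsorted(alphas))
  rows <- lapply(alphas, function(a) {
    r <- optimal_mu(start_pdf(family, s$geometry, alpha = a), s, mode = mode)
    data.frame(alpha = a, mu_opt = r$mu_opt, eta_max = r$eta_max,
               at_boundary = r$at_boundary)
  })
  do.call(rbind, rows)
}

#' Crossover fluctuation strength to ballistic optima
#'
#' Locates by bisection (in log alpha) the smallest fluctuation parameter
#' `alpha` at which the optimal strategy sits on the ballistic clamp.  The
#' two bracket endpoints must disagree on `at_boundary`; otherwise the
#' error names both endpoint states (for fluctuations around the faraway
#' target, `poisson_symmetric`, the optimum is ballistic at every `alpha`
#' and no crossover exists).
#'
#' @param family Poisson-like start family name.
#' @param s An `"efficiency_surrogate"`.
#' @param alpha_bracket Length-2 positive vector bracketing the crossover.
#' @param tol Relative width of the final bracket (default 0.05).
#' @param mode Efficiency reading, see [average_efficiency()].
#' @return List with `alpha_c` (geometric midpoint of the final bracket),
#'   `lower`, `upper`, and the sweep `history`.
#' @export
crossover_alpha <- function(family, s, alpha_bracket, tol = 0.05,
                            mode = "mean_inverse") {
  stopifnot(length(alpha_bracket) == 2L, all(alpha_bracket > 0),
            alpha_bracket[1] < alpha_bracket[2])
  at_clamp <- function(a)
    optimal_mu(start_pdf(family, s$geometry, alpha = a), s,
               mode = mode)$at_boundary
  lo <- alpha_bracket[1]; hi <- alpha_bracket[2]
  f_lo <- at_clamp(lo); f_hi <- at_clamp(hi)
  if (f_lo == f_hi)
    stop("no crossover in the bracket: at_boundary is ", f_lo, " at alpha = ",
         lo, " and ", f_hi, " at alpha = ", hi,
         if (!f_lo) " (no ballistic regime found)" else
           " (ballistic at both ends)")
  if (f_lo) stop("bracket is reversed: already ballistic at the lower end")
  hist <- data.frame(alpha = c(lo, hi), at_boundary = c(f_lo, f_hi))
  while (hi / lo - 1 > tol) {
    mid <- sqrt(lo * hi)
    f_mid <- at_clamp(mid)
    hist <- rbind(hist, data.frame(alpha = mid, at_boundary = f_mid))
    if (f_mid) hi <- mid else lo <- mid
  }
  list(alpha_c = sqrt(lo * hi), lower = lo, upper = hi,
       history = hist[order(hist$alpha), ])
}
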