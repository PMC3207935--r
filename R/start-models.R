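#' Start-position (landscape heterogeneity) models
#'
#' The landscape enters the model through the probability density
#' \eqn{\pi(x_0)} of the searcher's restart position after each encounter.
#' Because a search starting at \eqn{x_0} is statistically identical to one
#' starting at \eqn{\lambda - x_0}, all densities are defined and
#' normalized on the half-interval \eqn{[r_v, \lambda/2]}.
#'
#' Families:
#' * `delta_symmetric`: point mass at \eqn{\lambda/2} (fully symmetric
#'   start, the destructive-search limit: the searcher restarts equidistant
#'   from both targets).
#' * `delta_asymmetric`: point mass at \eqn{r_v} (highest-asymmetry start,
#'   the non-destructive limit: the searcher restarts at the detection
#'   threshold of the last-found target).
#' * `delta`: point mass at an arbitrary `x0` in the support (generalizes
#'   the two above; used for fixed-start experiments).
#' * `poisson_symmetric`: density \eqn{\propto e^{-(\lambda/2 - x_0)/(\alpha r_v)}},
#'   exponentially decaying with distance from the midpoint — fluctuations
#'   in the starting distance to the *faraway* targets.
#' * `poisson_asymmetric`: density \eqn{\propto e^{-(x_0 - r_v)/(\alpha r_v)}},
#'   decaying away from the near-target threshold — fluctuations in the
#'   starting distance to the *nearby* target.
#' * `uniform`: constant on the support (the \eqn{\alpha \to \infty} limit
#'   of both Poisson-like families).
#' * `power_law`: density \eqn{\propto x_0^{-\beta}} — scale-free start
#'   fluctuations.
#'
#' The dimensionless parameter `alpha` sets the decay length
#' \eqn{\sigma = \alpha r_v} of the Poisson-like families: small `alpha`
#' concentrates restarts near the reference point, large `alpha`
#' approaches the uniform law.
#'
#' @param family One of `"delta_symmetric"`, `"delta_asymmetric"`,
#'   `"delta"`, `"poisson_symmetric"`, `"poisson_asymmetric"`,
#'   `"uniform"`, `"power_law"`.
#' @param geometry A [search_geometry()].
#' @param alpha Positive fluctuation-range parameter (Poisson-like
#'   families only).
#' @param beta Positive exponent of the power-law family.
#' @param x0 Atom location for `family = "delta"`.
#'
#' @return An object of class `"start_pdf"`.
#' @examples
#' g <- search_geometry(lam = 100, rv = 1)
#' p <- start_pdf("poisson_asymmetric", g, alpha = 2)
#' start_density(p, c(1, 2, 5))
#' @export
start_pdf <- function(family = c("delta_symmetric", "delta_asymmetric", "delta",
                                 "poisson_symmetric", "poisson_asymmetric",
                                 "uniform", "power_law"),
                      geometry, alpha = NULL, beta = NULL, x0 = NULL) {
  family <- match.arg(family)
  stopifnot(is_search_geometry(geometry))
  rv <- geometry$rv; half <- geometry$lam / 2
  if (family %in% c("poisson_symmetric", "poisson_asymmetric")) {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
      stop("'alpha' must be a single positive number for the Poisson-like families")
  } else if (!is.null(alpha)) {
    stop("'alpha' applies only to the Poisson-like families")
  }
  if (family == "power_law") {
    if (is.null(beta) || !is.numeric(beta) || length(beta) != 1L || beta <= 0)
      stop("'beta' must be a single positive number for the power-law family")
  } else if (!is.null(beta)) {
    stop("'beta' applies only to the power-law family")
  }
  atom <- switch(family,
    delta_symmetric = half,
    delta_asymmetric = rv,
    delta = {
      if (is.null(x0) || !is.numeric(x0) || length(x0) != 1L)
        stop("'x0' must be a single position for family = \"delta\"")
      if (x0 < rv || x0 > half)
        stop("'x0' must lie in the support [rv, lam/2]")
      x0
    },
    NULL)
  structure(list(family = family, geometry = geometry,
                 alpha = alpha, beta = beta, atom = atom),
            class = "start_pdf")
}

#' @export
print.start_pdf <- function(x, ...) {
  cat("start-position pdf:", x$family, "\n")
  if (!is.null(x$alpha)) cat(sprintf("  alpha = %g (decay length %g)\n",
                                     x$alpha, x$alpha * x$geometry$rv))
  if (!is.null(x$beta)) cat(sprintf("  beta = %g\n", x$beta))
  if (!is.null(x$atom)) cat(sprintf("  point mass at x0 = %g\n", x$atom))
  cat(sprintf("  support: [%g, %g]\n", x$geometry$rv, x$geometry$lam / 2))
  invisible(x)
}

is_delta_family <- function(p) !is.null(p$atom)

# Normalizing constant of the unnormalized density on [rv, lam/2].
start_norm_const <- function(p) {
  rv <- p$geometry$rv; half <- p$geometry$lam / 2
  w <- half - rv
  switch(p$family,
    uniform = w,
    poisson_symmetric = ,
    poisson_asymmetric = {
      s <- p$alpha * rv
      s * (1 - exp(-w / s))
    },
    power_law = {
      b <- p$beta
      if (abs(b - 1) < 1e-12) log(half / rv)
      else (half^(1 - b) - rv^(1 - b)) / (1 - b)
    },
    stop("no normalizing constant for a point-mass family"))
}

#' Start-position density
#'
#' Normalized density of the restart position on the half-interval support
#' \eqn{[r_v, \lambda/2]}.  For the point-mass (delta) families the density
#' does not exist as a function; a symbolic atom marker of class
#' `"start_atom"` (fields `location`, `weight = 1`) is returned instead.
#'
#' @param p A [start_pdf()].
#' @param x0 Vector of positions, all inside the support.
#' @return Density values (1/length), or a `"start_atom"` marker for delta
#'   families.
#' @export
start_density <- function(p, x0) {
  stopifnot(inherits(p, "start_pdf"))
  if (is_delta_family(p))
    return(structure(list(location = p$atom, weight = 1),
                     class = "start_atom"))
  rv <- p$geometry$rv; half <- p$geometry$lam / 2
  tol <- 1e-9 * (half - rv)
  if (any(x0 < rv - tol) || any(x0 > half + tol))
    stop("positions outside the support [rv, lam/2] = [",
         rv, ", ", half, "]")
  x0 <- pmin(pmax(x0, rv), half)
  z <- start_norm_const(p)
  switch(p$family,
    uniform = rep(1 / z, length(x0)),
    poisson_symmetric = exp(-(half - x0) / (p$alpha * rv)) / z,
    poisson_asymmetric = exp(-(x0 - rv) / (p$alpha * rv)) / z,
    power_law = x0^(-p$beta) / z)
}

#' @export
print.start_atom <- function(x, ...) {
  cat(sprintf("point mass: weight %g at x0 = %g\n", x$weight, x$location))
  invisible(x)
}

# CDF on the support; used by sampling and by distributional tests.
start_cdf <- function(p, x0) {
  stopifnot(inherits(p, "start_pdf"))
  rv <- p$geometry$rv; half <- p$geometry$lam / 2
  x0 <- pmin(pmax(x0, rv), half)
  if (is_delta_family(p)) return(as.numeric(x0 >= p$atom))
  z <- start_norm_const(p)
  switch(p$family,
    uniform = (x0 - rv) / z,
    poisson_asymmetric = {
      s <- p$alpha * rv
      s * (1 - exp(-(x0 - rv) / s)) / z
    },
    poisson_symmetric = {
      s <- p$alpha * rv
      s * (exp(-(half - x0) / s) - exp(-(half - rv) / s)) / z
    },
    power_law = {
      b <- p$beta
      if (abs(b - 1) < 1e-12) log(x0 / rv) / z
      else (x0^(1 - b) - rv^(1 - b)) / (1 - b) / z
    })
}

#' Sample restart positions
#'
#' Draws from the normalized start-position density by inverse CDF (exact
#' for every continuous family; constant for the point masses), using the
#' global RNG.
#'
#' @param p A [start_pdf()].
#' @param n Number of draws.
#' @return Vector of `n` positions in \eqn{[r_v, \lambda/2]}.
#' @export
sample_start <- function(p, n = 1L) {
  stopifnot(inherits(p, "start_pdf"))
  if (is_delta_family(p)) return(rep(p$atom, n))
  rv <- p$geometry$rv; half <- p$geometry$lam / 2
  u <- runif(n)
  switch(p$family,
    uniform = rv + u * (half - rv),
    poisson_asymmetric = {
      s <- p$alpha * rv
      rv - s * log(1 - u * (1 - exp(-(half - rv) / s)))
    },
    poisson_symmetric = {
      s <- p$alpha * rv
      half + s * log(1 - u * (1 - exp(-(half - rv) / s)))
    },
    power_law = {
      b <- p$beta
      if (abs(b - 1) < 1e-12) rv * (half / rv)^u
      else (rv^(1 - b) + u * (half^(1 - b) - rv^(1 - b)))^(1 / (1 - b))
    })
}

#' Quadrature weights of a start-position pdf on a grid
#'
#' Trapezoidal weights of the normalized density on an ordered grid
#' covering the support \eqn{[r_v, \lambda/2]}, renormalized to sum
#' exactly to 1 so that averaging a constant is exact.  Point-mass
#' families put weight 1 on the grid node nearest the atom; it is an error
#' if that node is farther than half a grid cell from the atom.
#'
#' @param p A [start_pdf()].
#' @param grid Ordered vector of positions spanning the support.
#' @return Numeric weights, same length as `grid`, summing to 1.
#' @export
quadrature_weights <- function(p, grid) {
  stopifnot(inherits(p, "start_pdf"))
  n <- length(grid)
  if (n == 0L) stop("empty grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("'grid' must be strictly increasing")
  rv <- p$geometry$rv; half <- p$geometry$lam / 2
  span <- half - rv
  if (grid[1] > rv + 1e-8 * span || grid[n] < half - 1e-8 * span)
    stop("'grid' must cover the support [rv, lam/2]")
  if (is_delta_family(p)) {
    i <- which.min(abs(grid - p$atom))
    cell <- if (n > 1) stats::median(diff(grid)) else span
    if (abs(grid[i] - p$atom) > cell / 2 + 1e-12 * span)
      stop("no grid node within half a cell of the point mass at ", p$atom)
    w <- numeric(n)
    w[i] <- 1
    return(w)
  }
  f <- start_density(p, grid)
  # trapezoid: w_i = f_i * (x_{i+1} - x_{i-1})/2 with half cells at the ends
  h <- diff(grid)
  tw <- c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  if (n == 2L) tw <- c(h[1] / 2, h[1] / 2)
  w <- f * tw
  w / sum(w)
}
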