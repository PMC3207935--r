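#' Step-length distributions
#'
#' Constructors for the searcher's step-length laws.  All laws describe the
#' magnitude of a step; the direction (left/right) is drawn independently
#' with probability 1/2 each, see [sample_signed_step()].
#'
#' * `levy_steps(mu, ell0)`: truncated power law
#'   \eqn{p(\ell) = (\mu - 1)\,\ell_0^{\mu-1}\,\ell^{-\mu}} for
#'   \eqn{\ell \ge \ell_0}, zero below the cutoff.  For \eqn{1 < \mu \le 3}
#'   this is the long-range asymptotic form of a Levy stable law;
#'   \eqn{\mu \to 1} gives ballistic motion, \eqn{\mu \ge 3} Brownian-like
#'   diffusion.  `mu` must lie in `(1, 3]`.
#' * `exponential_steps(rate, ell0)`: shifted exponential
#'   \eqn{p(\ell) = \mathrm{rate}\, e^{-\mathrm{rate}(\ell-\ell_0)}} for
#'   \eqn{\ell \ge \ell_0} (a Poisson-like comparison model).
#' * `fixed_steps(ell)`: deterministic step of length `ell`.  A degenerate
#'   law used as a closed-form oracle: on a lattice it reduces the search
#'   to a gambler's-ruin problem.
#'
#' @param mu Power-law exponent, in `(1, 3]`.
#' @param ell0 Lower cutoff length, positive.
#' @param rate Inverse length scale of the exponential law, positive.
#' @param ell Deterministic step length, positive.
#'
#' @return An object of class `"step_distribution"` (and a subclass naming
#'   the family).
#' @examples
#' d <- levy_steps(mu = 2, ell0 = 1)
#' step_density(d, c(0.5, 1, 2))
#' @name step_models
NULL

#' @rdname step_models
#' @export
levy_steps <- function(mu, ell0 = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(ell0), length(ell0) == 1L, ell0 > 0)
  if (mu <= 1 || mu > 3)
    stop("'mu' must lie in (1, 3]: the power law is non-normalizable at mu <= 1 ",
         "and Brownian-like beyond mu = 3")
  structure(list(family = "levy", mu = mu, ell0 = ell0),
            class = c("levy_steps", "step_distribution"))
}

#' @rdname step_models
#' @export
exponential_steps <- function(rate, ell0 = 1) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0,
            is.numeric(ell0), length(ell0) == 1L, ell0 > 0)
  structure(list(family = "exponential", rate = rate, ell0 = ell0),
            class = c("exponential_steps", "step_distribution"))
}

#' @rdname step_models
#' @export
fixed_steps <- function(ell) {
  stopifnot(is.numeric(ell), length(ell) == 1L, ell > 0)
  structure(list(family = "fixed", ell = ell, ell0 = ell),
            class = c("fixed_steps", "step_distribution"))
}

#' @export
print.step_distribution <- function(x, ...) {
  cat("step-length distribution:", x$family, "\n")
  cat("  parameters:",
      paste(sprintf("%s = %g", setdiff(names(x), "family"),
                    unlist(x[setdiff(names(x), "family")])),
            collapse = ", "), "\n")
  invisible(x)
}

#' Step-length density
#'
#' Probability density of the step magnitude.  For the Levy family this is
#' \eqn{(\mu-1)\ell_0^{\mu-1} \ell^{-\mu}} on \eqn{[\ell_0, \infty)} and 0
#' below the cutoff.  The fixed-step law is a point mass and has no
#' density; requesting it is an error.
#'
#' @param d A `"step_distribution"`.
#' @param l Vector of nonnegative lengths.
#' @return Density values, same length as `l` (units 1/length).
#' @export
step_density <- function(d, l) UseMethod("step_density")

#' @export
step_density.levy_steps <- function(d, l) {
  stopifnot(all(l >= 0))
  ifelse(l >= d$ell0, (d$mu - 1) * d$ell0^(d$mu - 1) * l^(-d$mu), 0)
}

#' @export
step_density.exponential_steps <- function(d, l) {
  stopifnot(all(l >= 0))
  ifelse(l >= d$ell0, d$rate * exp(-d$rate * (l - d$ell0)), 0)
}

#' @export
step_density.fixed_steps <- function(d, l) {
  stop("the fixed-step law is a point mass at ell = ", d$ell,
       " and has no density")
}

#' Step-length survival function
#'
#' \eqn{P(\ell > l)} of the step magnitude.  Used for the closed-form cell
#' masses of the transition kernel and for tail (exceedance) checks.
#'
#' @inheritParams step_density
#' @return Survival probabilities in `[0, 1]`.
#' @export
step_ccdf <- function(d, l) UseMethod("step_ccdf")

#' @export
step_ccdf.levy_steps <- function(d, l) {
  ifelse(l <= d$ell0, 1, (l / d$ell0)^(1 - d$mu))
}

#' @export
step_ccdf.exponential_steps <- function(d, l) {
  ifelse(l <= d$ell0, 1, exp(-d$rate * (l - d$ell0)))
}

#' @export
step_ccdf.fixed_steps <- function(d, l) {
  as.numeric(l < d$ell)
}

#' Untruncated mean step length
#'
#' First moment of the magnitude law ignoring boundary truncation.
#' Infinite for the Levy family when `mu <= 2`.
#'
#' @param d A `"step_distribution"`.
#' @return A length, possibly `Inf`.
#' @export
step_mean <- function(d) UseMethod("step_mean")

#' @export
step_mean.levy_steps <- function(d) {
  if (d$mu > 2) (d$mu - 1) / (d$mu - 2) * d$ell0 else Inf
}

#' @export
step_mean.exponential_steps <- function(d) d$ell0 + 1 / d$rate

#' @export
step_mean.fixed_steps <- function(d) d$ell

# Expected travelled length of a single step in one direction when the
# detection threshold lies at distance dist: T(dist) = E[min(ell, dist)].
# Steps longer than dist are truncated at the threshold and contribute
# dist.  For dist < ell0 every step is truncated before covering ell0, so
# T(dist) = dist.
truncated_travel <- function(d, dist) UseMethod("truncated_travel")

#' @export
truncated_travel.levy_steps <- function(d, dist) {
  mu <- d$mu; l0 <- d$ell0
  out <- numeric(length(dist))
  below <- dist < l0
  out[below] <- dist[below]
  x <- dist[!below]
  if (length(x)) {
    if (abs(mu - 2) < 1e-9) {
      v <- l0 * (1 + log(x / l0))
      v[is.infinite(x)] <- Inf
    } else {
      # int_{l0}^{d} l p(l) dl + d P(l > d), closed forms of the power law
      v <- (mu - 1) * l0^(mu - 1) * (x^(2 - mu) - l0^(2 - mu)) / (2 - mu) +
        l0^(mu - 1) * x^(2 - mu)
      if (mu > 2) v[is.infinite(x)] <- (mu - 1) / (mu - 2) * l0
      else v[is.infinite(x)] <- Inf
    }
    out[!below] <- v
  }
  out
}

#' @export
truncated_travel.exponential_steps <- function(d, dist) {
  l0 <- d$ell0; r <- d$rate
  ifelse(dist < l0, dist, l0 + (1 - exp(-r * (dist - l0))) / r)
}

#' @export
truncated_travel.fixed_steps <- function(d, dist) pmin(dist, d$ell)

#' Mean length of a single boundary-truncated step
#'
#' Expected travelled distance of one signed step taken from a position
#' whose detection thresholds lie at distances `d_left` and `d_right`.
#' With equal probability 1/2 the step goes either way, and a step whose
#' magnitude exceeds the distance to the threshold in its direction is
#' truncated there, contributing only the distance up to the threshold:
#' \deqn{\langle|\ell|\rangle = \tfrac12 T(d_{left}) + \tfrac12 T(d_{right}),
#'   \quad T(d) = \int_{\ell_0}^{d} \ell\,p(\ell)\,d\ell +
#'   d \int_{d}^{\infty} p(\ell)\,d\ell,}
#' with \eqn{T(d) = d} for \eqn{d < \ell_0} (any step is cut before
#' covering the cutoff length).  Closed forms are used for all three step
#' families.
#'
#' @param d_left,d_right Nonnegative distances from the current position to
#'   the left and right detection thresholds.  `Inf` is allowed.
#' @param d A `"step_distribution"`.
#' @return Expected travelled length (scalar if both distances are scalar).
#' @examples
#' truncated_step_mean(1, 1, levy_steps(mu = 2, ell0 = 1))   # exactly ell0
#' @export
truncated_step_mean <- function(d_left, d_right, d) {
  if (any(d_left < 0) || any(d_right < 0))
    stop("distances to the detection thresholds must be nonnegative")
  0.5 * truncated_travel(d, d_left) + 0.5 * truncated_travel(d, d_right)
}

#' Sample step magnitudes
#'
#' Draws `n` magnitudes from the step-length law using the global RNG.
#' The Levy family uses the inverse CDF \eqn{\ell_0 u^{-1/(\mu-1)}} with
#' `u` uniform on (0, 1] (open at 0, so steps are finite).
#'
#' @param d A `"step_distribution"`.
#' @param n Number of draws.
#' @return Vector of `n` positive lengths.
#' @export
sample_step_magnitude <- function(d, n) UseMethod("sample_step_magnitude")

#' @export
sample_step_magnitude.levy_steps <- function(d, n) {
  u <- runif(n)  # in (0,1): excludes both endpoints, no infinite steps
  d$ell0 * u^(-1 / (d$mu - 1))
}

#' @export
sample_step_magnitude.exponential_steps <- function(d, n) {
  d$ell0 + rexp(n, rate = d$rate)
}

#' @export
sample_step_magnitude.fixed_steps <- function(d, n) rep(d$ell, n)

#' Sample signed steps
#'
#' Magnitude from the step law, sign -1/+1 with probability 1/2 each,
#' independent of the magnitude.
#'
#' @inheritParams sample_step_magnitude
#' @return Vector of `n` signed lengths.
#' @export
sample_signed_step <- function(d, n = 1L) {
  s <- ifelse(runif(n) < 0.5, -1, 1)
  s * sample_step_magnitude(d, n)
}
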