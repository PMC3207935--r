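# Independent oracles used across the suite.  These deliberately avoid the
# package's closed forms: travel moments by direct numerical quadrature of
# the defining integrals, absorption quantities by exact linear algebra on
# the lattice chain.

# E[min(ell, d)] for the truncated power law, by quadrature of
# int_{l0}^{d} l p(l) dl + d int_{d}^{inf} p(l) dl with p written inline.
oracle_levy_travel <- function(mu, ell0, d) {
  if (d < ell0) return(d)
  p <- function(l) (mu - 1) * ell0^(mu - 1) * l^(-mu)
  body <- integrate(function(l) l * p(l), ell0, d, rel.tol = 1e-12)$value
  tail <- integrate(p, d, Inf, rel.tol = 1e-12)$value
  body + d * tail
}

# Expected number of steps to absorption for the symmetric +-1 lattice walk
# started a cells from the left absorbing state of a row of a + b cells,
# by exact solve of the first-step equations (the gambler's-ruin chain).
oracle_ruin_steps <- function(a, b) {
  n <- a + b - 1                       # transient states 1 .. a+b-1
  A <- diag(n)
  for (i in seq_len(n)) {
    if (i > 1) A[i, i - 1] <- A[i, i - 1] - 0.5
    if (i < n) A[i, i + 1] <- A[i, i + 1] - 0.5
  }
  solve(A, rep(1, n))[a]
}

# Standard error of a Monte Carlo mean-distance estimate.
mc_se <- function(outcome) {
  stopifnot(!is.null(outcome$encounters))
  stats::sd(outcome$encounters$distance) / sqrt(outcome$n_targets)
}

small_geometry <- function() search_geometry(lam = 50, rv = 1)
study_geometry <- function() search_geometry(lam = 1000, rv = 1)
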