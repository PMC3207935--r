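#' Search geometry: interval, radius of vision, step cutoff
#'
#' Defines all length scales of the 1D search problem.  The two targets sit
#' at positions 0 and \code{lam}; a target is detected as soon as the
#' searcher comes within \code{rv} of it, so the search proceeds while the
#' position lies in \code{[rv, lam - rv]}.  \code{ell0} is the lower cutoff
#' of the step-length law and defaults to \code{rv}.
#'
#' The model's domain is the low target-density regime \code{lam/rv >> 1};
#' a warning is issued when \code{lam/rv < 10}.
#'
#' @param lam Interval length (distance between the two boundary targets).
#' @param rv Radius of vision; must satisfy \code{0 < 2*rv < lam}.
#' @param ell0 Lower cutoff of step lengths; defaults to \code{rv}.
#'
#' @return An object of class \code{"search_geometry"}.
#' @examples
#' g <- search_geometry(lam = 1000, rv = 1)
#' @export
search_geometry <- function(lam, rv, ell0 = rv) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam),
            is.numeric(rv), length(rv) == 1L, is.finite(rv),
            is.numeric(ell0), length(ell0) == 1L, is.finite(ell0))
  if (rv <= 0) stop("'rv' must be positive")
  if (ell0 <= 0) stop("'ell0' must be positive")
  if (lam <= 2 * rv) stop("'lam' must exceed 2*rv (targets must be farther apart than twice the radius of vision)")
  if (lam / rv < 10)
    warning("lam/rv < 10: outside the low-density regime the model is built for")
  structure(list(lam = lam, rv = rv, ell0 = ell0),
            class = "search_geometry")
}

#' @export
print.search_geometry <- function(x, ...) {
  cat("1D search geometry\n")
  cat(sprintf("  interval length lam : %g\n", x$lam))
  cat(sprintf("  radius of vision rv : %g\n", x$rv))
  cat(sprintf("  step cutoff ell0    : %g\n", x$ell0))
  cat(sprintf("  scarcity ratio lam/rv: %g\n", x$lam / x$rv))
  invisible(x)
}

is_search_geometry <- function(x) inherits(x, "search_geometry")

same_geometry <- function(a, b, tol = 1e-12) {
  abs(a$lam - b$lam) <= tol * a$lam &&
    abs(a$rv - b$rv) <= tol * a$rv &&
    abs(a$ell0 - b$ell0) <= tol * a$ell0
}
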