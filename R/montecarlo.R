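#' Monte Carlo simulation of the search process
#'
#' Simulates the full search: each encounter starts at a position drawn
#' from the start-position pdf, then the searcher takes signed steps drawn
#' from the step-length law until the path crosses a detection threshold
#' (the step is truncated there and only the travelled part counts), at
#' which point the search resets.  This simulator is an independent check
#' of the deterministic solver — it shares no code with the
#' integral-operator path — and is the only estimator of step-level
#' diagnostics such as the truncated-step fraction.
#'
#' Randomness comes from a single seeded stream: the restart positions are
#' drawn first, then the step sequence of each encounter, so one `seed`
#' reproduces the outcome exactly.
#'
#' @param geometry A [search_geometry()].
#' @param d A `"step_distribution"`.
#' @param p A [start_pdf()] on the same geometry.
#' @param n_targets Number of encounters to simulate (at least 1).
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param per_encounter If `TRUE`, also return a per-encounter data frame
#'   (columns `encounter`, `x0`, `distance`, `steps`).
#' @param max_steps_per_encounter Hard cap guarding pathological
#'   parameterizations; exceeding it is an error, never silent censoring.
#' @return Object of class `"search_outcome"`: tallies `n_targets`,
#'   `total_distance`, `n_steps`, `n_truncated`, the `seed`, and
#'   optionally `$encounters`.
#' @examples
#' g <- search_geometry(lam = 50, rv = 1)
#' o <- run_search(g, levy_steps(2, 1), start_pdf("delta_symmetric", g),
#'                 n_targets = 100, seed = 1)
#' estimate_efficiency(o)
#' @export
run_search <- function(geometry, d, p, n_targets, seed = NULL,
                       per_encounter = FALSE,
                       max_steps_per_encounter = 1e8) {
  stopifnot(is_search_geometry(geometry), inherits(d, "step_distribution"),
            inherits(p, "start_pdf"))
  if (!same_geometry(geometry, p$geometry))
    stop("start pdf was built for a different geometry")
  if (!is.numeric(n_targets) || length(n_targets) != 1L || n_targets < 1 ||
      n_targets != round(n_targets))
    stop("'n_targets' must be a positive integer")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  starts <- sample_start(p, n_targets)
  args <- switch(d$family,
    levy = list(type = 1L, p1 = d$mu, p2 = d$ell0),
    fixed = list(type = 2L, p1 = d$ell, p2 = 0),
    exponential = list(type = 3L, p1 = d$rate, p2 = d$ell0))
  res <- cpp_run_search(geometry$lam, geometry$rv, args$type, args$p1, args$p2,
                        starts, max_steps_per_encounter, per_encounter)
  out <- list(n_targets = as.integer(n_targets),
              total_distance = res$total_distance,
              n_steps = res$n_steps,
              n_truncated = res$n_truncated,
              seed = seed, geometry = geometry, step = d, start = p)
  if (per_encounter)
    out$encounters <- data.frame(encounter = seq_len(n_targets),
                                 x0 = starts,
                                 distance = res$encounter_distance,
                                 steps = res$encounter_steps)
  structure(out, class = "search_outcome")
}

#' @export
print.search_outcome <- function(x, ...) {
  cat("Monte Carlo search outcome\n")
  cat(sprintf("  encounters      : %d\n", x$n_targets))
  cat(sprintf("  total distance  : %.6g\n", x$total_distance))
  cat(sprintf("  steps (truncated): %.0f (%.0f)\n", x$n_steps, x$n_truncated))
  cat(sprintf("  efficiency      : %.6g\n", estimate_efficiency(x)))
  invisible(x)
}

#' Efficiency estimate from a simulated search
#'
#' The defining ratio: targets found per unit distance travelled.
#'
#' @param o A `"search_outcome"`.
#' @return `n_targets / total_distance` (1/length).
#' @export
estimate_efficiency <- function(o) {
  stopifnot(inherits(o, "search_outcome"))
  if (o$total_distance <= 0) stop("zero total distance")
  o$n_targets / o$total_distance
}

#' Fraction of steps truncated by target detection
#'
#' Each encounter ends exactly one truncated step, so this ratio equals
#' the inverse of the mean number of steps per encounter.  In the
#' low-density regime it is small except for near-ballistic strategies.
#'
#' @param o A `"search_outcome"`.
#' @return `n_truncated / n_steps`, in (0, 1].
#' @export
truncated_fraction <- function(o) {
  stopifnot(inherits(o, "search_outcome"))
  if (o$n_steps < 1) stop("no steps taken")
  o$n_truncated / o$n_steps
}
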