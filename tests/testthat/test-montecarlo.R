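test_that("tallies satisfy their defining identities", {
  g <- small_geometry()
  o <- run_search(g, levy_steps(2, 1), start_pdf("uniform", g),
                  n_targets = 500, seed = 3, per_encounter = TRUE)
  expect_equal(o$n_truncated, o$n_targets)   # each encounter ends one cut step
  expect_lte(o$n_truncated, o$n_steps)
  expect_gt(o$total_distance, 0)
  expect_equal(sum(o$encounters$distance), o$total_distance)
  expect_equal(sum(o$encounters$steps), o$n_steps)
  expect_equal(truncated_fraction(o), o$n_targets / o$n_steps)
  expect_true(all(o$encounters$x0 >= g$rv & o$encounters$x0 <= g$lam / 2))
})

test_that("the same seed reproduces the outcome exactly", {
  g <- small_geometry()
  o1 <- run_search(g, levy_steps(1.5, 1), start_pdf("poisson_asymmetric", g, alpha = 2),
                   n_targets = 200, seed = 99, per_encounter = TRUE)
  o2 <- run_search(g, levy_steps(1.5, 1), start_pdf("poisson_asymmetric", g, alpha = 2),
                   n_targets = 200, seed = 99, per_encounter = TRUE)
  expect_identical(o1$total_distance, o2$total_distance)
  expect_identical(o1$encounters, o2$encounters)
})

test_that("a step spanning the interval is always truncated", {
  g <- search_geometry(lam = 50, rv = 1)
  o <- run_search(g, fixed_steps(50), start_pdf("uniform", g),
                  n_targets = 300, seed = 5)
  expect_equal(o$n_steps, 300)
  expect_equal(truncated_fraction(o), 1)
  # from the exact midpoint the one deterministic flight travels lam/2 - rv
  om <- run_search(g, fixed_steps(50), start_pdf("delta_symmetric", g),
                   n_targets = 50, seed = 6)
  expect_equal(estimate_efficiency(om), 1 / (g$lam / 2 - g$rv))
})

test_that("efficiency is the encounter-per-distance ratio", {
  o <- structure(list(n_targets = 10L, total_distance = 50, n_steps = 40,
                      n_truncated = 10), class = "search_outcome")
  expect_equal(estimate_efficiency(o), 0.2)
  expect_equal(truncated_fraction(o), 0.25)
})

test_that("lattice walkers take the gambler's-ruin number of steps", {
  a <- 3; b <- 7
  g <- search_geometry(lam = a + b + 2, rv = 1)
  o <- run_search(g, fixed_steps(1), start_pdf("delta", g, x0 = 1 + a),
                  n_targets = 1e4, seed = 17, per_encounter = TRUE)
  se <- sd(o$encounters$steps) / sqrt(o$n_targets)
  expect_lt(abs(mean(o$encounters$steps) - oracle_ruin_steps(a, b)), 3 * se)
  expect_equal(oracle_ruin_steps(a, b), a * b, tolerance = 1e-12)
})

test_that("simulated mean distances match the deterministic solver", {
  g <- small_geometry()
  for (mu in c(1.5, 2.5)) {
    prof <- solve_mean_distance(g, levy_steps(mu, 1))
    for (fam in c("delta_symmetric", "delta_asymmetric")) {
      o <- run_search(g, levy_steps(mu, 1), start_pdf(fam, g),
                      n_targets = 5e3, seed = round(mu * 100), per_encounter = TRUE)
      D_ref <- 1 / average_efficiency(prof, start_pdf(fam, g))
      expect_lt(abs(mean(o$encounters$distance) - D_ref), 3 * mc_se(o))
    }
  }
})

test_that("randomized-start efficiency matches the averaged functional", {
  # the simulator estimates encounters / total distance, i.e. the
  # inverse-mean reading of the averaged efficiency
  g <- study_geometry()
  for (mu in c(1.5, 2.5)) {
    prof <- solve_mean_distance(g, levy_steps(mu, 1))
    for (a in c(1, 100)) {
      p <- start_pdf("poisson_asymmetric", g, alpha = a)
      o <- run_search(g, levy_steps(mu, 1), p, n_targets = 5e3,
                      seed = round(mu * 1000 + a), per_encounter = TRUE)
      eta_mc <- estimate_efficiency(o)
      eta_q <- average_efficiency(prof, p, mode = "inverse_mean")
      # delta-method SE of the ratio estimator
      se <- eta_mc * mc_se(o) / mean(o$encounters$distance)
      expect_lt(abs(eta_mc - eta_q), 3 * se)
    }
  }
})

test_that("near-ballistic walks truncate most steps, diffusive ones few", {
  g <- study_geometry()
  p <- start_pdf("delta_asymmetric", g)
  f15 <- truncated_fraction(run_search(g, levy_steps(1.5, 1), p, 400, seed = 31))
  f30 <- truncated_fraction(run_search(g, levy_steps(3, 1), p, 400, seed = 32))
  expect_gt(f15, f30)
  psym <- start_pdf("delta_symmetric", g)
  f20 <- truncated_fraction(run_search(g, levy_steps(2, 1), psym, 400, seed = 33))
  expect_lt(f20, 0.1)
})

test_that("the estimator's error shrinks like one over root n", {
  g <- small_geometry()
  p <- start_pdf("delta_symmetric", g)
  o1 <- run_search(g, levy_steps(2.5, 1), p, 2000, seed = 41, per_encounter = TRUE)
  o2 <- run_search(g, levy_steps(2.5, 1), p, 8000, seed = 41, per_encounter = TRUE)
  ratio <- mc_se(o1) / mc_se(o2)
  expect_gt(ratio, 1.4)   # fourfold n: expect about 2
  expect_lt(ratio, 2.9)
})

test_that("invalid inputs are rejected and the step cap is an error", {
  g <- small_geometry()
  expect_error(run_search(g, levy_steps(2, 1), start_pdf("uniform", g), 0),
               "n_targets")
  expect_error(run_search(g, levy_steps(3, 1), start_pdf("delta_symmetric", g),
                          n_targets = 10, seed = 8,
                          max_steps_per_encounter = 5),
               "step cap")
})
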