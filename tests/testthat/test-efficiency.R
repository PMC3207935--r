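# Profiles at the study scale are reused across blocks; solving them once
# here keeps the file fast.
study_profiles <- local({
  g <- search_geometry(lam = 1000, rv = 1)
  mus <- default_mu_grid()
  list(geometry = g, mus = mus,
       profiles = lapply(mus, function(m) solve_mean_distance(g, levy_steps(m, 1))))
})

test_that("averaged efficiency reduces exactly for point masses and constants", {
  g <- small_geometry()
  prof <- solve_mean_distance(g, levy_steps(2, 1))
  eta_sym <- average_efficiency(prof, start_pdf("delta_symmetric", g))
  expect_equal(eta_sym, 1 / prof$D[prof$nodes == g$lam / 2])
  eta_asym <- average_efficiency(prof, start_pdf("delta_asymmetric", g))
  expect_equal(eta_asym, 1 / prof$D[1])
  # constant mean distance: any normalized weighting gives 1/c in both modes
  flat <- prof; flat$D[] <- 3.7
  for (p in list(start_pdf("uniform", g),
                 start_pdf("poisson_asymmetric", g, alpha = 2)))
    for (mode in c("mean_inverse", "inverse_mean"))
      expect_equal(average_efficiency(flat, p, mode = mode), 1 / 3.7)
})

test_that("uniform weighting lies strictly between the endpoint efficiencies", {
  g <- small_geometry()
  prof <- solve_mean_distance(g, levy_steps(2, 1))
  eta <- average_efficiency(prof, start_pdf("uniform", g))
  half_D <- prof$D[prof$nodes <= g$lam / 2]
  expect_gt(eta, 1 / max(half_D))
  expect_lt(eta, 1 / min(half_D))
  # averaging 1/D exceeds 1/average D (Jensen)
  expect_gt(eta, average_efficiency(prof, start_pdf("uniform", g),
                                    mode = "inverse_mean"))
})

test_that("the surrogate reproduces its nodes and interpolates accurately", {
  s <- fit_surrogate(study_profiles$profiles)
  g <- study_profiles$geometry
  for (i in c(1, 6, 21)) {
    prof <- study_profiles$profiles[[i]]
    expect_equal(surrogate_profile(s, study_profiles$mus[i])$D, prof$D,
                 tolerance = 1e-12)
  }
  # inherited mirror symmetry at an off-node exponent
  D <- surrogate_profile(s, 1.77)$D
  expect_lt(max(abs(D - rev(D)) / D), 1e-6)
  # leave-one-out at interior exponent nodes: relative error < 2%
  for (i in c(5, 11, 16)) {
    s_loo <- fit_surrogate(study_profiles$profiles[-i])
    D_hat <- surrogate_profile(s_loo, study_profiles$mus[i])$D
    D_ref <- study_profiles$profiles[[i]]$D
    expect_lt(max(abs(D_hat - D_ref) / D_ref), 0.02)
  }
  expect_error(fit_surrogate(study_profiles$profiles[1:3]), ">= 5")
})

test_that("surrogate optima match exact per-exponent solves", {
  s <- fit_surrogate(study_profiles$profiles)
  g <- study_profiles$geometry
  for (p in list(start_pdf("delta_asymmetric", g),
                 start_pdf("poisson_asymmetric", g, alpha = 10))) {
    opt <- optimal_mu(p, s)
    # 10-point exact spot check, 0.05 apart, centred on the surrogate optimum
    mus <- seq(opt$mu_opt - 0.25, opt$mu_opt + 0.2, by = 0.05)
    mus <- mus[mus >= mu_domain()[1] & mus <= mu_domain()[2]]
    eta <- vapply(mus, function(m)
      average_efficiency(solve_mean_distance(g, levy_steps(m, 1)), p),
      numeric(1))
    expect_lt(abs(mus[which.max(eta)] - opt$mu_opt), 0.05 + 1e-9)
  }
})

test_that("stronger nearby-target fluctuations never raise the efficiency", {
  s <- fit_surrogate(study_profiles$profiles)
  g <- study_profiles$geometry
  for (mu in c(1.5, 2, 2.5)) {
    prof <- surrogate_profile(s, mu)
    eta <- vapply(c(0.1, 1, 10, 100, 1000), function(a)
      average_efficiency(prof, start_pdf("poisson_asymmetric", g, alpha = a)),
      numeric(1))
    expect_true(all(diff(eta) <= 1e-12))
  }
})

test_that("efficiency is invariant under a common rescaling of all lengths", {
  k <- 7
  g1 <- search_geometry(lam = 100, rv = 1)
  g2 <- search_geometry(lam = 100 * k, rv = k)
  for (mu in c(1.5, 2.5)) {
    p1 <- solve_mean_distance(g1, levy_steps(mu, g1$ell0))
    p2 <- solve_mean_distance(g2, levy_steps(mu, g2$ell0))
    e1 <- average_efficiency(p1, start_pdf("poisson_asymmetric", g1, alpha = 5))
    e2 <- average_efficiency(p2, start_pdf("poisson_asymmetric", g2, alpha = 5))
    expect_equal(e1, k * e2, tolerance = 1e-9)
  }
})

test_that("crossover search reports both endpoint states when there is none", {
  s <- fit_surrogate(study_profiles$profiles)
  expect_error(crossover_alpha("poisson_symmetric", s, c(0.1, 100)),
               "at_boundary is TRUE.*TRUE")
})
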