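test_that("continuous start densities normalize on the half-interval", {
  g <- search_geometry(lam = 100, rv = 1)
  fams <- list()
  for (a in c(0.1, 1, 10, 1e3))
    fams <- c(fams, list(start_pdf("poisson_symmetric", g, alpha = a),
                         start_pdf("poisson_asymmetric", g, alpha = a)))
  for (b in c(0.5, 1, 2))
    fams <- c(fams, list(start_pdf("power_law", g, beta = b)))
  fams <- c(fams, list(start_pdf("uniform", g)))
  for (p in fams) {
    mass <- integrate(function(x) start_density(p, x), g$rv, g$lam / 2,
                      rel.tol = 1e-10)$value
    expect_lt(abs(mass - 1), 1e-6)
    expect_true(all(start_density(p, seq(g$rv, g$lam / 2, length.out = 7)) >= 0))
  }
})

test_that("density values match the stated families", {
  g <- search_geometry(lam = 100, rv = 1)
  u <- start_pdf("uniform", g)
  expect_equal(start_density(u, c(5, 49)), rep(1 / 49, 2))
  pa <- start_pdf("poisson_asymmetric", g, alpha = 2)
  # decay length alpha * rv: density drops by e over one decay length
  r <- start_density(pa, g$rv) / start_density(pa, g$rv + 2 * g$rv)
  expect_equal(r, exp(1), tolerance = 1e-12)
  ps <- start_pdf("poisson_symmetric", g, alpha = 2)
  expect_equal(start_density(ps, g$lam / 2) / start_density(ps, g$lam / 2 - 2),
               exp(1), tolerance = 1e-12)
  expect_error(start_density(u, 0.5), "support")
  atom <- start_density(start_pdf("delta_symmetric", g), 10)
  expect_s3_class(atom, "start_atom")
  expect_equal(atom$location, 50)
  expect_equal(atom$weight, 1)
})

test_that("quadrature weights are a normalized trapezoid of the density", {
  g <- search_geometry(lam = 100, rv = 1)
  grid <- seq(g$rv, g$lam / 2, by = 1)
  w <- quadrature_weights(start_pdf("uniform", g), grid)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(max(w[-c(1, length(w))]), min(w[-c(1, length(w))]))
  expect_equal(w[1], w[2] / 2)
  # point masses collapse to the nearest node
  wd <- quadrature_weights(start_pdf("delta_symmetric", g), grid)
  expect_equal(wd[grid == 50], 1)
  expect_equal(sum(wd), 1)
  expect_error(quadrature_weights(start_pdf("delta", g, x0 = 10.6), grid[grid != 11]),
               "half a cell")
  # alpha -> 0 limit of the nearby-target family piles weight on rv
  w0 <- quadrature_weights(start_pdf("poisson_asymmetric", g, alpha = 1e-3), grid)
  expect_gte(w0[1], 0.999)
})

test_that("the Poisson-like family interpolates delta and uniform limits", {
  g <- search_geometry(lam = 100, rv = 1)
  grid <- seq(g$rv, g$lam / 2, by = 0.5)
  unif <- start_density(start_pdf("uniform", g), grid)
  sup <- vapply(c(1e3, 1e4, 1e5), function(a)
    max(abs(start_density(start_pdf("poisson_asymmetric", g, alpha = a), grid) -
              unif)), numeric(1))
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 1e-3 * unif[1])
})

test_that("sampling agrees with the density", {
  g <- search_geometry(lam = 100, rv = 1)
  set.seed(21)
  n <- 1e5
  expect_equal(sample_start(start_pdf("delta_asymmetric", g), 5), rep(1, 5))
  xu <- sample_start(start_pdf("uniform", g), n)
  expect_true(all(xu >= g$rv & xu <= g$lam / 2))
  se_u <- (g$lam / 2 - g$rv) / sqrt(12 * n)
  expect_lt(abs(mean(xu) - (g$rv + g$lam / 2) / 2), 3 * se_u)
  # truncated-exponential mean of the nearby-target family, alpha = 1
  pa <- start_pdf("poisson_asymmetric", g, alpha = 1)
  xa <- sample_start(pa, n)
  s <- 1 * g$rv; w <- g$lam / 2 - g$rv
  m_exact <- g$rv + s - w * exp(-w / s) / (1 - exp(-w / s))
  expect_lt(abs(mean(xa) - m_exact), 3 * sd(xa) / sqrt(n))
  # Kolmogorov-Smirnov distance against the model CDF
  for (p in list(pa, start_pdf("poisson_symmetric", g, alpha = 5),
                 start_pdf("power_law", g, beta = 1))) {
    x <- sample_start(p, n)
    ks <- max(abs(ecdf(x)(sort(x)) - levysearch:::start_cdf(p, sort(x))))
    expect_lt(ks, 0.01)
  }
})

test_that("constructor validates family parameters", {
  g <- search_geometry(lam = 100, rv = 1)
  expect_error(start_pdf("poisson_asymmetric", g), "alpha")
  expect_error(start_pdf("uniform", g, alpha = 1), "alpha")
  expect_error(start_pdf("power_law", g), "beta")
  expect_error(start_pdf("delta", g, x0 = 60), "support")
})
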