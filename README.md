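# levysearch

Optimal Lévy search strategies in heterogeneous one-dimensional landscapes.

## The problem

A random searcher (a forager, a protein scanning DNA, a predator in a prey
field) looks for sparse targets it cannot sense beyond a short *radius of
vision* r_v. A classical idealization places the two nearest targets at the
ends of an interval of length λ ≫ r_v; the searcher takes steps of random
length and direction, a step ends early if its path brings a target within
r_v (the step is *truncated* at the detection threshold), and after every
encounter the search restarts. The searcher's step lengths follow a
truncated power law

p(ℓ) = (μ − 1) ℓ₀^(μ−1) ℓ^(−μ),  ℓ ≥ ℓ₀,

the Lévy-flight family: μ → 1 is ballistic (straight-line-like) motion,
μ ≥ 3 is Brownian-like diffusion, and intermediate μ are superdiffusive.

Classically two restart conventions are studied: *non-destructive* search
(restart at x₀ = r_v, next to the last target found) with optimum μ ≈ 2,
and *destructive* search (restart at x₀ = λ/2, equidistant from all
targets) with a ballistic optimum. Real landscapes are neither: patchiness
makes the searcher's initial distances to nearby and faraway targets
*fluctuate*. This package models that heterogeneity by drawing the restart
position x₀ from a density π(x₀) — a point mass, an exponential
(Poisson-like) law of width α·r_v decaying from either reference point, a
uniform law, or a scale-free power law — and asks how the optimal exponent
μ_opt moves as the fluctuations widen.

## What the package computes

* **⟨D(x₀)⟩**, the mean distance travelled between consecutive encounters,
  by discretizing the integral-operator (Fredholm) identity
  D = m + K D, where m(x₀) is the mean length of a single
  boundary-truncated step and K the kernel of survival (non-truncated)
  transitions, with closed-form power-law cell masses
  (`solve_mean_distance`).
* **⟨η⟩ = ∫ π(x₀) / ⟨D(x₀)⟩ dx₀**, the fluctuation-averaged search
  efficiency (`average_efficiency`), evaluated through a smooth
  tensor-spline surrogate of log ⟨D(x₀; μ)⟩ (`fit_surrogate`).
* **μ_opt(π)**, the efficiency-maximizing exponent on the admissible
  domain μ ∈ [1.01, 3] (`optimal_mu`, `optimal_mu_curve`), and
  **α_c**, the fluctuation strength at which the optimum crosses over from
  a superdiffusive compromise to the ballistic clamp (`crossover_alpha`).
* **Monte Carlo simulation** of the full search process (`run_search`), an
  independent oracle for the solver and the only estimator of step-level
  diagnostics such as the truncated-step fraction.

## Worked example

```r
library(levysearch)

g <- search_geometry(lam = 1000, rv = 1)          # low density: lam/rv = 1000
mu_grid <- default_mu_grid()
profiles <- lapply(mu_grid, function(m) solve_mean_distance(g, levy_steps(m, g$ell0)))
s <- fit_surrogate(profiles)

optimal_mu(start_pdf("delta_asymmetric", g), s)
#> optimal Levy exponent for start pdf 'delta_asymmetric'
#>   mu_opt = 1.916   eta_max = 0.00706589   [interior optimum]

optimal_mu(start_pdf("poisson_asymmetric", g, alpha = 100), s)
#> optimal Levy exponent for start pdf 'poisson_asymmetric' (alpha = 100)
#>   mu_opt = 1.251   eta_max = 0.00206653   [interior optimum]

crossover_alpha("poisson_asymmetric", s, c(1, 1000))$alpha_c
#> [1] 145.2477
```

Read: with restarts pinned next to the last-found target the best strategy
is the classical superdiffusive compromise μ_opt ≈ 1.92; widening the
fluctuations of the nearby-target distance (α = 100) pushes the optimum to
much faster motion (μ_opt ≈ 1.25, efficiency down by ×3.4); beyond
α_c ≈ 145 the optimum sits on the ballistic clamp μ = 1.01.

The Monte Carlo oracle agrees with the deterministic solver:

```r
o <- run_search(g, levy_steps(mu = 2, ell0 = 1), start_pdf("delta_symmetric", g),
                n_targets = 2000, seed = 1)
estimate_efficiency(o)                            # 0.000433777
1 / profile_at(profiles[[11]], 500)               # 0.000442883  (mu = 2 solve)
```

Both numbers are encounters per unit distance for destructive search at
μ = 2; they differ by ~1 Monte Carlo standard error.

A command-line interface wrapping these functions is installed at
`inst/cli/levysearch.R` (subcommands `solve`, `simulate`, `sweep`,
`optimize`, `crossover`, `fixtures`); run it with
`Rscript $(Rscript -e 'cat(system.file("cli/levysearch.R", package="levysearch"))') solve --lam 1000 --rv 1 --mu 2 --out profile.csv`.

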