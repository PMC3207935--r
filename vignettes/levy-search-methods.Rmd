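---
title: "Methods: mean encounter distance, averaged efficiency and optimal Lévy exponents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean encounter distance, averaged efficiency and optimal Lévy exponents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levysearch)
```

## The model

The search space is the interval $[0, \lambda]$ with a target at each end.
The searcher has a radius of vision $r_v$: a target is detected as soon as
the searcher's position comes within $r_v$ of it, so the *live* interval is
$[r_v, \lambda - r_v]$. Steps are signed: a magnitude drawn from the
step-length law, a direction left/right with probability $1/2$ each. If a
step's path reaches a detection threshold the step is *truncated* there —
only the distance up to the threshold is travelled — and an encounter is
scored; the search then restarts at a position drawn from the
start-position density $\pi(x_0)$. The model's domain is the low-density
regime $\lambda / r_v \gg 1$; `search_geometry()` warns below
$\lambda/r_v = 10$.

The step law of interest is the truncated power law
$p(\ell) = (\mu - 1)\,\ell_0^{\mu-1}\,\ell^{-\mu}$ on
$[\ell_0, \infty)$, the long-range asymptotic form of a Lévy stable law.
It is non-normalizable at $\mu \le 1$, so the admissible exponent domain
is clamped to $[1 + 0.01,\; 3]$ (`mu_domain()`): "ballistic" is
operationally an optimum on the lower clamp. The cutoff defaults to
$\ell_0 = r_v$, the model's natural microscale; both can be set
independently. A shifted-exponential law (Poisson-like comparison searcher)
and a deterministic fixed-step law (closed-form test oracle) complete the
family.

Landscape heterogeneity enters only through $\pi(x_0)$. Because a search
from $x_0$ is statistically identical to one from $\lambda - x_0$, all
start densities are defined and normalized on the half-interval
$[r_v, \lambda/2]$. The families are point masses at $\lambda/2$
(destructive limit), at $r_v$ (non-destructive limit) or at arbitrary
$x_0$; exponential laws of decay length $\sigma = \alpha\, r_v$ attached
to either reference point (the dimensionless $\alpha$ is the fluctuation
width; the proportionality constant between $\sigma$ and $r_v$ is a
modelling choice — only the product matters and $r_v$ is the natural
unit); the uniform law (the $\alpha \to \infty$ limit of both); and a
power law $\pi \propto x_0^{-\beta}$ with no offset in the argument
(the simplest scale-free convention).

## Mean distance between encounters

For a start at $x_0$, the mean distance travelled until detection obeys
the linear integral identity
$$\langle D(x_0)\rangle \;=\; m(x_0) \;+\; \int K(x_0, x)\,
  \langle D(x)\rangle\, dx,$$
where $m(x_0)$ is the expected travelled length of one truncated step,
$$m(x_0) = \tfrac12 T(x_0 - r_v) + \tfrac12 T(\lambda - r_v - x_0),
  \qquad T(d) = \int_{\ell_0}^{d}\!\ell\, p(\ell)\,d\ell
  + d \int_{d}^{\infty}\! p(\ell)\, d\ell,$$
and $K$ carries the probability of surviving (non-truncated) transitions.
$T(d) = d$ for $d < \ell_0$: a step launched closer to a threshold than
the cutoff is necessarily cut before covering $\ell_0$. Closed forms of
$T$ are implemented for all three step families (`truncated_step_mean`)
and are verified against direct quadrature of the defining integrals to
$10^{-8}$ relative in the test suite.

### Discretization

`solver_grid()` places uniform nodes of spacing $\Delta \le r_v$ (default
$\Delta = r_v$) from $r_v$ to $\lambda - r_v$; cells are the
midpoint-bounded intervals around each node, with half-cells at the two
thresholds. The kernel entry $(i, j)$ is the *exact* mass of the step
magnitude law over the distance range subtended by cell $j$ as seen from
node $i$, computed from the survival function
$S(d) = P(\ell > d)$; midpoint evaluation of the density would
misrepresent the $\ell^{-\mu}$ singularity at the cutoff. The kernel is
Toeplitz except in the two threshold columns, and its row sums telescope
exactly to the one-step survival probability
$\tfrac12 P(\ell < x_i - r_v) + \tfrac12 P(\ell < \lambda - r_v - x_i)$ —
the conservation identity the suite asserts. The dense system
$(I - K) D = m$ is solved directly; absorption keeps the spectral radius
of $K$ below 1, and grids up to a few thousand nodes are solved in
seconds, so no iterative machinery is used.

Boundary conventions: a path that *reaches* a threshold is truncated
there. For continuous laws the weak/strict distinction is measure-zero;
for the lattice fixed-step law it is the convention under which the solver
reproduces the gambler's-ruin closed form — a walker with step
$\ell = \Delta$ starting $a$ cells from one threshold and $b$ from the
other travels $a\,b\,\Delta$ on average — exactly (to $10^{-14}$), which
the suite checks against both the closed form and an independent
absorption-chain solve. The Monte Carlo simulator uses the same weak
inequality, so all three routes share one model.

Grid convergence is a test-suite concern, not a runtime one
(`check_grid_convergence`): at $\mu = 2$, $\lambda/r_v = 100$, halving
$\Delta$ from $r_v$ to $r_v/2$ moves the midpoint value by under $0.1\%$;
the largest relative movement, about $1.4\%$, is confined to the nodes
adjacent to the thresholds where $D$ is smallest.

## Averaged efficiency and its two readings

Search efficiency for a fixed start is $1/\langle D(x_0)\rangle$. With
fluctuating starts the package averages the *efficiency*, not the
distance:
$$\langle\eta\rangle = \int_{r_v}^{\lambda/2}
  \frac{\pi(x_0)}{\langle D(x_0)\rangle}\, dx_0,$$
by trapezoidal quadrature on the solver nodes (weights renormalized to
sum to one, so constants average exactly; point masses collapse onto the
nearest node and reduce to $1/\langle D(\mathrm{atom})\rangle$ exactly).
The alternative reading $1/\int \pi\,\langle D\rangle\,dx_0$ — the
long-run encounters-per-distance ratio of a single run with randomized
restarts, by Jensen's inequality never larger — is available as
`mode = "inverse_mean"`; the Monte Carlo cross-check of the quadrature is
performed in that mode because `estimate_efficiency` is exactly that
ratio estimator. The two modes coincide for point-mass $\pi$ and differ
little when $\pi$ is narrow; all optimal-exponent results reported by the
package use the default reading.

## The surrogate and the optimization

Locating $\mu_{\mathrm{opt}}$ requires $\langle D(x_0; \mu)\rangle$ at
arbitrary $\mu$. A closed-form regression of the surface would need a
basis choice that nothing in the model pins down, so the package instead
interpolates: profiles are solved exactly on an exponent grid (default
$\{1.01, 1.1, 1.2, \ldots, 3\}$) and `fit_surrogate()` builds a
tensor-product natural-cubic interpolant of $\log D$ in $(\mu, x_0)$. It
reproduces the input solves exactly; leave-one-out error at interior
exponent nodes is below $2\%$ at $\lambda/r_v = 10^3$, and the optimum it
yields is within $0.05$ in $\mu$ of a brute-force exact-solve scan — both
are tested, so the surrogate is an acceleration, not an approximation the
conclusions depend on.

`optimal_mu()` maximizes $\mu \mapsto \langle\eta\rangle$ by a dense scan
(step $0.01$) plus golden-section refinement when the maximizer is
interior. Maximization is used instead of solving
$\partial\langle\eta\rangle/\partial\mu = 0$ because in the ballistic
regime the maximizer sits on the $\mu = 1.01$ clamp where the derivative
does not vanish; such optima are flagged `at_boundary`. `crossover_alpha()`
bisects in $\log\alpha$ for the smallest fluctuation width whose optimum
is on the clamp, to a $5\%$ relative bracket; when no crossover exists in
the bracket (as for fluctuations around the faraway target, where every
$\alpha$ is ballistic) the error names both endpoint states.

## Monte Carlo simulator

`run_search()` is the independent oracle: it shares no code with the
solver path. Restart positions are drawn first from $\pi$ (exact inverse
CDF for every family), then a compiled loop draws signed steps and applies
the same truncation rule; a single seeded stream makes one `seed`
reproduce the outcome bit-for-bit. Tallies satisfy
`n_truncated == n_targets` by construction (each encounter ends exactly
one truncated step), and the truncated-step fraction equals the inverse
mean number of steps per encounter — both identities are asserted rather
than assumed. A hard cap of $10^8$ steps per encounter turns pathological
parameterizations into errors, never silent censoring. Detection is
path-based: a jump whose path crosses the threshold is truncated there;
point-landing detection with leapovers is out of scope.

## Study conditions and problem sizes

The package's reference conditions, used by the tests, the fixture
generator (`generate_fixtures`) and the acceptance script, are
$\lambda/r_v = 10^3$ with $\ell_0 = r_v = \Delta$ (999 solver nodes), the
exponent grid above, fluctuation widths
$\alpha \in \{0.1, 1, 10, 10^2, 10^3\}$, $10^4$ encounters per Monte Carlo
oracle cell, and a reduced 11-node exponent grid for the
$\lambda/r_v = 4\cdot10^3$ crossover solve (cross-checked at
$\lambda/r_v = 10^3$: $\alpha_c$ agrees with the full grid within the
bisection tolerance). Fast unit tests use $\lambda/r_v = 50$. Under these
conditions the package reproduces: $\mu_{\mathrm{opt}} \approx 1.92$ for
the non-destructive point start; ballistic optima for the symmetric point
start and for midpoint-centred fluctuations at every width tested;
$\mu_{\mathrm{opt}}(\alpha)$ decreasing from $\approx 1.92$ to the clamp
with $\alpha_c \approx 145$ at $\lambda/r_v = 10^3$; and
$\alpha_c \approx 547$ at $\lambda/r_v = 4\cdot10^3$ — a broader
superdiffusive regime at lower target density.

## What the generator emulates — and what it does not

The synthetic landscape is a two-target interval with restart
fluctuations; it emulates the coupling between start-distance asymmetry
and optimal diffusivity, which is the mechanism under study. It does not
emulate: many-target landscapes with correlated gaps, target motion or
regeneration, energy costs of travel, higher-dimensional geometry (where
ballistic strategies lose efficiency and the crossover should narrow), or
detection failure on fast flights. Passing tests therefore validate the
mechanism and the numerics, not any field data set.

## Known limitations

* $\langle D\rangle$ is a distance, not a first-passage *time*; velocity
  and time bookkeeping are out of scope.
* The solver's accuracy near the thresholds is limited by the cell
  resolution $\Delta$; quantities dominated by the within-$\ell_0$ region
  (e.g. $D$ at the first node) converge more slowly than the interior.
* The crossover $\alpha_c$ inherits the $5\%$ bisection tolerance plus the
  surrogate's $\mu$ resolution; its absolute value also depends on the
  $\sigma = \alpha\,r_v$ decay-length convention, so comparisons across
  geometries (its growth with $\lambda/r_v$) are more meaningful than its
  absolute scale.
* Exponents are clamped at $1.01$; statements about "$\mu \to 1$" are
  realized at the clamp.
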