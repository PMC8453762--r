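---
title: "Models and methods: trait variation, rewiring, and G×E under warming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: trait variation, rewiring, and G×E under warming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecorewire)
```

# The two models

`ecorewire` implements two proof-of-concept models of how phenotypic
variation — genetic (G), plastic (E), and genotype-by-environment
(G×E) — restructures trophic interactions.

## Trait-integrated multispecies functional response

A predator population carries a quantitative trait $x$ (body size is
the canonical example) distributed as $N(\bar x, \sigma^2)$. Each prey
$i$ has a trait optimum $X_{opt,i}$ at which the predator's attack
rate is maximal and its handling time minimal; performance degrades
with the phenotypic mismatch $(x - X_{opt,i})^2$. The population mean
intake on prey $i$ is the multispecies type II functional response
averaged over the trait distribution:

$$
f_i = \int_{-\infty}^{\infty}
\frac{\alpha_i(x)\, R_i\, C}{1 + \sum_j \alpha_j(x)\, \eta_j(x)\, R_j}
\, p(x;\bar x,\sigma^2)\, dx ,
$$

with prey densities $R_j$, predator density $C$, attack kernels
$\alpha_j$ and handling kernels $\eta_j$. The shared denominator
couples all prey: time spent handling one prey is unavailable for
hunting another.

**Kernel forms.** Only the extremes at $X_{opt}$ are biologically
constrained, so the functional forms are a modelling choice. We use a
Gaussian attack rate
$\alpha(x) = \alpha_{max} e^{-(x - X_{opt})^2 / 2\tau_\alpha^2}$ and an
exponentially inflating handling time
$\eta(x) = \eta_{min} e^{(x - X_{opt})^2 / 2\tau_\eta^2}$ — smooth,
positive, symmetric, and standard in trait-matching models. Both
kernels accept a replacement `shape` function of the mismatch, so
alternatives (e.g. quadratic inflation) can be plugged in without
touching the integrator.

**Assumptions.** One trait; prey trait distributions are collapsed to
point optima; prey densities are parameters, not dynamical state (no
depletion during intake evaluation); units are dimensionless simulation
units throughout and are not checked.

**Rewiring metrics.** A prey counts as a trophic *link* when
$f_i > \varepsilon$. The threshold is not biologically given, so
`variance_sweep()` defaults to a scale-free relative cutoff,
$\varepsilon = 10^{-3} \times \max_i f_i$ at the smallest variance in
the sweep, recorded in the output. Turnover between two scenarios is
the Jaccard complement $1 - |\text{retained}|/|\text{union}|$.
Monotonicity of link counts (nondecreasing in $\sigma^2$) and of
maximum strength (nonincreasing) is asserted only on the mismatch-graded
reference fixture described below; arbitrary communities need not be
monotone.

## Temperature-dependent consumer–resource model with G×E

The community model, in per-capita form (per-capita growth being the
natural fitness scale):

$$
\frac{1}{R}\frac{dR}{dt} = r - \frac{r}{K} R - a C , \qquad
\frac{1}{C}\frac{dC}{dt} = e a R - m .
$$

Closed forms used throughout: $R^* = m/(ea)$,
$C^* = (r/a)(1 - R^*/K)$, feasible iff $R^* < K$; the Jacobian at the
coexistence equilibrium is
$\begin{pmatrix} -rR^*/K & -aR^* \\ eaC^* & 0 \end{pmatrix}$, whose
trace is strictly negative and determinant strictly positive whenever
the equilibrium is feasible — every feasible coexistence state of this
model is locally stable, which the test suite confirms on 1,000 random
feasible draws. Resilience is reported as $-\mathrm{Re}(\lambda_{max})$,
the asymptotic return rate after a small perturbation. The reciprocal
return time is the same information up to ordering near equilibrium; we
expose the eigenvalue form as primary because it is exact rather than
trajectory-dependent.

**Reaction norms.** Each parameter may follow a thermal reaction norm.
Linear norms are `value_at_ref + slope * (T - T_ref)` with
`T_ref = 15` °C; temperatures are in °C. Genotypes constructed with
equal `value_at_ref` have identical phenotypes at 15 °C, so intercept
spread is G, the mean slope is E, and slope spread is G×E. The
resource's intrinsic growth rate defaults to a quadratic-peak norm
(value anchored at `T_ref`, maximum at 25 °C, curvature −0.002 per
°C²), reflecting ectotherm growth that rises and then falls with
temperature; the carrying capacity defaults to flat since there is no
comparably general expectation for $K(T)$. The default valid range is
5–35 °C, inside which the default $r(T)$ stays positive.

**Parameter flooring.** Linear norms cross zero. Evaluations are
floored at $10^{-6}$ (configurable) with a warning and a `floored` flag
in the evaluated parameter set, rather than an error — sweeps stay
total while biological invalidity remains visible.

**Selection.** Evolution is modelled as competition among a discrete
genotype panel by pairwise invasibility at ecological equilibrium
(timescale separation: ecology equilibrates between invasions). The
invasion fitness of genotype $j$ into resident $i$ is
$s_{ij} = e_j a_j R^*_i - m_j$, which gives $s_{ii} = 0$ and
$\mathrm{sign}(s_{ij}) = \mathrm{sign}(R^*_i - R^*_j)$: the panel
member minimizing $R^*$ is uninvadable (the R\* rule). No explicit
genotype-frequency dynamics are simulated. Ties within $10^{-9}$ in
$R^*$ are flagged neutral and broken to the lexicographically smaller
id for reproducibility.

**Crossing temperatures.** `crossing_temperature()` locates roots of
$R^*_A(T) - R^*_B(T)$ by sign-bracketing on a 512-point grid followed
by bisection (`uniroot`, tolerance $10^{-12}$); multiple roots are all
returned, and identical genotypes are flagged degenerate rather than
root-found. A caution that shaped the test fixtures: if two genotypes'
$(a, m)$ slopes are proportional between genotypes, their $R^*$ curves
coincide at *every* temperature and there is no isolated crossing.

**Variance decomposition.** `decompose_variance()` evaluates one
parameter on the full genotype × temperature grid and applies the exact
two-way population-variance decomposition: $V_G$ = variance of genotype
means, $V_E$ = variance of temperature means, $V_{G\times E}$ = mean
squared interaction residual. On a complete grid the cross terms vanish
and the components sum to the total to machine precision; parallel
norms give $V_{G\times E} = 0$ up to floating-point cancellation
(observed $< 10^{-30}$ on unit-scale parameters).

# Numerical choices

* **Quadrature.** The intake integral uses Gauss–Hermite quadrature in
  the standardized trait (the natural rule under a Gaussian weight),
  via `pracma::gaussHermite`, with 256 nodes by default. The node count
  was set by comparing against adaptive quadrature at `rel.tol` 1e-13:
  on the reference fixture at $\sigma^2 = 7$ the worst relative error
  is $6 \times 10^{-5}$ at 256 nodes (1.5% at 64 — the shared
  denominator varies too sharply for a small rule). An adaptive
  fallback (`adaptive = TRUE`, `stats::integrate` on $\bar x \pm
  8\sigma$) is available for unusual kernel shapes.
* **Degenerate variance.** $\sigma^2 \le 10^{-12}$ routes to the
  point-mass branch (the response evaluated at $\bar x$), avoiding
  zero-width Gaussians; the quadrature and point-mass branches agree to
  $4 \times 10^{-12}$ relative at the boundary.
* **Overflow.** At extreme mismatch the attack rate underflows while
  the handling time overflows; the $\alpha_j \eta_j$ denominator
  products are therefore formed in log space.
* **ODE integration.** `deSolve::ode` (lsoda), relative tolerance
  $10^{-8}$, absolute $10^{-10}$; tiny negative integrator excursions
  are clipped to zero.
* **Trajectory decay rate.** The worked case ($r=1, K=10, a=1, e=0.5,
  m=1$) has $\lambda = -0.1 \pm i\sqrt{0.79}$; after a 5% perturbation
  the log distance to equilibrium oscillates around a linear trend, so
  the decay rate is estimated by regression over $t \in [10, 80]$
  (≈ 10 oscillation periods, past the transient).

# The synthetic fixtures

The generators define the study conditions; all tests run on them.

* `make_mismatch_community()` — the reference community: 10 prey with
  mismatch evenly spaced on $[0, 9]$ (even spacing keeps the
  monotonicity assertions stable; the upper end matches the
  $\sigma^2 = 7$ vs $\sigma^2 \approx 0$ contrast being illustrated),
  equal unit densities, predator density 1, shared kernels
  $\alpha_{max} = 1$, $\tau_\alpha = 0.5$, $\eta_{min} = 1$,
  $\tau_\eta = 1$. The attack width is set narrower than the handling
  width so that at near-zero variance distant prey are effectively
  unlinked — giving the link count room to grow as variance spreads
  the trait distribution across prey optima.
* `make_genotype_panel()` — normal draws of intercepts (sd =
  `intercept_sd`; 0 reproduces the equal-at-15 °C construction) and
  slopes (mean `mean_slope`, sd `slope_sd`) per parameter; intercepts
  truncated at the parameter floor (truncations counted, not
  resampled). The planted $V_G$, $V_E$, $V_{G\times E}$ on the
  requested grid are computed analytically from the drawn coefficients
  and returned for recovery tests.
* `random_feasible_params()` — uniform draws on positive ranges,
  rejection-sampled to feasibility $m/(ea) < K$, with an error if
  acceptance falls below 1%.

All draws use R's default Mersenne-Twister through a seed-scoped
wrapper that restores the caller's RNG state, so a seed fully
determines every fixture across platforms.

What the fixtures emulate is deliberately minimal: graded mismatch,
controlled variance structure, feasible demography. They do not emulate
empirical trait distributions (skew, multimodality), correlated prey
densities, multi-trait matching, prey trait variance, or measurement
error — so passing tests demonstrate internal correctness of the
models, not calibration to any real food web.

# Problem sizes

Default analysis and test sizes — 10-prey communities, 256 quadrature
nodes, $10^6$-sample Monte-Carlo cross-checks on 100 seeded
communities, 1,000 random feasible draws for the stability and
selection properties, 26-point temperature sweeps — keep the full suite
and the acceptance script in the tens of seconds on one CPU while
leaving estimation error far below the tolerances being asserted.

# Known limitations

* Single consumer, single trait; no assembled multi-consumer network,
  and no nestedness/modularity statistics.
* Temperature dependence is linear or single-peaked; no
  Boltzmann–Arrhenius kinetics.
* Selection is among a finite genotype panel; no continuous trait
  evolution (no breeder's-equation dynamics) and no
  mutation-limited adaptive-dynamics branching analysis.
* The link threshold $\varepsilon$ is a reporting convention, not a
  biological quantity; conclusions about link *counts* (not strengths)
  depend on it.
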