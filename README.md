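# ecorewire

Phenotypic variation — genetic (G), plastic (E) and
genotype-by-environment (G×E) — reshapes who eats whom, and how
strongly. `ecorewire` provides a tested simulator for two complementary
views of that process, aimed at ecologists and evolutionary biologists
exploring how trait variance and warming rewire food webs:

1. **Trait variance and link structure.** A predator population carries
   a Gaussian quantitative trait *x* ~ N(x̄, σ²) (think body size).
   Foraging on prey *i* peaks at a prey-specific optimum
   *X*<sub>opt,*i*</sub>: the attack rate α(x) is maximal and the
   handling time η(x) minimal there, degrading with the phenotypic
   mismatch (x − *X*<sub>opt</sub>)². The population mean intake on
   prey *i* integrates a multispecies type II functional response over
   the trait distribution:

   f_i = ∫ [ α_i(x) R_i C / (1 + Σ_j α_j(x) η_j(x) R_j) ] p(x; x̄, σ²) dx

   with prey densities *R<sub>j</sub>* and predator density *C*.
   Counting prey with *f<sub>i</sub>* above a threshold as trophic
   links, raising σ² produces *more but weaker* links; shrinking it,
   *fewer but stronger* ones — rewiring driven purely by trait
   variance.

2. **G×E under warming.** A consumer–resource model in per-capita form,

   (1/R) dR/dt = r − (r/K) R − a C,
   (1/C) dC/dt = e a R − m,

   where each parameter may follow a thermal reaction norm. Consumer
   genotypes share a phenotype at the 15 °C reference but differ in
   thermal sensitivity (slope) of attack rate *a* and mortality *m* — a
   G×E effect. The package computes closed-form equilibria
   (R\* = m/(ea), C\* = (r/a)(1 − R\*/K)), Jacobian eigenvalues and
   resilience −Re(λ<sub>max</sub>), pairwise invasion fitness
   s = e′a′R\*<sub>resident</sub> − m′, the genotype favoured by
   selection (the R\* rule: smallest m/(ea) wins), the temperature at
   which the favoured genotype switches, ODE trajectories, and an exact
   two-way decomposition of parameter variance into V_G, V_E and V_G×E.

A synthetic fixture generator (mismatch-graded prey communities,
genotype panels with planted variance components, feasible random
parameter draws) makes every analysis reproducible without external
data, and a YAML-config runner (`load_config()` / `run_command()`, plus
the thin CLI at `inst/cli/ecorewire.R`) turns analyses into re-runnable,
provenance-stamped CSV outputs.

## Worked example

```r
library(ecorewire)

# 10 prey, mismatch evenly spaced on [0, 9], shared kernels
fx <- make_mismatch_community()
variance_sweep(fx$community, fx$kernels, c(0.01, 7))
#> Variance sweep (2 sigma2 values, epsilon = 0.0004299)
#>  sigma2    epsilon n_links max_strength mean_strength total_intake
#>    0.01 0.00042992       4     0.429918      0.125505      0.50224
#>    7.00 0.00042992      10     0.086036      0.032971      0.32971
```

At near-zero trait variance the predator holds 4 links, the strongest
at 0.43 intakes per unit time and area; at σ² = 7 it holds all 10, but
the strongest has dropped five-fold — more but weaker interactions.

```r
p <- cr_params(r = 1, K = 10, a = 1, e = 0.5, m = 1)
equilibrium(p)
#> Equilibrium: R* = 2, C* = 0.8 (feasible)
stability(p)
#> Stability: lambda_max = -0.1 (stable), resilience -Re(lambda_max) = 0.1

# two genotypes, equal at 15 C, B with steeper thermal sensitivity
gA <- genotype("A", reaction_norm(0.5, 0.005), reaction_norm(0.2, 0.008),
               reaction_norm(0.5))
gB <- genotype("B", reaction_norm(0.5, 0.025), reaction_norm(0.2, 0.010),
               reaction_norm(0.5))
env <- resource_environment()
favoured_genotype(list(gA, gB), env, 25)
#> Favoured genotype: B
#> R* by genotype:
#>        A        B
#> 1.018182 0.800000
crossing_temperature(gA, gB, env)
#> [1] 15
```

At 25 °C genotype B depresses the resource to R\* = 0.80 versus A's
1.02, so B excludes A; below the 15 °C crossing the ranking reverses.
Selection flips with warming purely through G×E in thermal slopes.

```r
pn <- make_genotype_panel(n_genotypes = 4, intercept_sd = 0.05, seed = 7)
decompose_variance(pn$panel, pn$T_grid, "a")
#> Variance decomposition of 'a' (4 genotypes x 6 temperatures):
#>   V_G = 0.00712162  V_E = 0.076654  V_GxE = 0.00537855  (total 0.0891541)
```

The components sum to the total exactly, and match the generator's
planted values.

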