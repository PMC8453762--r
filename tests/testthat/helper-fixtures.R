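# Shared fixtures, all generated in code.

# mismatch-graded reference fixture (10 prey, mismatch 0..9, shared kernels)
ref_fixture <- function() make_mismatch_community()

# worked consumer-resource parameter set with known closed forms:
# R* = 2, C* = 0.8, J = [[-0.2, -2], [0.4, 0]], lambda = -0.1 +/- i sqrt(0.79)
worked_params <- function() cr_params(r = 1, K = 10, a = 1, e = 0.5, m = 1)

# Demonstration panel: equal phenotypes at 15 C, genotype B with
# steeper thermal sensitivity of both attack and mortality, conversion
# efficiency flat. A's mortality outpaces its attack under warming
# while B's attack outpaces its mortality, so the R* curves cross at
# 15 C: A is favoured below, B above. (Slopes must not be proportional
# between genotypes or the R* curves coincide everywhere.)
demo_panel <- function() {
  list(
    genotype("A",
             norm_a = reaction_norm(0.5, 0.005),
             norm_m = reaction_norm(0.2, 0.008),
             norm_e = reaction_norm(0.5, 0)),
    genotype("B",
             norm_a = reaction_norm(0.5, 0.025),
             norm_m = reaction_norm(0.2, 0.010),
             norm_e = reaction_norm(0.5, 0)))
}

demo_env <- function() resource_environment()

# seeded random genotype panel with spread in intercepts and slopes
random_panel <- function(seed, n = 5) {
  make_genotype_panel(
    n_genotypes = n,
    base = list(a = 0.6, m = 0.25, e = 0.5),
    intercept_sd = list(a = 0.1, m = 0.05, e = 0.05),
    mean_slope = list(a = 0.015, m = 0.006, e = 0),
    slope_sd = list(a = 0.008, m = 0.003, e = 0),
    seed = seed)$panel
}

# central finite differences of the consumer-resource right-hand side
fd_jacobian <- function(p, state, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (k in 1:2) {
    up <- state; up[k] <- up[k] + h
    dn <- state; dn[k] <- dn[k] - h
    J[, k] <- (cr_rhs(up, p) - cr_rhs(dn, p)) / (2 * h)
  }
  J
}
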