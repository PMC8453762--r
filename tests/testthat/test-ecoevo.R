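# Temperature-dependent consumer-resource model: reaction norms,
# equilibria, stability, invasion analysis, sweeps, trajectories and
# variance decomposition.

test_that("reaction norms evaluate linearly and anchor at the reference", {
  expect_equal(evaluate_norm(reaction_norm(0.7, 0), 40), 0.7)
  expect_equal(evaluate_norm(reaction_norm(0.5, 0.01), 25), 0.6)
  # equal value at T_ref regardless of slope (same initial phenotype)
  nA <- reaction_norm(0.5, 0.01)
  nB <- reaction_norm(0.5, 0.03)
  expect_equal(evaluate_norm(nA, 15), evaluate_norm(nB, 15))
  # quadratic peak: anchored at T_ref, maximal at the peak
  nq <- reaction_norm(1, form = "quadratic-peak", peak_temperature = 25,
                      curvature = -0.002)
  expect_equal(as.numeric(evaluate_norm(nq, 15)), 1)
  Ts <- seq(5, 35, 0.5)
  v <- as.numeric(evaluate_norm(nq, Ts))
  expect_equal(Ts[which.max(v)], 25)
  expect_error(reaction_norm(1, form = "quadratic-peak",
                             peak_temperature = 25, curvature = 0.1),
               "curvature")
})

test_that("norm evaluation floors at a positive value with a warning", {
  n <- reaction_norm(0.1, -0.05)  # crosses zero above 17 C
  expect_warning(v <- evaluate_norm(n, 30), "floored")
  expect_equal(as.numeric(v), 1e-6)
  g <- genotype("A", norm_a = n, norm_m = reaction_norm(0.2),
                norm_e = reaction_norm(0.5))
  p <- params_at(g, resource_environment(), 30)
  expect_true(p$floored)
  expect_equal(p$a, 1e-6)
})

test_that("params_at evaluates all five parameters and checks the range", {
  env <- resource_environment()
  flat <- genotype("F", reaction_norm(0.5), reaction_norm(0.2),
                   reaction_norm(0.5))
  p10 <- params_at(flat, env, 10)
  p30 <- params_at(flat, env, 30)
  expect_equal(p10[c("a", "m", "e", "K")], p30[c("a", "m", "e", "K")])
  rising_m <- genotype("M", reaction_norm(0.5), reaction_norm(0.2, 0.01),
                       reaction_norm(0.5))
  expect_gt(params_at(rising_m, env, 30)$m, params_at(rising_m, env, 10)$m)
  expect_error(params_at(flat, env, 100), "outside valid range")
})

test_that("equilibrium matches the closed form and the rhs vanishes there", {
  eq <- equilibrium(worked_params())
  expect_equal(eq$R_star, 2)
  expect_equal(eq$C_star, 0.8)
  expect_true(eq$feasible)
  # infeasible when R* >= K
  bad <- cr_params(r = 1, K = 1, a = 1, e = 0.5, m = 1)
  expect_false(equilibrium(bad)$feasible)
  expect_lte(equilibrium(bad)$C_star, 0)
  # rhs is zero at every feasible equilibrium
  for (p in random_feasible_params(50, seed = 5)) {
    e <- equilibrium(p)
    expect_lt(max(abs(cr_rhs(c(e$R_star, e$C_star), p))), 1e-12)
  }
})

test_that("rhs has the boundary fixed points and rejects negative densities", {
  p <- worked_params()
  expect_equal(cr_rhs(c(0, 0), p), c(0, 0))
  expect_equal(cr_rhs(c(p$K, 0), p), c(0, 0))
  expect_error(cr_rhs(c(-1, 0), p), "invalid state")
})

test_that("analytic Jacobian matches hand computation and finite differences", {
  p <- worked_params()
  J <- cr_jacobian(p)
  expect_equal(J, matrix(c(-0.2, -2, 0.4, 0), 2, byrow = TRUE))
  for (pp in random_feasible_params(25, seed = 9)) {
    e <- equilibrium(pp)
    expect_equal(cr_jacobian(pp, e), fd_jacobian(pp, c(e$R_star, e$C_star)),
                 tolerance = 1e-6)
    # trace is the negative resource self-limitation term
    expect_equal(sum(diag(cr_jacobian(pp, e))), -pp$r * e$R_star / pp$K)
  }
  expect_error(cr_jacobian(cr_params(1, 1, 1, 0.5, 1)), "infeasible")
})

test_that("stability reproduces the quadratic-formula eigenvalues", {
  st <- stability(worked_params())
  # characteristic polynomial lambda^2 + 0.2 lambda + 0.8 = 0
  expect_equal(sort(Re(st$eigenvalues)), c(-0.1, -0.1))
  expect_equal(sort(Im(st$eigenvalues)), c(-sqrt(0.79), sqrt(0.79)))
  expect_equal(st$resilience, 0.1)
  expect_true(st$stable)
  # eigen() output against quadratic-formula roots on random draws
  for (p in random_feasible_params(20, seed = 3)) {
    e <- equilibrium(p)
    tr <- -p$r * e$R_star / p$K
    det <- p$e * p$a^2 * e$R_star * e$C_star
    roots <- (tr + c(-1, 1) * sqrt(as.complex(tr^2 - 4 * det))) / 2
    st <- stability(p)
    expect_equal(sort(Re(st$eigenvalues)), sort(Re(roots)), tolerance = 1e-10)
    expect_equal(sort(abs(Im(st$eigenvalues))), sort(abs(Im(roots))),
                 tolerance = 1e-10)
  }
})

test_that("every feasible coexistence equilibrium is locally stable", {
  draws <- random_feasible_params(1000, seed = 17)
  lmax <- vapply(draws, function(p) stability(p)$lambda_max_real, numeric(1))
  expect_true(all(lmax < 0))
})

test_that("invasion fitness is neutral on self and tracks R* differences", {
  env <- demo_env()
  panel <- demo_panel()
  expect_equal(invasion_fitness(panel[[1]], panel[[1]], env, 20), 0)
  # lower mortality, all else equal, invades
  lowm <- genotype("L", reaction_norm(0.5, 0.01), reaction_norm(0.15, 0.004),
                   reaction_norm(0.5))
  expect_gt(invasion_fitness(panel[[1]], lowm, env, 20), 0)
  # sign(s) = sign(R*_resident - R*_invader) on seeded pairs
  for (seed in 1:25) {
    pair <- random_panel(seed, n = 2)
    T <- 10 + (seed %% 4) * 5
    RA <- equilibrium(params_at(pair[[1]], env, T))$R_star
    RB <- equilibrium(params_at(pair[[2]], env, T))$R_star
    s <- invasion_fitness(pair[[1]], pair[[2]], env, T)
    expect_equal(sign(s), sign(RA - RB))
    # antisymmetry of invasion signs
    if (RA != RB)
      expect_lt(s * invasion_fitness(pair[[2]], pair[[1]], env, T), 0)
  }
})

test_that("the pairwise-invasibility winner obeys the R* rule", {
  env <- demo_env()
  for (seed in 1:60) {
    panel <- random_panel(seed)
    T <- 8 + (seed %% 5) * 5
    res <- favoured_genotype(panel, env, T)
    expect_equal(res$favoured_genotype, names(which.min(res$R_star)))
    # winner is uninvadable: its resident row is nonpositive
    win <- res$favoured_genotype
    expect_true(all(res$fitness[win, ] <= 1e-12))
    # self-invasion diagonal vanishes for feasible residents
    feas <- !is.na(res$R_star)
    expect_true(all(abs(diag(res$fitness)[feas]) < 1e-12))
    # brute force: the only genotype with a nonpositive resident row
    brute <- rownames(res$fitness)[apply(res$fitness, 1, function(r)
      all(r[!is.na(r)] <= 1e-12))]
    expect_true(win %in% brute)
  }
})

test_that("identical genotypes tie neutrally with a deterministic winner", {
  env <- demo_env()
  g1 <- genotype("B", reaction_norm(0.5, 0.01), reaction_norm(0.2, 0.004),
                 reaction_norm(0.5))
  g2 <- genotype("A", reaction_norm(0.5, 0.01), reaction_norm(0.2, 0.004),
                 reaction_norm(0.5))
  res <- favoured_genotype(list(g1, g2), env, 20)
  expect_true(res$neutral)
  expect_equal(res$favoured_genotype, "A")
  expect_error(favoured_genotype(list(
    genotype("X", reaction_norm(0.001), reaction_norm(5), reaction_norm(0.1))),
    env, 20), "no viable genotype")
})

test_that("steeper attack slopes win above the reference temperature", {
  env <- demo_env()
  gA <- genotype("A", reaction_norm(0.5, 0.01), reaction_norm(0.2),
                 reaction_norm(0.5))
  gB <- genotype("B", reaction_norm(0.5, 0.03), reaction_norm(0.2),
                 reaction_norm(0.5))
  expect_equal(favoured_genotype(list(gA, gB), env, 25)$favoured_genotype, "B")
  expect_true(favoured_genotype(list(gA, gB), env, 15)$neutral)
})

test_that("crossing temperature finds the R* intersection", {
  env <- demo_env()
  # constructed symmetric case: equal at 15 C, different a slopes
  gA <- genotype("A", reaction_norm(0.5, 0.01), reaction_norm(0.2),
                 reaction_norm(0.5))
  gB <- genotype("B", reaction_norm(0.5, 0.03), reaction_norm(0.2),
                 reaction_norm(0.5))
  Tx <- crossing_temperature(gA, gB, env)
  expect_length(Tx, 1)
  expect_equal(Tx, 15, tolerance = 1e-8)
  # identical genotypes: degenerate, flagged
  Td <- crossing_temperature(gA, gA, env)
  expect_true(is.na(Td))
  expect_true(attr(Td, "degenerate"))
  # residual check on randomized pairs with a crossing
  found <- 0
  for (seed in 1:20) {
    pair <- random_panel(seed, n = 2)
    Tx <- crossing_temperature(pair[[1]], pair[[2]], env, T_range = c(5, 30))
    for (t in Tx[!is.na(Tx)]) {
      RA <- equilibrium(params_at(pair[[1]], env, t))$R_star
      RB <- equilibrium(params_at(pair[[2]], env, t))$R_star
      expect_lt(abs(RA - RB), 1e-10)
      found <- found + 1
    }
  }
  expect_gt(found, 0)
})

test_that("temperature sweeps track selection and resilience", {
  env <- demo_env()
  # flat single genotype: resilience constant only if r is flat too
  flat_env <- resource_environment(norm_r = reaction_norm(1),
                                   norm_K = reaction_norm(10))
  flat <- genotype("F", reaction_norm(0.5), reaction_norm(0.2),
                   reaction_norm(0.5))
  sw <- temperature_sweep(list(flat), flat_env, seq(5, 30, 5))
  expect_equal(length(unique(round(sw$resilience, 12))), 1)
  # demonstration panel: favoured genotype switches along the gradient,
  # and the genotype gap in resilience widens toward the warm end
  panel <- demo_panel()
  grid <- seq(5, 30, by = 1)
  sw <- temperature_sweep(panel, env, grid)
  favA <- sw$favoured[sw$genotype_id == "A"]
  favB <- sw$favoured[sw$genotype_id == "B"]
  expect_true(favA[1] && !favB[1])          # cold end favours A
  expect_true(favB[length(favB)] && !favA[length(favA)])  # warm end favours B
  gap <- abs(sw$resilience[sw$genotype_id == "A"] -
             sw$resilience[sw$genotype_id == "B"])
  expect_gt(gap[length(gap)], gap[grid == 16])
  expect_gt(mean(diff(gap[grid >= 15])), 0)
  # the favoured switch brackets the analytic crossing temperature
  Tx <- crossing_temperature(panel[[1]], panel[[2]], env, T_range = c(5, 30))
  switch_idx <- which(diff(favB) == 1)
  expect_length(switch_idx, 1)
  expect_true(grid[switch_idx] <= Tx && Tx <= grid[switch_idx + 1])
  expect_error(temperature_sweep(panel, env, numeric(0)), "nonempty")
})

test_that("trajectories stay on fixed points and decay at the linearized rate", {
  p <- worked_params()
  eq <- equilibrium(p)
  times <- seq(0, 80, 0.1)
  # start exactly at equilibrium: stays there
  tr <- simulate_trajectory(p, init = c(eq$R_star, eq$C_star), times = times)
  expect_lt(max(abs(tr$R - eq$R_star)), 1e-6)
  expect_lt(max(abs(tr$C - eq$C_star)), 1e-6)
  # consumer-free axis: resource converges to K
  tr0 <- simulate_trajectory(p, init = c(0.5, 0), times = seq(0, 200, 1))
  expect_equal(tail(tr0$R, 1), p$K, tolerance = 1e-6)
  expect_true(all(tr0$C == 0))
  # 5% perturbation: log-distance decays at about -Re(lambda_max) = 0.1
  tr5 <- simulate_trajectory(p, init = 1.05 * c(eq$R_star, eq$C_star),
                             times = times)
  d <- sqrt((tr5$R - eq$R_star)^2 + (tr5$C - eq$C_star)^2)
  keep <- times >= 10  # several oscillation periods, past transients
  fit <- lm(log(d[keep]) ~ times[keep])
  expect_equal(unname(coef(fit)[2]), -0.1, tolerance = 0.1)
  expect_error(simulate_trajectory(p, init = c(-1, 1), times = times),
               "nonnegative")
})

test_that("variance decomposition is exact and recovers planted components", {
  Tg <- seq(5, 30, 5)
  # two flat-vs-shifted genotypes: pure G
  gA <- genotype("A", reaction_norm(1), reaction_norm(0.2), reaction_norm(0.5))
  gB <- genotype("B", reaction_norm(2), reaction_norm(0.2), reaction_norm(0.5))
  dec <- decompose_variance(list(gA, gB), c(10, 20), "a")
  expect_equal(dec$V_G, 0.25)
  expect_equal(dec$V_E, 0)
  expect_equal(dec$V_GxE, 0)
  # parallel norms (equal slopes, different intercepts): no GxE
  gC <- genotype("C", reaction_norm(1, 0.02), reaction_norm(0.2),
                 reaction_norm(0.5))
  gD <- genotype("D", reaction_norm(2, 0.02), reaction_norm(0.2),
                 reaction_norm(0.5))
  decP <- decompose_variance(list(gC, gD), Tg, "a")
  expect_equal(decP$V_GxE, 0)
  # components always sum to the total
  for (seed in 1:10) {
    panel <- random_panel(seed, n = 4)
    for (par in c("a", "m")) {
      d <- decompose_variance(panel, Tg, par)
      expect_equal(d$V_G + d$V_E + d$V_GxE, d$V_total, tolerance = 1e-10)
    }
  }
  expect_error(decompose_variance(list(gA), c(10, 20), "a"),
               "insufficient design")
  expect_error(decompose_variance(list(gA, gB), 10, "a"),
               "insufficient design")
})
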