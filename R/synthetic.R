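# Synthetic fixtures: mismatch-graded prey communities and genotype
# panels with planted G / E / GxE variance structure. Everything is
# deterministic under a fixed seed (R's default Mersenne-Twister), so
# generated fixtures double as reproducible reference inputs.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Mismatch-graded prey community
#'
#' Builds a prey community whose phenotypic mismatches relative to the
#' predator trait mean are evenly spaced on `[0, mismatch_max]` (the
#' first prey sits exactly at the predator's optimum) with shared
#' kernels, the configuration under which raising trait variance
#' produces more but weaker links.
#'
#' @param n_prey Number of prey (>= 1).
#' @param mismatch_max Largest mismatch (>= 0), trait units squared.
#' @param density Per-prey densities: a number or vector (recycled), or
#'   `"lognormal"` for seeded lognormal(0, 0.25) draws.
#' @param seed RNG seed (used only for random density rules).
#' @param trait_mean Predator trait mean the mismatches are measured
#'   from (optima are placed at `trait_mean + sqrt(mismatch)`).
#' @param consumer_density Predator density.
#' @param alpha_max,tau_alpha,eta_min,tau_eta Shared kernel parameters.
#' @return List with elements `community` ([prey_community()]) and
#'   `kernels` ([kernel_set()]).
#' @export
make_mismatch_community <- function(n_prey = 10, mismatch_max = 9,
                                    density = 1, seed = 1,
                                    trait_mean = 0, consumer_density = 1,
                                    alpha_max = 1, tau_alpha = 0.5,
                                    eta_min = 1, tau_eta = 1) {
  if (n_prey < 1L) stop("n_prey must be >= 1")
  if (mismatch_max < 0) stop("mismatch_max must be >= 0")
  mism <- if (n_prey == 1L) 0 else
    seq(0, mismatch_max, length.out = n_prey)
  dens <- if (identical(density, "lognormal"))
    with_seed(seed, stats::rlnorm(n_prey, 0, 0.25))
  else rep_len(density, n_prey)
  comm <- prey_community(
    id = sprintf("prey%02d", seq_len(n_prey)),
    density = dens,
    x_opt = trait_mean + sqrt(mism),
    consumer_density = consumer_density)
  list(community = comm,
       kernels = kernel_set(comm, alpha_max = alpha_max,
                            tau_alpha = tau_alpha, eta_min = eta_min,
                            tau_eta = tau_eta))
}

#' Random prey community
#'
#' Seeded random community for property tests: optima uniform on
#' `trait_mean +/- spread`, densities lognormal, kernel widths fixed.
#'
#' @param n_prey Number of prey.
#' @param seed RNG seed; fully determines the community.
#' @param spread Half-width of the optimum range (trait units).
#' @inheritParams make_mismatch_community
#' @return As [make_mismatch_community()].
#' @export
make_random_community <- function(n_prey = 5, seed = 1, spread = 3,
                                  trait_mean = 0, consumer_density = 1,
                                  alpha_max = 1, tau_alpha = 1,
                                  eta_min = 1, tau_eta = 1) {
  with_seed(seed, {
    comm <- prey_community(
      id = sprintf("prey%02d", seq_len(n_prey)),
      density = stats::rlnorm(n_prey, 0, 0.5),
      x_opt = stats::runif(n_prey, trait_mean - spread, trait_mean + spread),
      consumer_density = consumer_density)
    list(community = comm,
         kernels = kernel_set(comm, alpha_max = alpha_max,
                              tau_alpha = tau_alpha, eta_min = eta_min,
                              tau_eta = tau_eta))
  })
}

#' Genotype panel with planted G, E and GxE structure
#'
#' Draws a panel of consumer genotypes with linear thermal reaction
#' norms for attack rate, mortality and conversion efficiency.
#' Per parameter: intercepts (values at `T_ref`) are normal around the
#' base value with standard deviation `intercept_sd` (0 makes all
#' genotypes identical at `T_ref`); slopes are normal around
#' `mean_slope` with standard deviation `slope_sd` (0 gives parallel
#' norms, i.e. no GxE). Intercept draws are truncated at the parameter
#' floor (truncations counted, not resampled). The analytically planted
#' variance components on `T_grid` are returned for recovery checks.
#'
#' @param n_genotypes Number of genotypes (>= 2).
#' @param base Named list of base values at `T_ref` for `a`, `m`, `e`.
#' @param intercept_sd,mean_slope,slope_sd Named lists (entries `a`,
#'   `m`, `e`) of per-parameter generator settings; scalars are
#'   recycled to all three parameters.
#' @param T_ref Reference temperature, degrees C.
#' @param T_grid Temperature grid the planted components refer to.
#' @param seed RNG seed; fully determines the panel.
#' @return List with `panel` (list of [genotype()]s), `planted` (per
#'   parameter: `V_G`, `V_E`, `V_GxE`, `V_total` on `T_grid`),
#'   `truncated` (count of floored intercept draws), and the drawn
#'   `intercepts` / `slopes` matrices.
#' @export
make_genotype_panel <- function(n_genotypes = 2,
                                base = list(a = 0.5, m = 0.2, e = 0.5),
                                intercept_sd = 0,
                                mean_slope = list(a = 0.02, m = 0.01, e = 0),
                                slope_sd = list(a = 0.01, m = 0.005, e = 0),
                                T_ref = 15,
                                T_grid = seq(5, 30, by = 5),
                                seed = 1) {
  if (n_genotypes < 2L) stop("n_genotypes must be >= 2")
  as_par_list <- function(x, what) {
    if (!is.list(x)) x <- list(a = x, m = x, e = x)
    if (!all(c("a", "m", "e") %in% names(x)))
      stop(what, " must name entries a, m, e (or be a scalar)")
    x
  }
  intercept_sd <- as_par_list(intercept_sd, "intercept_sd")
  mean_slope <- as_par_list(mean_slope, "mean_slope")
  slope_sd <- as_par_list(slope_sd, "slope_sd")
  for (p in c("a", "m", "e"))
    if (intercept_sd[[p]] < 0 || slope_sd[[p]] < 0)
      stop("standard deviations must be nonnegative")

  pars <- c("a", "m", "e")
  draws <- with_seed(seed, {
    ic <- sapply(pars, function(p)
      stats::rnorm(n_genotypes, base[[p]], intercept_sd[[p]]))
    sl <- sapply(pars, function(p)
      stats::rnorm(n_genotypes, mean_slope[[p]], slope_sd[[p]]))
    list(ic = matrix(ic, n_genotypes, dimnames = list(NULL, pars)),
         sl = matrix(sl, n_genotypes, dimnames = list(NULL, pars)))
  })
  truncated <- sum(draws$ic < PARAM_FLOOR)
  draws$ic[draws$ic < PARAM_FLOOR] <- PARAM_FLOOR

  ids <- if (n_genotypes <= 26L) LETTERS[seq_len(n_genotypes)] else
    sprintf("G%03d", seq_len(n_genotypes))
  panel <- lapply(seq_len(n_genotypes), function(i)
    genotype(ids[i],
             norm_a = reaction_norm(draws$ic[i, "a"], draws$sl[i, "a"], T_ref = T_ref),
             norm_m = reaction_norm(draws$ic[i, "m"], draws$sl[i, "m"], T_ref = T_ref),
             norm_e = reaction_norm(draws$ic[i, "e"], draws$sl[i, "e"], T_ref = T_ref)))

  pvar <- function(v) mean((v - mean(v))^2)
  dT <- T_grid - T_ref
  planted <- lapply(pars, function(p) {
    ic <- draws$ic[, p]; sl <- draws$sl[, p]
    g_means <- ic + sl * mean(dT)
    list(V_G = pvar(g_means),
         V_E = mean(sl)^2 * pvar(dT),
         V_GxE = pvar(sl) * pvar(dT),
         V_total = pvar(g_means) + mean(sl)^2 * pvar(dT) + pvar(sl) * pvar(dT))
  })
  names(planted) <- pars

  list(panel = panel, planted = planted, truncated = truncated,
       intercepts = draws$ic, slopes = draws$sl,
       T_ref = T_ref, T_grid = T_grid, seed = seed)
}

#' Random feasible consumer-resource parameter draws
#'
#' Rejection-samples parameter sets uniform on the given ranges,
#' keeping only feasible ones (`m / (e a) < K`, so a coexistence
#' equilibrium exists). Errors if the ranges make feasibility too rare
#' (acceptance below 1%).
#'
#' @param n_draws Number of feasible draws wanted (>= 1).
#' @param ranges Named list of `c(lo, hi)` ranges for `r`, `K`, `a`,
#'   `e`, `m`; all positive.
#' @param seed RNG seed.
#' @return List of `n_draws` [cr_params()] objects.
#' @export
random_feasible_params <- function(
    n_draws,
    ranges = list(r = c(0.5, 2), K = c(5, 20), a = c(0.5, 2),
                  e = c(0.2, 0.8), m = c(0.1, 1)),
    seed = 1) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  for (p in c("r", "K", "a", "e", "m")) {
    rg <- ranges[[p]]
    if (is.null(rg) || length(rg) != 2L || any(rg <= 0) || rg[1] > rg[2])
      stop("ranges must give positive c(lo, hi) for ", p)
  }
  with_seed(seed, {
    out <- vector("list", n_draws)
    got <- 0L; tried <- 0L
    while (got < n_draws) {
      # draw in blocks; feasibility check is vectorized
      nb <- max(64L, 2L * (n_draws - got))
      d <- lapply(ranges, function(rg) stats::runif(nb, rg[1], rg[2]))
      ok <- which(d$m / (d$e * d$a) < d$K)
      tried <- tried + nb
      if (tried >= 100L * n_draws && (got + length(ok)) / tried < 0.01)
        stop("degenerate ranges: feasibility rejection rate above 99%")
      for (k in ok) {
        if (got >= n_draws) break
        got <- got + 1L
        out[[got]] <- cr_params(r = d$r[k], K = d$K[k], a = d$a[k],
                                e = d$e[k], m = d$m[k])
      }
    }
    out
  })
}
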