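# Temperature-dependent consumer-resource model with
# genotype-by-environment reaction norms.
#
# Per-capita dynamics:
#   (1/R) dR/dt = r - (r/K) R - a C
#   (1/C) dC/dt = e a R - m
#
# r: resource intrinsic growth rate, K: carrying capacity, a: consumer
# attack rate, e: conversion efficiency, m: consumer mortality. Each
# parameter may follow a thermal reaction norm; consumer genotypes
# differ in intercept (G at the reference temperature) and slope
# (thermal sensitivity; slope differences are GxE).

PARAM_FLOOR <- 1e-6

#' Thermal reaction norm
#'
#' Linear norms encode `value_at_ref + slope * (T - T_ref)`.
#' Quadratic-peak norms encode a hump-shaped response,
#' `value_at_ref + curvature * ((T - peak)^2 - (T_ref - peak)^2)`,
#' anchored so the value at `T_ref` equals `value_at_ref` (typical of
#' ectotherm growth rates, which rise then fall with temperature).
#'
#' @param value_at_ref Parameter value at the reference temperature.
#' @param slope Thermal sensitivity (parameter units per degree C);
#'   linear norms only.
#' @param form `"linear"` or `"quadratic-peak"`.
#' @param T_ref Reference temperature, degrees C (default 15).
#' @param peak_temperature Temperature of the maximum (quadratic-peak).
#' @param curvature Negative curvature of the peak (quadratic-peak).
#' @return An object of class `reaction_norm`.
#' @export
reaction_norm <- function(value_at_ref, slope = 0, form = c("linear", "quadratic-peak"),
                          T_ref = 15, peak_temperature = NULL, curvature = NULL) {
  form <- match.arg(form)
  if (form == "quadratic-peak") {
    if (is.null(peak_temperature) || is.null(curvature))
      stop("quadratic-peak norms need peak_temperature and curvature")
    if (curvature >= 0) stop("quadratic-peak curvature must be < 0")
  }
  structure(list(form = form, value_at_ref = value_at_ref, slope = slope,
                 T_ref = T_ref, peak_temperature = peak_temperature,
                 curvature = curvature),
            class = "reaction_norm")
}

#' Evaluate a reaction norm at a temperature
#'
#' Values are floored at a small positive constant (default 1e-6) so
#' that linear norms crossing zero stay biologically evaluable; a
#' flooring event raises a warning rather than an error.
#'
#' @param norm A [reaction_norm()].
#' @param T Temperature(s), degrees C.
#' @param floor Positive floor applied to the result.
#' @return Parameter value(s) at `T`; attribute `floored` flags floored
#'   entries.
#' @export
evaluate_norm <- function(norm, T, floor = PARAM_FLOOR) {
  stopifnot(inherits(norm, "reaction_norm"), all(is.finite(T)))
  v <- switch(norm$form,
    "linear" = norm$value_at_ref + norm$slope * (T - norm$T_ref),
    "quadratic-peak" = norm$value_at_ref + norm$curvature *
      ((T - norm$peak_temperature)^2 - (norm$T_ref - norm$peak_temperature)^2))
  fl <- v < floor
  if (any(fl)) {
    warning(sprintf("reaction norm floored at %g for %d temperature(s)",
                    floor, sum(fl)))
    v[fl] <- floor
    attr(v, "floored") <- fl
  }
  v
}

#' Consumer genotype
#'
#' Bundles the consumer's thermal reaction norms for attack rate `a`,
#' mortality `m` and conversion efficiency `e`. Genotypes constructed
#' with equal `value_at_ref` share the same phenotype at the reference
#' temperature; differing slopes are a GxE effect.
#'
#' @param id Genotype label (e.g. `"A"`).
#' @param norm_a,norm_m,norm_e [reaction_norm()]s for `a`, `m`, `e`.
#' @return An object of class `genotype`.
#' @export
genotype <- function(id, norm_a, norm_m, norm_e) {
  stopifnot(inherits(norm_a, "reaction_norm"),
            inherits(norm_m, "reaction_norm"),
            inherits(norm_e, "reaction_norm"))
  structure(list(id = as.character(id), norm_a = norm_a, norm_m = norm_m,
                 norm_e = norm_e),
            class = "genotype")
}

#' Resource thermal environment
#'
#' Reaction norms of the resource: intrinsic growth `r` (default a
#' quadratic peak — ectotherm growth rises then falls with temperature)
#' and carrying capacity `K` (default flat).
#'
#' @param norm_r,norm_K [reaction_norm()]s for `r` and `K`.
#' @param T_range Valid temperature range, degrees C.
#' @return An object of class `resource_environment`.
#' @export
resource_environment <- function(
    norm_r = reaction_norm(1, form = "quadratic-peak",
                           peak_temperature = 25, curvature = -0.002),
    norm_K = reaction_norm(10),
    T_range = c(5, 35)) {
  stopifnot(inherits(norm_r, "reaction_norm"),
            inherits(norm_K, "reaction_norm"),
            length(T_range) == 2L, T_range[1] < T_range[2])
  structure(list(norm_r = norm_r, norm_K = norm_K, T_range = T_range),
            class = "resource_environment")
}

#' Consumer-resource parameters at a temperature
#'
#' Evaluates all five model parameters for one genotype in one
#' environment at temperature `T`.
#'
#' @param g A [genotype()].
#' @param env A [resource_environment()].
#' @param T Temperature, degrees C, inside `env$T_range`.
#' @return An object of class `cr_params`: list with `r`, `K`, `a`, `e`,
#'   `m`, `T`, `genotype_id` and a `floored` flag.
#' @export
params_at <- function(g, env, T) {
  stopifnot(inherits(g, "genotype"), inherits(env, "resource_environment"))
  if (T < env$T_range[1] || T > env$T_range[2])
    stop(sprintf("temperature %g outside valid range [%g, %g]",
                 T, env$T_range[1], env$T_range[2]))
  vals <- withCallingHandlers({
    list(r = evaluate_norm(env$norm_r, T), K = evaluate_norm(env$norm_K, T),
         a = evaluate_norm(g$norm_a, T), e = evaluate_norm(g$norm_e, T),
         m = evaluate_norm(g$norm_m, T))
  }, warning = function(w) invokeRestart("muffleWarning"))
  floored <- any(vapply(vals, function(v) isTRUE(any(attr(v, "floored"))),
                        TRUE))
  cr_params(r = as.numeric(vals$r), K = as.numeric(vals$K),
            a = as.numeric(vals$a), e = as.numeric(vals$e),
            m = as.numeric(vals$m), T = T, genotype_id = g$id,
            floored = floored)
}

#' Consumer-resource parameter set
#'
#' @param r Resource intrinsic growth rate (per time).
#' @param K Resource carrying capacity (density).
#' @param a Consumer attack rate (per density per time).
#' @param e Conversion efficiency (dimensionless).
#' @param m Consumer mortality (per time).
#' @param T Temperature label (degrees C), optional.
#' @param genotype_id Genotype label, optional.
#' @param floored Whether any parameter was floored during evaluation.
#' @return An object of class `cr_params`.
#' @export
cr_params <- function(r, K, a, e, m, T = NA_real_,
                      genotype_id = NA_character_, floored = FALSE) {
  vals <- c(r = r, K = K, a = a, e = e, m = m)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all of r, K, a, e, m must be positive and finite")
  structure(list(r = r, K = K, a = a, e = e, m = m, T = T,
                 genotype_id = genotype_id, floored = floored),
            class = "cr_params")
}

#' @export
print.cr_params <- function(x, ...) {
  cat(sprintf(
    "Consumer-resource parameters%s%s:\n  r = %g, K = %g, a = %g, e = %g, m = %g\n",
    if (is.na(x$genotype_id)) "" else paste0(" (genotype ", x$genotype_id, ")"),
    if (is.na(x$T)) "" else sprintf(" at T = %g C", x$T),
    x$r, x$K, x$a, x$e, x$m))
  invisible(x)
}

#' Right-hand side of the consumer-resource system
#'
#' @param state Numeric vector `c(R, C)` of nonnegative densities.
#' @param p A [cr_params()].
#' @return Numeric vector `c(dR/dt, dC/dt)`.
#' @export
cr_rhs <- function(state, p) {
  stopifnot(inherits(p, "cr_params"), length(state) == 2L)
  if (any(state < 0)) stop("invalid state: densities must be nonnegative")
  R <- state[1]; C <- state[2]
  c(R * (p$r - (p$r / p$K) * R - p$a * C),
    C * (p$e * p$a * R - p$m))
}

#' Coexistence equilibrium
#'
#' Closed form: `R* = m / (e a)` and `C* = (r / a) (1 - R*/K)`.
#' Feasible when `R* < K` (equivalently `C* > 0`); infeasibility is
#' flagged, not an error.
#'
#' @param p A [cr_params()].
#' @return An object of class `cr_equilibrium`: list with `R_star`,
#'   `C_star`, `feasible`.
#' @export
equilibrium <- function(p) {
  stopifnot(inherits(p, "cr_params"))
  R_star <- p$m / (p$e * p$a)
  C_star <- (p$r / p$a) * (1 - R_star / p$K)
  structure(list(R_star = R_star, C_star = C_star,
                 feasible = R_star < p$K),
            class = "cr_equilibrium")
}

#' @export
print.cr_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium: R* = %g, C* = %g (%s)\n", x$R_star, x$C_star,
              if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Jacobian at the coexistence equilibrium
#'
#' Analytic linearization of [cr_rhs()] at `(R*, C*)`:
#' `[[-r R*/K, -a R*], [e a C*, 0]]`.
#'
#' @param p A [cr_params()].
#' @param eq Optional precomputed [equilibrium()]; must be feasible.
#' @return 2x2 numeric matrix.
#' @export
cr_jacobian <- function(p, eq = equilibrium(p)) {
  stopifnot(inherits(p, "cr_params"), inherits(eq, "cr_equilibrium"))
  if (!eq$feasible)
    stop("infeasible equilibrium: consumer cannot persist (R* >= K)")
  matrix(c(-p$r * eq$R_star / p$K, -p$a * eq$R_star,
           p$e * p$a * eq$C_star, 0),
         nrow = 2, byrow = TRUE)
}

#' Local stability and resilience
#'
#' Eigenvalues of the Jacobian at the coexistence equilibrium;
#' resilience is `-max(Re(lambda))`, the asymptotic rate of return to
#' equilibrium after a small perturbation (larger = more resilient).
#'
#' @param p A [cr_params()].
#' @return An object of class `cr_stability`: `eigenvalues` (complex
#'   pair), `lambda_max_real`, `resilience`, `stable`, and the
#'   equilibrium used.
#' @export
stability <- function(p) {
  eq <- equilibrium(p)
  J <- cr_jacobian(p, eq)
  ev <- eigen(J, only.values = TRUE)$values
  lmr <- max(Re(ev))
  structure(list(eigenvalues = ev, lambda_max_real = lmr,
                 resilience = -lmr, stable = lmr < 0, equilibrium = eq),
            class = "cr_stability")
}

#' @export
print.cr_stability <- function(x, ...) {
  cat(sprintf(
    "Stability: lambda_max = %g (%s), resilience -Re(lambda_max) = %g\n",
    x$lambda_max_real, if (x$stable) "stable" else "unstable",
    x$resilience))
  invisible(x)
}

#' Invasion fitness of a rare genotype
#'
#' Per-capita growth rate of a rare invader at the resident genotype's
#' ecological equilibrium: `s = e_inv * a_inv * R*_resident - m_inv`.
#' Positive `s` means the invader can spread.
#'
#' @param resident,invader [genotype()]s.
#' @param env A [resource_environment()].
#' @param T Temperature, degrees C.
#' @return Invasion fitness (per time).
#' @export
invasion_fitness <- function(resident, invader, env, T) {
  pr <- params_at(resident, env, T)
  eq <- equilibrium(pr)
  if (!eq$feasible)
    stop("infeasible resident: genotype ", resident$id,
         " has no coexistence equilibrium at T = ", T)
  pi <- params_at(invader, env, T)
  pi$e * pi$a * eq$R_star - pi$m
}

#' Genotype favoured by selection at a temperature
#'
#' Builds the full pairwise invasion-fitness matrix for a genotype panel
#' and identifies the genotype no other panel member can invade. In
#' this model that winner obeys the R* rule: it is the genotype
#' minimizing `R* = m / (e a)`, i.e. the one depressing the resource
#' furthest.
#'
#' @param panel List of [genotype()]s (unique ids).
#' @param env A [resource_environment()].
#' @param T Temperature, degrees C.
#' @param neutral_tol Two genotypes within this R* distance are treated
#'   as selectively neutral (tie broken to the lexicographically
#'   smaller id).
#' @return An object of class `invasion_result`: `fitness` matrix
#'   (rows = residents, columns = invaders), `favoured_genotype`,
#'   `R_star` per genotype (NA when infeasible), `neutral` flag.
#' @export
favoured_genotype <- function(panel, env, T, neutral_tol = 1e-9) {
  ids <- vapply(panel, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("genotype ids must be unique")
  n <- length(panel)
  R_star <- vapply(panel, function(g) {
    eq <- equilibrium(params_at(g, env, T))
    if (eq$feasible) eq$R_star else NA_real_
  }, numeric(1))
  if (all(is.na(R_star)))
    stop("no viable genotype: no panel member persists at T = ", T)
  s <- matrix(NA_real_, n, n, dimnames = list(resident = ids, invader = ids))
  for (i in seq_len(n)) {
    if (is.na(R_star[i])) next
    for (j in seq_len(n)) {
      pj <- params_at(panel[[j]], env, T)
      s[i, j] <- pj$e * pj$a * R_star[i] - pj$m
    }
  }
  ord <- order(R_star, ids, na.last = TRUE)
  best <- ord[1L]
  neutral <- sum(!is.na(R_star)) > 1L &&
    abs(R_star[ord[2L]] - R_star[best]) < neutral_tol
  structure(list(fitness = s, favoured_genotype = ids[best],
                 R_star = stats::setNames(R_star, ids), neutral = neutral),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("Favoured genotype: %s%s\n", x$favoured_genotype,
              if (x$neutral) " (neutral tie)" else ""))
  cat("R* by genotype:\n")
  print(round(x$R_star, 6))
  invisible(x)
}

#' Temperature at which two genotypes' R* curves cross
#'
#' Finds the roots of `R*_A(T) - R*_B(T)` on a temperature range by
#' bracketing on a fine grid followed by bisection
#' ([stats::uniroot()]). The favoured genotype switches at each such
#' crossing.
#'
#' @param gA,gB [genotype()]s.
#' @param env A [resource_environment()].
#' @param T_range Length-2 temperature range to search.
#' @param n_grid Number of bracketing grid points (default 512).
#' @param tol Root tolerance passed to [stats::uniroot()].
#' @return Sorted numeric vector of crossing temperatures; empty
#'   (length 0) if the difference never changes sign; `NA` with a
#'   `degenerate` attribute when the genotypes' R* curves coincide over
#'   the whole range (no isolated root).
#' @export
crossing_temperature <- function(gA, gB, env, T_range = env$T_range,
                                 n_grid = 512, tol = 1e-12) {
  dR <- function(T) {
    vapply(T, function(Ti) {
      eA <- equilibrium(params_at(gA, env, Ti))
      eB <- equilibrium(params_at(gB, env, Ti))
      eA$R_star - eB$R_star
    }, numeric(1))
  }
  Ts <- seq(T_range[1], T_range[2], length.out = n_grid)
  d <- dR(Ts)
  if (all(abs(d) < 1e-13)) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  roots <- numeric(0)
  for (k in seq_len(n_grid - 1L)) {
    if (d[k] == 0) { roots <- c(roots, Ts[k]); next }
    if (sign(d[k]) * sign(d[k + 1L]) < 0) {
      roots <- c(roots, stats::uniroot(dR, c(Ts[k], Ts[k + 1L]),
                                       tol = tol)$root)
    }
  }
  if (length(d) && d[n_grid] == 0) roots <- c(roots, Ts[n_grid])
  sort(unique(roots))
}

#' Sweep a genotype panel across a temperature grid
#'
#' For each temperature: evaluates each genotype's parameters,
#' equilibrium, stability and resilience, and marks the genotype
#' favoured by selection (the R* winner). Infeasible genotype-by-
#' temperature cells are flagged, not fatal.
#'
#' @param panel List of [genotype()]s.
#' @param env A [resource_environment()].
#' @param T_grid Nonempty temperature grid inside `env$T_range`.
#' @return An object of class `temperature_sweep`: data frame with
#'   columns `T`, `genotype_id`, `a`, `m`, `e`, `r`, `K`, `R_star`,
#'   `C_star`, `feasible`, `lambda_max_real`, `resilience`,
#'   `favoured`, `neutral`, `floored`.
#' @export
temperature_sweep <- function(panel, env, T_grid) {
  if (length(T_grid) < 1L) stop("temperature grid must be nonempty")
  rows <- list()
  for (T in T_grid) {
    fav <- tryCatch(favoured_genotype(panel, env, T), error = function(e) NULL)
    for (g in panel) {
      p <- params_at(g, env, T)
      eq <- equilibrium(p)
      st <- if (eq$feasible) stability(p) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        T = T, genotype_id = g$id, a = p$a, m = p$m, e = p$e,
        r = p$r, K = p$K, R_star = eq$R_star, C_star = eq$C_star,
        feasible = eq$feasible,
        lambda_max_real = if (is.null(st)) NA_real_ else st$lambda_max_real,
        resilience = if (is.null(st)) NA_real_ else st$resilience,
        favoured = !is.null(fav) && identical(fav$favoured_genotype, g$id),
        neutral = !is.null(fav) && fav$neutral,
        floored = p$floored,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            class = c("temperature_sweep", "data.frame"))
}

#' @export
print.temperature_sweep <- function(x, ...) {
  cat(sprintf("Temperature sweep: %d temperatures x %d genotypes\n",
              length(unique(x$T)), length(unique(x$genotype_id))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.temperature_sweep <- function(x, ...) {
  ids <- unique(x$genotype_id)
  cols <- stats::setNames(seq_along(ids) + 1L, ids)
  graphics::plot(range(x$T), range(x$resilience, na.rm = TRUE), type = "n",
                 xlab = "temperature (C)", ylab = "resilience -Re(lambda_max)")
  for (id in ids) {
    d <- x[x$genotype_id == id, ]
    graphics::lines(d$T, d$resilience, col = cols[id])
    graphics::points(d$T, d$resilience, col = cols[id],
                     pch = ifelse(d$favoured, 19, 1))
  }
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = ids, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate consumer-resource dynamics
#'
#' Numerically integrates the system with [deSolve::ode()] (lsoda,
#' relative tolerance 1e-8 by default). Densities are kept nonnegative
#' by clipping tiny negative integrator excursions at zero. Temperature
#' can vary over time by supplying a schedule: parameters are then
#' re-evaluated from the genotype and environment at each step.
#'
#' @param p A [cr_params()] (constant-parameter run), or `NULL` when
#'   using a schedule.
#' @param init Initial state `c(R, C)`, nonnegative.
#' @param times Output time points (numeric, increasing).
#' @param schedule Optional list `list(genotype =, env =, T_of_t =)`
#'   where `T_of_t(t)` returns the temperature at time `t`.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `cr_trajectory`: data frame `t`, `R`, `C`.
#' @export
simulate_trajectory <- function(p = NULL, init, times, schedule = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  if (any(init < 0)) stop("initial densities must be nonnegative")
  if (is.null(p) && is.null(schedule))
    stop("supply either constant parameters p or a temperature schedule")
  deriv <- function(t, y, parms) {
    pp <- if (is.null(schedule)) p else
      params_at(schedule$genotype, schedule$env, schedule$T_of_t(t))
    y <- pmax(y, 0)
    list(cr_rhs(y, pp))
  }
  sol <- deSolve::ode(y = c(R = init[1], C = init[2]), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("numerical failure: ODE integrator did not complete (istate = ",
         attr(sol, "istate")[1L], ")")
  out <- data.frame(t = sol[, "time"], R = pmax(sol[, "R"], 0),
                    C = pmax(sol[, "C"], 0))
  structure(out, class = c("cr_trajectory", "data.frame"))
}

#' @export
plot.cr_trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$R, x$C), type = "l", lty = 1,
                    col = c("darkgreen", "firebrick"),
                    xlab = "time", ylab = "density", ...)
  graphics::legend("topright", legend = c("resource R", "consumer C"),
                   col = c("darkgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Decompose parameter variance into G, E and GxE
#'
#' Evaluates one named parameter for every genotype at every temperature
#' of a complete grid and performs the exact two-way (population-
#' variance) decomposition: `V_G` is the variance of genotype means,
#' `V_E` the variance of temperature means, and `V_GxE` the variance of
#' the interaction residuals (cell - genotype mean - temperature mean +
#' grand mean). On a complete grid the three components sum to the
#' total variance of the cells. Parallel reaction norms (equal slopes)
#' give `V_GxE = 0` exactly.
#'
#' @param panel List of >= 2 [genotype()]s.
#' @param T_grid Grid of >= 2 temperatures.
#' @param parameter One of `"a"`, `"m"`, `"e"`.
#' @return An object of class `gxe_decomposition`: `V_G`, `V_E`,
#'   `V_GxE`, `V_total`, plus the value grid.
#' @export
decompose_variance <- function(panel, T_grid, parameter = c("a", "m", "e")) {
  parameter <- match.arg(parameter)
  if (length(panel) < 2L || length(T_grid) < 2L)
    stop("insufficient design: need >= 2 genotypes and >= 2 temperatures")
  norm_name <- paste0("norm_", parameter)
  vals <- vapply(panel, function(g)
    as.numeric(suppressWarnings(evaluate_norm(g[[norm_name]], T_grid))),
    numeric(length(T_grid)))
  # vals: temperatures in rows, genotypes in columns
  grand <- mean(vals)
  g_means <- colMeans(vals)
  t_means <- rowMeans(vals)
  resid <- vals - outer(t_means, rep(1, ncol(vals))) -
    outer(rep(1, nrow(vals)), g_means) + grand
  pvar <- function(v) mean((v - mean(v))^2)
  out <- list(V_G = pvar(g_means), V_E = pvar(t_means),
              V_GxE = mean(resid^2), V_total = pvar(as.numeric(vals)),
              parameter = parameter,
              values = vals, T_grid = T_grid,
              genotype_ids = vapply(panel, function(g) g$id, character(1)))
  structure(out, class = "gxe_decomposition")
}

#' @export
print.gxe_decomposition <- function(x, ...) {
  cat(sprintf(
    "Variance decomposition of '%s' (%d genotypes x %d temperatures):\n",
    x$parameter, length(x$genotype_ids), length(x$T_grid)))
  cat(sprintf("  V_G = %.6g  V_E = %.6g  V_GxE = %.6g  (total %.6g)\n",
              x$V_G, x$V_E, x$V_GxE, x$V_total))
  invisible(x)
}
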