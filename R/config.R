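# Configuration-driven runs: parse a YAML/JSON config, validate it
# strictly (unknown keys are rejected so typos cannot silently change a
# run), execute one subcommand, and write CSV outputs plus a JSON
# provenance block (config echo + package version + seed) so every run
# is re-runnable verbatim.

CONFIG_SCHEMA <- list(
  top = c("command", "seed", "output_dir", "community", "sigma2_grid",
          "epsilon", "panel", "environment", "T_grid", "decompose",
          "simulate", "compare"),
  community = c("n_prey", "mismatch_max", "density", "seed", "trait_mean",
                "consumer_density", "alpha_max", "tau_alpha", "eta_min",
                "tau_eta"),
  panel = c("n_genotypes", "base", "intercept_sd", "mean_slope",
            "slope_sd", "T_ref", "T_grid", "seed"),
  environment = c("r_value", "r_peak", "r_curvature", "K_value", "T_range"),
  decompose = c("parameter"),
  simulate = c("r", "K", "a", "e", "m", "init", "t_max", "n_steps"),
  compare = c("sigma2_a", "sigma2_b"))

COMMANDS <- c("intake-sweep", "rewire-compare", "temp-sweep", "decompose",
              "simulate", "make-fixture")

check_keys <- function(x, allowed, where, strict) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) && strict)
    stop("config validation error: unknown key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  invisible(x)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills documented defaults and
#' validates it. Validation is strict by default: unknown keys raise an
#' error naming them.
#'
#' @param path Path to a YAML or JSON config file.
#' @param strict Reject unknown keys (default `TRUE`).
#' @return An object of class `run_config` (a named list).
#' @export
load_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_run_config(cfg, strict = strict)
}

#' Build a validated run configuration from a list
#'
#' @param cfg Named list as produced by [load_config()] or in code.
#' @param strict Reject unknown keys (default `TRUE`).
#' @return An object of class `run_config`.
#' @export
as_run_config <- function(cfg, strict = TRUE) {
  check_keys(cfg, CONFIG_SCHEMA$top, "config", strict)
  if (is.null(cfg$command) || !cfg$command %in% COMMANDS)
    stop("config validation error: 'command' must be one of ",
         paste(COMMANDS, collapse = ", "))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$output_dir <- if (is.null(cfg$output_dir)) "." else cfg$output_dir
  for (sec in c("community", "panel", "environment", "decompose",
                "simulate", "compare"))
    if (!is.null(cfg[[sec]]))
      check_keys(cfg[[sec]], CONFIG_SCHEMA[[sec]], sec, strict)
  if (!is.null(cfg$sigma2_grid) && any(cfg$sigma2_grid < 0))
    stop("config validation error: sigma2_grid must be nonnegative")
  if (!is.null(cfg$epsilon) && cfg$epsilon < 0)
    stop("config validation error: epsilon must be nonnegative")
  structure(cfg, class = "run_config")
}

config_community <- function(cfg) {
  args <- if (is.null(cfg$community)) list() else cfg$community
  args$seed <- if (is.null(args$seed)) cfg$seed else args$seed
  do.call(make_mismatch_community, args)
}

config_panel <- function(cfg) {
  args <- if (is.null(cfg$panel)) list() else cfg$panel
  args$seed <- if (is.null(args$seed)) cfg$seed else args$seed
  do.call(make_genotype_panel, args)
}

config_environment <- function(cfg) {
  e <- if (is.null(cfg$environment)) list() else cfg$environment
  resource_environment(
    norm_r = reaction_norm(
      value_at_ref = if (is.null(e$r_value)) 1 else e$r_value,
      form = "quadratic-peak",
      peak_temperature = if (is.null(e$r_peak)) 25 else e$r_peak,
      curvature = if (is.null(e$r_curvature)) -0.002 else e$r_curvature),
    norm_K = reaction_norm(if (is.null(e$K_value)) 10 else e$K_value),
    T_range = if (is.null(e$T_range)) c(5, 35) else e$T_range)
}

write_provenance <- function(cfg, dir, files) {
  prov <- list(
    package = "ecorewire",
    version = as.character(utils::packageVersion("ecorewire")),
    seed = cfg$seed,
    command = cfg$command,
    config = unclass(cfg),
    outputs = files)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

write_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  path
}

#' Execute a configured run
#'
#' Dispatches on `config$command` and writes CSV outputs plus a
#' `provenance.json` into `config$output_dir`. Subcommands:
#' `intake-sweep` (trait-variance sweep tables and per-variance edge
#' lists), `rewire-compare` (link turnover between two variances),
#' `temp-sweep` (temperature sweep of a genotype panel), `decompose`
#' (G/E/GxE variance components), `simulate` (consumer-resource
#' trajectory), `make-fixture` (serializes the generated fixture
#' parameters back to a re-runnable YAML config).
#'
#' @param config A `run_config` (see [load_config()], [as_run_config()]).
#' @return Invisibly, a named list of written file paths.
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()

  if (config$command %in% c("intake-sweep", "rewire-compare", "make-fixture")) {
    fx <- config_community(config)
  }

  if (config$command == "intake-sweep") {
    grid <- if (is.null(config$sigma2_grid)) c(0.01, 7) else config$sigma2_grid
    sw <- variance_sweep(fx$community, fx$kernels, grid,
                         epsilon = config$epsilon)
    files$sweep <- write_csv(sw, file.path(dir, "intake_sweep.csv"))
    eps <- attr(sw, "epsilon")
    edges <- do.call(rbind, lapply(attr(sw, "profiles"), function(pr) {
      el <- edge_list(pr, eps)
      if (nrow(el)) cbind(sigma2 = attr(pr, "sigma2"), el) else NULL
    }))
    if (!is.null(edges))
      files$edges <- write_csv(edges, file.path(dir, "edge_list.csv"))
    prof <- do.call(rbind, lapply(attr(sw, "profiles"), function(pr)
      data.frame(prey_id = pr$prey_id, mismatch = pr$mismatch, f = pr$f,
                 sigma2 = attr(pr, "sigma2"))))
    files$profiles <- write_csv(prof, file.path(dir, "intake_profiles.csv"))
  } else if (config$command == "rewire-compare") {
    cmp_cfg <- if (is.null(config$compare))
      list(sigma2_a = 0.01, sigma2_b = 7) else config$compare
    pa <- intake_profile(fx$community,
                         trait_distribution(0, cmp_cfg$sigma2_a), fx$kernels)
    pb <- intake_profile(fx$community,
                         trait_distribution(0, cmp_cfg$sigma2_b), fx$kernels)
    eps <- if (is.null(config$epsilon)) 1e-3 * max(pa$f) else config$epsilon
    cmp <- compare_profiles(pa, pb, eps)
    files$delta <- write_csv(cmp$delta, file.path(dir, "rewire_delta.csv"))
    files$summary <- write_csv(
      data.frame(sigma2_a = cmp_cfg$sigma2_a, sigma2_b = cmp_cfg$sigma2_b,
                 epsilon = eps, n_gained = length(cmp$gained),
                 n_lost = length(cmp$lost), n_retained = length(cmp$retained),
                 jaccard_turnover = cmp$jaccard_turnover),
      file.path(dir, "rewire_summary.csv"))
  } else if (config$command == "temp-sweep") {
    pn <- config_panel(config)
    env <- config_environment(config)
    grid <- if (is.null(config$T_grid)) seq(5, 30, by = 1) else config$T_grid
    sw <- temperature_sweep(pn$panel, env, grid)
    files$sweep <- write_csv(sw, file.path(dir, "temperature_sweep.csv"))
  } else if (config$command == "decompose") {
    pn <- config_panel(config)
    par <- if (is.null(config$decompose$parameter)) "a"
           else config$decompose$parameter
    dec <- decompose_variance(pn$panel, pn$T_grid, par)
    files$decomposition <- write_csv(
      data.frame(parameter = par, V_G = dec$V_G, V_E = dec$V_E,
                 V_GxE = dec$V_GxE, V_total = dec$V_total),
      file.path(dir, "variance_decomposition.csv"))
  } else if (config$command == "simulate") {
    s <- config$simulate
    if (is.null(s)) stop("config validation error: 'simulate' section required")
    p <- cr_params(r = s$r, K = s$K, a = s$a, e = s$e, m = s$m)
    times <- seq(0, if (is.null(s$t_max)) 100 else s$t_max,
                 length.out = if (is.null(s$n_steps)) 501 else s$n_steps)
    tr <- simulate_trajectory(p, init = unlist(s$init), times = times)
    files$trajectory <- write_csv(tr, file.path(dir, "trajectory.csv"))
  } else if (config$command == "make-fixture") {
    fix <- list(command = "intake-sweep", seed = config$seed,
                community = if (is.null(config$community)) list()
                            else config$community)
    path <- file.path(dir, "fixture.yaml")
    yaml::write_yaml(fix, path)
    files$fixture <- path
    files$community <- write_csv(
      data.frame(id = fx$community$id, density = fx$community$density,
                 x_opt = fx$community$x_opt),
      file.path(dir, "community.csv"))
  }

  files$provenance <- write_provenance(config, dir, files)
  invisible(files)
}
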