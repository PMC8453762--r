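# Rewiring metrics: turn intake profiles into link counts, strength
# summaries, and turnover between scenarios. A trophic "link" is a prey
# whose intake rate exceeds a threshold epsilon; rewiring is the change
# in the set and strength of links between two scenarios (e.g. two
# levels of trait variance).

#' Count trophic links in an intake profile
#'
#' @param profile An [intake_profile()].
#' @param epsilon Link-strength threshold (>= 0); a prey counts as a
#'   link when `f_i > epsilon`.
#' @return Integer number of links.
#' @export
count_links <- function(profile, epsilon) {
  stopifnot(inherits(profile, "intake_profile"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("invalid threshold: epsilon must be a single nonnegative number")
  sum(profile$f > epsilon)
}

#' Summarize link structure of an intake profile
#'
#' @inheritParams count_links
#' @return An object of class `rewiring_summary`: a one-row data frame
#'   with `sigma2`, `epsilon`, `n_links`, `max_strength`,
#'   `mean_strength`, `total_intake`. Strength fields are `NA` when no
#'   link clears the threshold; `total_intake` sums all `f_i` regardless
#'   of the threshold.
#' @export
summarize_profile <- function(profile, epsilon) {
  n <- count_links(profile, epsilon)
  linked <- profile$f[profile$f > epsilon]
  out <- data.frame(
    sigma2 = attr(profile, "sigma2"),
    epsilon = epsilon,
    n_links = n,
    max_strength = if (n > 0) max(linked) else NA_real_,
    mean_strength = if (n > 0) mean(linked) else NA_real_,
    total_intake = sum(profile$f))
  structure(out, class = c("rewiring_summary", "data.frame"),
            link_ids = profile$prey_id[profile$f > epsilon])
}

#' Compare link sets between two intake profiles
#'
#' Quantifies rewiring between two scenarios computed on the same prey
#' community: which links were gained, lost or retained, the Jaccard
#' turnover `1 - |retained| / |union|`, and per-prey strength changes.
#'
#' @param a,b [intake_profile()]s over identical prey id sets.
#' @param epsilon Link threshold applied to both.
#' @return An object of class `rewiring_comparison` with elements
#'   `gained`, `lost`, `retained` (prey id vectors, from `a` to `b`),
#'   `jaccard_turnover`, and `delta` (data frame of per-prey strength
#'   changes `f_b - f_a`).
#' @export
compare_profiles <- function(a, b, epsilon) {
  stopifnot(inherits(a, "intake_profile"), inherits(b, "intake_profile"))
  if (!setequal(a$prey_id, b$prey_id))
    stop("incompatible profiles: prey id sets differ")
  la <- a$prey_id[a$f > epsilon]
  lb <- b$prey_id[b$f > epsilon]
  retained <- intersect(la, lb)
  un <- union(la, lb)
  turnover <- if (length(un) == 0) 0 else 1 - length(retained) / length(un)
  fb <- b$f[match(a$prey_id, b$prey_id)]
  structure(list(
    gained = setdiff(lb, la),
    lost = setdiff(la, lb),
    retained = retained,
    jaccard_turnover = turnover,
    delta = data.frame(prey_id = a$prey_id, f_a = a$f, f_b = fb,
                       delta = fb - a$f, stringsAsFactors = FALSE)),
    class = "rewiring_comparison")
}

#' @export
print.rewiring_comparison <- function(x, ...) {
  cat(sprintf(
    "Rewiring: %d gained, %d lost, %d retained; Jaccard turnover %.3f\n",
    length(x$gained), length(x$lost), length(x$retained),
    x$jaccard_turnover))
  invisible(x)
}

#' Sweep trait variance and summarize rewiring
#'
#' Computes an intake profile and its link summary for each value of a
#' trait-variance grid. On the mismatch-graded reference fixture (equal
#' densities, shared kernels, evenly spaced mismatch) the number of
#' links is nondecreasing and the maximum link strength nonincreasing
#' across the grid: more phenotypic variation yields more but weaker
#' interactions.
#'
#' @param comm A [prey_community()].
#' @param kernels A [kernel_set()] for `comm`.
#' @param sigma2_grid Nonempty vector of nonnegative trait variances.
#' @param epsilon Link threshold; `NULL` (default) uses `1e-3 * max(f)`
#'   at the smallest variance in the grid (a scale-free relative
#'   cutoff), recorded in the output.
#' @param trait_mean Predator trait mean (default 0).
#' @param ... Passed to [intake_profile()].
#' @return An object of class `variance_sweep`: a data frame with one
#'   [summarize_profile()] row per variance, plus the list of profiles
#'   in attribute `profiles`.
#' @export
variance_sweep <- function(comm, kernels, sigma2_grid, epsilon = NULL,
                           trait_mean = 0, ...) {
  if (length(sigma2_grid) < 1L)
    stop("sigma2 grid must be nonempty")
  if (any(sigma2_grid < 0))
    stop("invalid variance: sigma2 grid must be nonnegative")
  sigma2_grid <- sort(sigma2_grid)
  profiles <- lapply(sigma2_grid, function(s2)
    intake_profile(comm, trait_distribution(trait_mean, s2), kernels, ...))
  if (is.null(epsilon))
    epsilon <- 1e-3 * max(profiles[[1L]]$f)
  rows <- lapply(profiles, summarize_profile, epsilon = epsilon)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  structure(out, class = c("variance_sweep", "data.frame"),
            profiles = profiles, epsilon = epsilon)
}

#' @export
print.variance_sweep <- function(x, ...) {
  cat(sprintf("Variance sweep (%d sigma2 values, epsilon = %.4g)\n",
              nrow(x), attr(x, "epsilon")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.variance_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$sigma2, x$n_links, type = "b", pch = 19,
                 xlab = "trait variance sigma2", ylab = "number of links")
  graphics::plot(x$sigma2, x$max_strength, type = "b", pch = 19,
                 xlab = "trait variance sigma2", ylab = "max link strength")
  invisible(x)
}

#' Weighted edge list of a profile's links
#'
#' @inheritParams count_links
#' @param consumer_id Label for the consumer node.
#' @return Data frame `consumer_id`, `prey_id`, `weight` for links with
#'   `f_i > epsilon`.
#' @export
edge_list <- function(profile, epsilon, consumer_id = "consumer") {
  stopifnot(inherits(profile, "intake_profile"))
  keep <- profile$f > epsilon
  data.frame(consumer_id = consumer_id, prey_id = profile$prey_id[keep],
             weight = profile$f[keep], stringsAsFactors = FALSE)
}
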