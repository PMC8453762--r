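# Trait-integrated multispecies type II functional response.
#
# A predator population carries a quantitative trait x (e.g. body size)
# with Gaussian distribution p(x; mean, sigma2). Foraging performance on
# each prey peaks at a prey-specific optimum X_opt: attack rate is
# maximal and handling time minimal there, and both degrade with the
# phenotypic mismatch (x - X_opt)^2. The population mean intake on prey
# i integrates the multispecies type II response over the trait
# distribution:
#
#   f_i = int alpha_i(x) R_i C / (1 + sum_j alpha_j(x) eta_j(x) R_j) p(x) dx

#' Gaussian predator trait distribution
#'
#' @param mean Trait mean (trait units).
#' @param sigma2 Trait variance (trait units^2), must be >= 0. A
#'   variance at or below the degeneracy tolerance of
#'   [intake_rate()] is treated as a point mass there.
#' @return An object of class `trait_distribution`.
#' @examples
#' trait_distribution(mean = 0, sigma2 = 1)
#' @export
trait_distribution <- function(mean = 0, sigma2 = 1) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2))
  if (sigma2 < 0)
    stop("invalid variance: sigma2 must be >= 0, got ", sigma2)
  structure(list(mean = mean, sigma2 = sigma2),
            class = "trait_distribution")
}

#' @export
print.trait_distribution <- function(x, ...) {
  cat(sprintf("Trait distribution: Gaussian(mean = %g, sigma2 = %g)\n",
              x$mean, x$sigma2))
  invisible(x)
}

#' Trait density
#'
#' Density of the predator trait distribution at trait value `x`.
#'
#' @param x Trait value(s).
#' @param dist A [trait_distribution()]; requires `sigma2 > 0`.
#' @return Nonnegative density value(s).
#' @export
trait_density <- function(x, dist) {
  stopifnot(inherits(dist, "trait_distribution"))
  if (dist$sigma2 <= 0)
    stop("invalid variance: trait_density requires sigma2 > 0 ",
         "(point masses are handled by intake_rate's degenerate branch)")
  stats::dnorm(x, mean = dist$mean, sd = sqrt(dist$sigma2))
}

#' Attack-rate kernel
#'
#' Gaussian-shaped attack rate, maximal at the prey's trait optimum:
#' `alpha(x) = alpha_max * exp(-(x - x_opt)^2 / (2 * tau^2))`.
#' The functional form is pluggable via `shape`, a function of the
#' mismatch `(x - x_opt)^2` returning a multiplier in (0, 1] that must
#' equal 1 at zero mismatch and decrease with mismatch.
#'
#' @param alpha_max Maximum attack rate (area per predator per time), > 0.
#' @param tau Kernel width (trait units), > 0.
#' @param x_opt Trait optimum for this prey.
#' @param shape Optional replacement mismatch multiplier.
#' @return An object of class `attack_kernel`; call it via [attack_rate()].
#' @export
attack_kernel <- function(alpha_max = 1, tau = 1, x_opt = 0, shape = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("invalid kernel: attack width tau must be > 0")
  if (!is.numeric(alpha_max) || alpha_max <= 0)
    stop("invalid kernel: alpha_max must be > 0")
  log_shape <- NULL
  if (is.null(shape)) {
    t2 <- tau^2
    shape <- function(mismatch) exp(-mismatch / (2 * t2))
    log_shape <- function(mismatch) -mismatch / (2 * t2)
  } else {
    log_shape <- function(mismatch) log(shape(mismatch))
  }
  structure(list(alpha_max = alpha_max, tau = tau, x_opt = x_opt,
                 shape = shape, log_shape = log_shape),
            class = "attack_kernel")
}

#' Handling-time kernel
#'
#' Handling time minimal at the prey's trait optimum and inflating
#' exponentially with mismatch:
#' `eta(x) = eta_min * exp((x - x_opt)^2 / (2 * tau^2))`.
#'
#' @param eta_min Minimum handling time (time units), > 0.
#' @param tau Kernel width (trait units), > 0.
#' @param x_opt Trait optimum for this prey.
#' @param shape Optional replacement mismatch multiplier (>= 1, equal to
#'   1 at zero mismatch, increasing with mismatch).
#' @return An object of class `handling_kernel`; call via [handling_time()].
#' @export
handling_kernel <- function(eta_min = 1, tau = 1, x_opt = 0, shape = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("invalid kernel: handling width tau must be > 0")
  if (!is.numeric(eta_min) || eta_min <= 0)
    stop("invalid kernel: eta_min must be > 0")
  log_shape <- NULL
  if (is.null(shape)) {
    t2 <- tau^2
    shape <- function(mismatch) exp(mismatch / (2 * t2))
    log_shape <- function(mismatch) mismatch / (2 * t2)
  } else {
    log_shape <- function(mismatch) log(shape(mismatch))
  }
  structure(list(eta_min = eta_min, tau = tau, x_opt = x_opt,
                 shape = shape, log_shape = log_shape),
            class = "handling_kernel")
}

#' Attack rate at a trait value
#' @param x Trait value(s).
#' @param k An [attack_kernel()].
#' @return Attack rate(s), positive for all finite `x`.
#' @export
attack_rate <- function(x, k) {
  stopifnot(inherits(k, "attack_kernel"))
  k$alpha_max * k$shape((x - k$x_opt)^2)
}

#' Handling time at a trait value
#' @param x Trait value(s).
#' @param k A [handling_kernel()].
#' @return Handling time(s), >= `eta_min` everywhere.
#' @export
handling_time <- function(x, k) {
  stopifnot(inherits(k, "handling_kernel"))
  k$eta_min * k$shape((x - k$x_opt)^2)
}

#' Prey community
#'
#' A set of prey, each with a density and a trait optimum, plus the
#' predator (consumer) density. Units are dimensionless simulation
#' units throughout.
#'
#' @param id Unique prey labels.
#' @param density Prey densities `R_i` (> 0), recycled to length of `id`.
#' @param x_opt Per-prey trait optima `X_opt_i`.
#' @param consumer_density Predator density `C` (> 0).
#' @return An object of class `prey_community`.
#' @export
prey_community <- function(id, density, x_opt, consumer_density = 1) {
  id <- as.character(id)
  n <- length(id)
  if (n < 1L) stop("prey community must contain at least one prey")
  if (anyDuplicated(id)) stop("prey ids must be unique")
  density <- rep_len(as.numeric(density), n)
  x_opt <- rep_len(as.numeric(x_opt), n)
  if (any(!is.finite(density)) || any(density <= 0))
    stop("prey densities must be positive and finite")
  if (!is.numeric(consumer_density) || consumer_density <= 0)
    stop("consumer density must be > 0")
  structure(list(id = id, density = density, x_opt = x_opt,
                 consumer_density = consumer_density),
            class = "prey_community")
}

#' @export
print.prey_community <- function(x, ...) {
  cat(sprintf("Prey community: %d prey, consumer density %g\n",
              length(x$id), x$consumer_density))
  print(data.frame(id = x$id, density = x$density, x_opt = x$x_opt),
        row.names = FALSE)
  invisible(x)
}

#' Per-prey kernel set
#'
#' Pairs each prey with its attack and handling kernels. Kernel
#' parameters default to shared values across prey while each prey keeps
#' its own optimum; pass lists of kernels to override per prey.
#'
#' @param comm A [prey_community()].
#' @param alpha_max,tau_alpha Shared attack kernel parameters.
#' @param eta_min,tau_eta Shared handling kernel parameters.
#' @param attack,handling Optional lists of per-prey kernels (same
#'   length as the community); when given they take precedence.
#' @return An object of class `kernel_set`: lists `attack` and
#'   `handling` of per-prey kernels.
#' @export
kernel_set <- function(comm, alpha_max = 1, tau_alpha = 1,
                       eta_min = 1, tau_eta = 1,
                       attack = NULL, handling = NULL) {
  stopifnot(inherits(comm, "prey_community"))
  n <- length(comm$id)
  if (is.null(attack))
    attack <- lapply(comm$x_opt, function(xo)
      attack_kernel(alpha_max, tau_alpha, xo))
  if (is.null(handling))
    handling <- lapply(comm$x_opt, function(xo)
      handling_kernel(eta_min, tau_eta, xo))
  if (length(attack) != n || length(handling) != n)
    stop("kernel lists must match the number of prey (", n, ")")
  stopifnot(all(vapply(attack, inherits, TRUE, "attack_kernel")),
            all(vapply(handling, inherits, TRUE, "handling_kernel")))
  structure(list(attack = attack, handling = handling),
            class = "kernel_set")
}

# Bracketed term of the intake integrand for prey i, vectorized over x:
# alpha_i(x) R_i C / (1 + sum_j alpha_j(x) eta_j(x) R_j)
# The alpha * eta product is formed in log space: at extreme mismatch
# the attack rate underflows while the handling time overflows, and the
# naive product would be 0 * Inf = NaN.
intake_integrand <- function(x, i, comm, kernels) {
  denom <- rep(1, length(x))
  for (j in seq_along(comm$id)) {
    ka <- kernels$attack[[j]]; kh <- kernels$handling[[j]]
    lp <- log(ka$alpha_max) + ka$log_shape((x - ka$x_opt)^2) +
      log(kh$eta_min) + kh$log_shape((x - kh$x_opt)^2)
    denom <- denom + exp(lp) * comm$density[j]
  }
  attack_rate(x, kernels$attack[[i]]) * comm$density[i] *
    comm$consumer_density / denom
}

#' Mean intake rate on one prey
#'
#' Integrates the multispecies type II functional response for prey `i`
#' over the predator trait distribution, by Gauss-Hermite quadrature in
#' the standardized trait. When `sigma2` is at or below the degeneracy
#' tolerance the point-mass limit (the response evaluated at the trait
#' mean) is returned instead.
#'
#' @param i Prey index (1-based) into `comm`.
#' @param comm A [prey_community()].
#' @param dist A [trait_distribution()].
#' @param kernels A [kernel_set()] for `comm`.
#' @param nodes Number of Gauss-Hermite nodes (default 256).
#' @param degenerate_tol Variance at or below this routes to the
#'   point-mass branch (default 1e-12).
#' @param adaptive Use adaptive quadrature on `mean +/- 8*sigma` instead
#'   of Gauss-Hermite (fallback for sharply varying integrands).
#' @return Intake rate `f_i` (prey per time per area), with
#'   `0 <= f_i <= alpha_max_i * R_i * C`.
#' @export
intake_rate <- function(i, comm, dist, kernels, nodes = 256,
                        degenerate_tol = 1e-12, adaptive = FALSE) {
  stopifnot(inherits(comm, "prey_community"),
            inherits(dist, "trait_distribution"),
            inherits(kernels, "kernel_set"))
  n <- length(comm$id)
  if (i < 1L || i > n) stop("prey index out of range")
  if (length(kernels$attack) != n)
    stop("kernel set does not match community size")
  s2 <- dist$sigma2
  if (s2 < 0) stop("invalid variance: sigma2 must be >= 0")
  if (s2 <= degenerate_tol)
    return(intake_integrand(dist$mean, i, comm, kernels))
  sd <- sqrt(s2)
  if (adaptive) {
    f <- stats::integrate(function(x)
      intake_integrand(x, i, comm, kernels) * trait_density(x, dist),
      lower = dist$mean - 8 * sd, upper = dist$mean + 8 * sd,
      rel.tol = 1e-10, subdivisions = 400L)$value
  } else {
    gh <- gauss_hermite_nodes(nodes)
    x <- dist$mean + sqrt(2) * sd * gh$x
    f <- sum(gh$w * intake_integrand(x, i, comm, kernels)) / sqrt(pi)
  }
  if (!is.finite(f))
    stop("numerical failure: intake quadrature returned non-finite value ",
         "(prey ", comm$id[i], ", sigma2 = ", s2, ")")
  f
}

# cache Gauss-Hermite rules by node count (physicists' weight exp(-x^2))
gh_cache <- new.env(parent = emptyenv())
gauss_hermite_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]]))
    gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

#' Intake profile across the whole community
#'
#' Computes `f_i` for every prey and reports them ordered by
#' nondecreasing phenotypic mismatch `(mean - X_opt_i)^2` relative to
#' the predator trait mean.
#'
#' @inheritParams intake_rate
#' @return An object of class `intake_profile`: a data frame with
#'   columns `prey_id`, `x_opt`, `mismatch`, `density`, `f`, sorted by
#'   mismatch, with the trait variance, kernels and community recorded
#'   as attributes.
#' @export
intake_profile <- function(comm, dist, kernels, nodes = 256,
                           degenerate_tol = 1e-12, adaptive = FALSE) {
  n <- length(comm$id)
  f <- vapply(seq_len(n), intake_rate, numeric(1),
              comm = comm, dist = dist, kernels = kernels, nodes = nodes,
              degenerate_tol = degenerate_tol, adaptive = adaptive)
  mism <- (dist$mean - comm$x_opt)^2
  ord <- order(mism, comm$id)
  out <- data.frame(prey_id = comm$id[ord], x_opt = comm$x_opt[ord],
                    mismatch = mism[ord], density = comm$density[ord],
                    f = f[ord], stringsAsFactors = FALSE)
  structure(out, class = c("intake_profile", "data.frame"),
            sigma2 = dist$sigma2, trait_mean = dist$mean,
            community = comm, kernels = kernels)
}

#' @export
print.intake_profile <- function(x, ...) {
  cat(sprintf(
    "Intake profile (sigma2 = %g, %d prey, ordered by mismatch)\n",
    attr(x, "sigma2"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.intake_profile <- function(x, ...) {
  graphics::plot(x$mismatch, x$f, type = "b", pch = 19,
                 xlab = "phenotypic mismatch (x - X_opt)^2",
                 ylab = "intake rate f_i",
                 main = sprintf("sigma2 = %g", attr(x, "sigma2")), ...)
  invisible(x)
}
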