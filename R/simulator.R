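#' Build a discrete random fiber network
#'
#' Samples `n_fibers` straight fibers with orientations i.i.d. uniform on
#' `[0, pi/2]` (the in-plane random-layup assumption, folded by symmetry)
#' and diameters i.i.d. lognormal. Lognormal is chosen for its positive
#' support and the right skew typical of electrospun mats; `sigma_ln = 0`
#' gives the degenerate all-equal-diameter network used for exact oracle
#' comparisons. Regeneration from the same seed is bit-identical.
#'
#' @param n_fibers number of fibers (>= 1).
#' @param mu_ln lognormal log-scale parameter (log nm).
#' @param sigma_ln lognormal shape parameter (>= 0).
#' @param seed integer RNG seed (required; seeds are explicit, never global).
#' @return an object of class `fiber_network` with fields `theta`, `d`,
#'   `seed`, `provenance`.
#' @export
build_network <- function(n_fibers, mu_ln, sigma_ln, seed) {
  if (!is.numeric(n_fibers) || length(n_fibers) != 1L || n_fibers < 1)
    stop_domain("n_fibers must be >= 1")
  check_scalar(mu_ln, "mu_ln")
  check_scalar(sigma_ln, "sigma_ln", lower = 0)
  n_fibers <- as.integer(n_fibers)
  draws <- with_seed(seed, {
    theta <- stats::runif(n_fibers, 0, pi / 2)
    d <- if (sigma_ln == 0) rep(exp(mu_ln), n_fibers)
         else stats::rlnorm(n_fibers, meanlog = mu_ln, sdlog = sigma_ln)
    list(theta = theta, d = d)
  })
  structure(list(
    theta = draws$theta, d = draws$d, seed = as.integer(seed),
    provenance = list(n_fibers = n_fibers, mu_ln = mu_ln,
                      sigma_ln = sigma_ln, orientation = "uniform[0, pi/2]")
  ), class = "fiber_network")
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf(
    "<fiber_network> %d fibers, seed %d, d ~ lognormal(%.4g, %.4g) nm\n",
    length(x$theta), x$seed, x$provenance$mu_ln, x$provenance$sigma_ln))
  invisible(x)
}

#' Discrete-fiber Monte-Carlo membrane simulation
#'
#' Independent oracle for the analytic membrane model: instead of the
#' orientation integral, every fiber of the network is deformed, clamped and
#' projected individually, and the unit-cell force is the literal sum
#' `(n_model / n_fibers) * sum(f_y)` with `n_model` from [fiber_count()].
#' Each fiber's *own* diameter enters both the force cross-section and the
#' `(1 + d/D)/2` stress correction (`D` taken from the spec), so for
#' dispersed diameters the simulation also stress-tests the analytic model's
#' `d = D` aggregation choice; with equal diameters (`sigma_ln = 0`,
#' `d = D`) the two routes share the same expectation and differ only by
#' Monte-Carlo error in orientation.
#'
#' @param network a [build_network()] result.
#' @param spec a [membrane_spec()].
#' @param params a [fiber_law()].
#' @param strain_grid non-negative, strictly increasing strain values.
#' @param clamp logical; clamp compressive/negative-law fibers to zero force.
#' @return a [stress_strain_curve()] of simulated membrane stress, with a
#'   `se_mpa` column giving the Monte-Carlo standard error at each strain.
#' @export
simulate_tension <- function(network, spec, params, strain_grid, clamp = TRUE) {
  stopifnot(inherits(network, "fiber_network"),
            inherits(spec, "membrane_spec"),
            inherits(params, "fiber_law"))
  if (!is.numeric(strain_grid) || any(strain_grid < 0) ||
      (length(strain_grid) > 1L && any(diff(strain_grid) <= 0)))
    stop_domain("strain_grid must be non-negative and strictly increasing")
  n_mc <- length(network$theta)
  n_model <- fiber_count(spec)
  scale <- n_model / (n_mc * spec$A)
  corr <- 0.5 * (1 + network$d / spec$D)
  stress <- se <- numeric(length(strain_grid))
  for (i in seq_along(strain_grid)) {
    state <- deformation_state(strain_grid[i], spec$v, spec$v_convention)
    eps_f <- fiber_axial_strain(network$theta, state)
    theta_p <- reorient_angle(network$theta, state)
    if (clamp) {
      sigma <- numeric(n_mc)
      active <- eps_f > 0
      if (any(active)) sigma[active] <- pmax(0, law_raw(params, eps_f[active]))
    } else {
      sigma <- law_raw(params, eps_f)
    }
    f_y <- (pi / 4) * network$d^2 * corr * sigma * sin(theta_p)
    stress[i] <- scale * sum(f_y)
    se[i] <- n_model / spec$A * stats::sd(f_y) / sqrt(n_mc)
  }
  out <- stress_strain_curve(strain_grid, stress)
  out$se_mpa <- se
  out
}

#' Synthetic noisy single-fiber tensile curve
#'
#' Fixture generator emulating a measured single-nanofiber stress-strain
#' record: the clamped logarithmic law evaluated on an equispaced strain
#' grid plus i.i.d. Gaussian noise. Reproducible by seed.
#'
#' @param params a [fiber_law()].
#' @param noise_sd Gaussian noise standard deviation (MPa, >= 0).
#' @param n_points number of strain points (>= 4).
#' @param strain_range length-2 vector, strain interval (within the law's
#'   domain, `min >= 0`).
#' @param seed integer RNG seed.
#' @return a [stress_strain_curve()].
#' @export
generate_synthetic_fiber_curve <- function(params, noise_sd, n_points,
                                           strain_range, seed) {
  stopifnot(inherits(params, "fiber_law"))
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (!is.numeric(n_points) || n_points < 4)
    stop_domain("n_points must be >= 4")
  if (!is.numeric(strain_range) || length(strain_range) != 2L ||
      strain_range[1] < 0 || strain_range[2] <= strain_range[1])
    stop_domain("strain_range must be an increasing non-negative interval")
  grid <- seq(strain_range[1], strain_range[2], length.out = as.integer(n_points))
  stress <- evaluate_fiber_stress(params, grid)
  noise <- with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  stress_strain_curve(grid, stress + noise)
}

#' Synthetic fiber diameter sample
#'
#' Lognormal diameter sample emulating SEM-based diameter measurements of
#' electrospun mats (means around 60-100 nm for the defaults used in the
#' examples). Reproducible by seed.
#'
#' @param mu_ln lognormal log-scale parameter (log nm).
#' @param sigma_ln lognormal shape parameter (>= 0).
#' @param n sample size (>= 1).
#' @param seed integer RNG seed.
#' @return numeric vector of diameters (nm).
#' @export
generate_diameter_sample <- function(mu_ln, sigma_ln, n, seed) {
  check_scalar(mu_ln, "mu_ln")
  check_scalar(sigma_ln, "sigma_ln", lower = 0)
  if (!is.numeric(n) || n < 1) stop_domain("n must be >= 1")
  with_seed(seed, {
    if (sigma_ln == 0) rep(exp(mu_ln), as.integer(n))
    else stats::rlnorm(as.integer(n), meanlog = mu_ln, sdlog = sigma_ln)
  })
}
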