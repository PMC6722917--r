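# Raw law evaluation used inside the orientation integral: fiber axial
# strains can be negative (transverse shrinkage), which the public
# evaluate_fiber_stress() rejects; only the logarithm domain is enforced here.
law_raw <- function(params, eps_f) {
  if (any(eps_f + params$c <= 0))
    stop_domain("fiber strain + c must be positive (logarithm domain)")
  params$a - params$b * log(eps_f + params$c)
}

#' Axial force contribution of a single fiber
#'
#' A fiber of diameter `d` carrying axial stress `sigma_f` at deformed angle
#' `theta_p` contributes `(pi/4) d^2 sigma_f sin(theta_p)` to the force along
#' the stretch axis.
#'
#' @param d fiber diameter (nm, > 0).
#' @param sigma_f axial fiber stress (MPa, >= 0).
#' @param theta_p deformed inclination angle (radians in `[0, pi/2]`).
#' @return force in MPa * nm^2.
#' @export
fiber_force_y <- function(d, sigma_f, theta_p) {
  if (any(d <= 0)) stop_domain("d must be positive")
  if (any(sigma_f < 0)) stop_domain("sigma_f must be non-negative")
  check_theta(theta_p)
  (pi / 4) * d^2 * sigma_f * sin(theta_p)
}

# Per-fiber axial force as a function of the *initial* angle theta, chaining
# reorientation -> fiber strain -> (clamped) law -> force projection.
# corr_factor multiplies the law (1 for the d = D choice).
force_integrand <- function(theta, state, params, D, corr_factor, clamp) {
  eps_f <- fiber_axial_strain(theta, state)
  theta_p <- reorient_angle(theta, state)
  if (clamp) {
    # buckled fibers (eps_f <= 0) carry nothing; evaluate the law only on
    # the tensile set so its logarithm never sees eps_f + c <= 0
    sigma <- numeric(length(eps_f))
    active <- eps_f > 0
    if (any(active)) sigma[active] <- pmax(0, law_raw(params, eps_f[active]))
  } else {
    sigma <- law_raw(params, eps_f)
  }
  (pi / 4) * D^2 * corr_factor * sigma * sin(theta_p)
}

# Panel boundaries where the clamp switches the integrand on/off. eps_f is
# monotone in theta for any admissible state, so each fiber-strain threshold
# maps to at most one angle.
clamp_breakpoints <- function(state, params) {
  thresholds <- 0
  if (params$b != 0) {
    x0 <- exp(params$a / params$b) - params$c  # zero of the raw law
    if (is.finite(x0)) thresholds <- c(thresholds, x0)
  }
  e0 <- fiber_axial_strain(0, state)
  e1 <- fiber_axial_strain(pi / 2, state)
  lo <- min(e0, e1); hi <- max(e0, e1)
  breaks <- numeric(0)
  for (t in thresholds) {
    if (t > lo && t < hi) {
      root <- stats::uniroot(function(th) fiber_axial_strain(th, state) - t,
                             lower = 0, upper = pi / 2, tol = 1e-14)$root
      breaks <- c(breaks, root)
    }
  }
  sort(unique(breaks))
}

gauss_rule <- function(f, a, b, order) {
  gl <- pracma::gaussLegendre(order, a, b)
  sum(gl$w * f(gl$x))
}

# Adaptive bisection on one panel: the clamped law has a steep boundary
# layer just above the clamp angle (the logarithm's branch point lies a few
# 1e-4 in fiber strain below the panel edge), which a single fixed-order
# rule resolves poorly.
adaptive_gauss <- function(f, a, b, order, tol, depth = 40L) {
  whole <- gauss_rule(f, a, b, order)
  halves <- gauss_rule(f, a, (a + b) / 2, order) +
            gauss_rule(f, (a + b) / 2, b, order)
  if (abs(halves - whole) <= tol || depth <= 0L) return(halves)
  adaptive_gauss(f, a, (a + b) / 2, order, tol / 2, depth - 1L) +
    adaptive_gauss(f, (a + b) / 2, b, order, tol / 2, depth - 1L)
}

gauss_panels <- function(f, breaks, order) {
  edges <- c(0, breaks, pi / 2)
  crude <- 0
  for (i in seq_len(length(edges) - 1L)) {
    if (edges[i + 1L] - edges[i] < .Machine$double.eps) next
    crude <- crude + abs(gauss_rule(f, edges[i], edges[i + 1L], order))
  }
  tol <- 1e-13 * max(crude, 1)
  total <- 0
  for (i in seq_len(length(edges) - 1L)) {
    if (edges[i + 1L] - edges[i] < .Machine$double.eps) next
    total <- total + adaptive_gauss(f, edges[i], edges[i + 1L], order, tol)
  }
  total
}

#' Orientation-averaged axial fiber force
#'
#' Computes `(2/pi) * integral_0^{pi/2} f_y(theta) d theta`, the mean force
#' along the stretch axis over a uniformly oriented fiber population, by
#' Gauss-Legendre quadrature. The integrand chains [reorient_angle()],
#' [fiber_axial_strain()], the (clamped) fiber law and [fiber_force_y()],
#' evaluated at the harmonic mean diameter `D` of the spec. The integration
#' interval is split at the angles where the clamp activates (found by root
#' bracketing on the monotone fiber strain), so each quadrature panel sees a
#' smooth integrand; the result is verified against a doubled-order rule and
#' an error is raised if the two disagree.
#'
#' @param strain applied membrane strain (>= 0).
#' @param spec a [membrane_spec()].
#' @param params a [fiber_law()].
#' @param clamp logical; clamp fibers in compression and negative law values
#'   to zero force (default `TRUE`).
#' @param order Gauss-Legendre order per panel (default 64).
#' @param correction `"harmonic"` evaluates every fiber at `d = D`
#'   (correction factor 1, the default); `"expected"` multiplies by the
#'   population-expected factor `(1 + d_bar/D)/2`, which requires `mean_d_nm`
#'   in the spec.
#' @return mean axial force per fiber, MPa * nm^2.
#' @export
mean_fiber_force <- function(strain, spec, params, clamp = TRUE, order = 64,
                             correction = c("harmonic", "expected")) {
  stopifnot(inherits(spec, "membrane_spec"), inherits(params, "fiber_law"))
  correction <- match.arg(correction)
  corr_factor <- switch(correction,
    harmonic = 1,
    expected = {
      if (is.null(spec$d_bar))
        stop_domain("'expected' correction needs mean_d_nm in the membrane spec")
      0.5 * (1 + spec$d_bar / spec$D)
    })
  state <- deformation_state(strain, spec$v, spec$v_convention)
  f <- function(th) force_integrand(th, state, params, spec$D, corr_factor, clamp)
  breaks <- if (clamp) clamp_breakpoints(state, params) else numeric(0)
  v1 <- gauss_panels(f, breaks, order)
  v2 <- gauss_panels(f, breaks, 2L * order)
  if (abs(v2 - v1) > max(1e-6 * abs(v2), 1e-12))
    stop_domain(sprintf(
      "quadrature did not converge: order %d gives %.12g, order %d gives %.12g",
      order, v1, 2L * order, v2))
  (2 / pi) * v1
}

#' Total axial force and membrane stress at one strain
#'
#' Scales the orientation-averaged fiber force by the unit-cell fiber count
#' (`F_y = n * f_bar_y`) and converts to membrane stress through the slab
#' convention `sigma = F_y / A`.
#'
#' @inheritParams mean_fiber_force
#' @return an object of class `force_summary` with fields `f_bar_y`, `F_y`,
#'   `sigma_membrane` (MPa) and `strain`.
#' @export
total_force <- function(strain, spec, params, clamp = TRUE, order = 64,
                        correction = c("harmonic", "expected")) {
  f_bar <- mean_fiber_force(strain, spec, params, clamp = clamp,
                            order = order, correction = correction)
  n <- fiber_count(spec)
  F_y <- n * f_bar
  structure(list(f_bar_y = f_bar, F_y = F_y,
                 sigma_membrane = F_y / spec$A, strain = strain),
            class = "force_summary")
}

#' @export
print.force_summary <- function(x, ...) {
  cat(sprintf(
    "<force_summary> strain %.4g: f_bar_y = %.6g MPa*nm^2, F_y = %.6g MPa*nm^2, sigma = %.6g MPa\n",
    x$strain, x$f_bar_y, x$F_y, x$sigma_membrane))
  invisible(x)
}

#' Predicted membrane stress-strain curve
#'
#' Evaluates the membrane model on a strain grid: for each strain the fiber
#' population is affinely reoriented, each orientation's axial force is
#' computed from the fitted single-fiber law, the forces are averaged over
#' orientation and scaled by porosity and fiber count. Deterministic.
#'
#' @inheritParams mean_fiber_force
#' @param strain_grid non-negative, strictly increasing strain values.
#' @return a [stress_strain_curve()] of predicted membrane stress (MPa).
#' @export
predict_stress_strain <- function(spec, params, strain_grid, clamp = TRUE,
                                  order = 64,
                                  correction = c("harmonic", "expected")) {
  if (!is.numeric(strain_grid) || length(strain_grid) == 0L)
    stop_domain("strain_grid must be non-empty numeric")
  if (any(strain_grid < 0) ||
      (length(strain_grid) > 1L && any(diff(strain_grid) <= 0)))
    stop_domain("strain_grid must be non-negative and strictly increasing")
  sigma <- vapply(strain_grid, function(e)
    total_force(e, spec, params, clamp = clamp, order = order,
                correction = correction)$sigma_membrane, numeric(1))
  stress_strain_curve(strain_grid, sigma)
}
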