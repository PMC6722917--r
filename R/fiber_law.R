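#' Single-fiber constitutive parameters
#'
#' Holds the fitted parameters of the logarithmic single-fiber law
#' \eqn{\sigma(\varepsilon) = a - b\,\ln(\varepsilon + c)} with stress in MPa
#' and strain dimensionless. `b` is stored exactly as fitted (negative for a
#' hardening fiber) and is never re-signed; `c` must be strictly positive so
#' the logarithm is defined at zero strain.
#'
#' @param a stress scale (MPa).
#' @param b stress slope (MPa); negative values give a law that stiffens with
#'   strain.
#' @param c strain offset (dimensionless, > 0).
#' @return an object of class `fiber_law`.
#' @export
fiber_law <- function(a, b, c) {
  check_scalar(a, "a")
  check_scalar(b, "b")
  check_scalar(c, "c", lower = 0, strict_lower = TRUE)
  structure(list(a = a, b = b, c = c), class = "fiber_law")
}

#' @export
print.fiber_law <- function(x, ...) {
  cat(sprintf("<fiber_law> sigma = %.4g - (%.4g) * ln(strain + %.4g)  [MPa]\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Evaluate the single-fiber constitutive law
#'
#' Computes \eqn{a - b\,\ln(\varepsilon + c)}. By default negative law values
#' are clamped to zero: the fitted law is negative at very small strains for
#' typical electrospun-fiber parameter sets, and a fiber cannot transmit
#' negative axial stress. Set `clamp = FALSE` to inspect the raw law (as used
#' when computing goodness of fit).
#'
#' @param params a [fiber_law()].
#' @param strain numeric vector of fiber axial strains (each >= 0 and
#'   `strain + c > 0`).
#' @param clamp logical; clamp negative stresses to zero (default `TRUE`).
#' @return stress in MPa, same length as `strain`.
#' @export
evaluate_fiber_stress <- function(params, strain, clamp = TRUE) {
  stopifnot(inherits(params, "fiber_law"))
  if (!is.numeric(strain) || any(!is.finite(strain)))
    stop_domain("strain must be finite numeric")
  if (any(strain < 0))
    stop_domain("strain must be non-negative")
  if (any(strain + params$c <= 0))
    stop_domain("strain + c must be positive (logarithm domain)")
  sigma <- params$a - params$b * log(strain + params$c)
  if (clamp) sigma <- pmax(0, sigma)
  sigma
}

#' Diameter-corrected ("harmonic") fiber stress
#'
#' Scales the single-fiber law by \eqn{\tfrac12(1 + d/D)}, where `d` is the
#' diameter of the fiber at hand and `D` the harmonic mean diameter of the
#' fiber population. The correction accounts for the tested fiber's diameter
#' differing from the population it represents; for `d = D` it is the
#' identity.
#'
#' @inheritParams evaluate_fiber_stress
#' @param d fiber diameter (nm, > 0).
#' @param D harmonic mean diameter of the population (nm, > 0).
#' @return corrected stress in MPa.
#' @export
harmonic_stress <- function(params, strain, d, D, clamp = TRUE) {
  check_scalar(d, "d", lower = 0, strict_lower = TRUE)
  check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  0.5 * (1 + d / D) * evaluate_fiber_stress(params, strain, clamp = clamp)
}

#' Fit the logarithmic law to a measured single-fiber curve
#'
#' Least-squares fit of \eqn{\sigma = a - b\,\ln(\varepsilon + c)} by
#' Levenberg-Marquardt with `c` bounded below by `1e-8` (the Jacobian becomes
#' ill-conditioned as `c` approaches zero). The default initial guess is
#' `a = max(stress)`, `b = -range(stress)/log(range(strain))`, `c = 1e-3`.
#' The fit is deterministic given the curve and initial guess.
#'
#' @param curve a [stress_strain_curve()] with at least 4 distinct strain
#'   points and non-constant stress.
#' @param initial_guess optional [fiber_law()] used as the starting point.
#' @return a list with elements `params` (a [fiber_law()]) and `r_squared`.
#' @export
fit_fiber_law <- function(curve, initial_guess = NULL) {
  stopifnot(is_ss_curve(curve))
  if (nrow(curve) < 4L)
    stop_domain("fit requires at least 4 strain points")
  if (diff(range(curve$strain)) <= 0)
    stop_domain("fit requires a positive strain span")
  if (stats::sd(curve$stress_mpa) == 0)
    stop_domain("fit is degenerate: stress is constant across the curve")

  if (is.null(initial_guess)) {
    span <- diff(range(curve$strain))
    b0 <- -diff(range(curve$stress_mpa)) / log(span)
    if (!is.finite(b0) || b0 == 0) b0 <- -1
    start <- c(a = max(curve$stress_mpa), b = b0, c = 1e-3)
  } else {
    stopifnot(inherits(initial_guess, "fiber_law"))
    start <- c(a = initial_guess$a, b = initial_guess$b, c = initial_guess$c)
  }

  resid_fn <- function(p) {
    curve$stress_mpa - (p[1] - p[2] * log(curve$strain + p[3]))
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(-Inf, -Inf, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (!fit$info %in% 1:4)
    stop_domain(sprintf("fit did not converge (nls.lm info %d: %s)",
                        fit$info, fit$message))
  params <- fiber_law(fit$par[[1]], fit$par[[2]], fit$par[[3]])
  list(params = params, r_squared = r_squared(curve, params))
}

#' Coefficient of determination of a fitted law on a curve
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, computed against the *unclamped* law.
#'
#' @inheritParams fit_fiber_law
#' @param params a [fiber_law()].
#' @return R-squared, in \eqn{(-\infty, 1]}.
#' @export
r_squared <- function(curve, params) {
  stopifnot(is_ss_curve(curve))
  pred <- evaluate_fiber_stress(params, curve$strain, clamp = FALSE)
  ss_tot <- sum((curve$stress_mpa - mean(curve$stress_mpa))^2)
  if (ss_tot == 0)
    stop_domain("R-squared undefined: stress column has zero variance")
  1 - sum((curve$stress_mpa - pred)^2) / ss_tot
}

#' Reference single-fiber fits for the five SF/PCL blends
#'
#' Published least-squares parameters of the logarithmic law for single
#' electrospun silk-fibroin/poly(e-caprolactone) nanofibers at blend weight
#' ratios 100/0 through 0/100, with the reported coefficient of
#' determination. These are the parameter sets used throughout the examples
#' and the acceptance checks.
#'
#' @return a data frame with columns `blend`, `a`, `b`, `c`, `r_squared`.
#' @export
sfpcl_fiber_params <- function() {
  data.frame(
    blend = c("100/0", "75/25", "50/50", "25/75", "0/100"),
    a = c(27.207, 22.669, 26.576, 12.569, 17.130),
    b = c(-3.297, -2.810, -4.313, -1.802, -3.219),
    c = c(1.006e-4, 2.663e-4, 1.290e-3, 5.822e-4, 8.120e-3),
    r_squared = c(0.984, 0.976, 0.975, 0.949, 0.975),
    stringsAsFactors = FALSE
  )
}

#' Reference diameter summaries for the five SF/PCL blends
#'
#' Published arithmetic mean, root-mean-square and harmonic mean fiber
#' diameters (nm, from 100 SEM measurements per blend) for electrospun
#' silk-fibroin/poly(e-caprolactone) membranes.
#'
#' @return a data frame with columns `blend`, `arithmetic_nm`, `rms_nm`,
#'   `harmonic_nm`.
#' @export
sfpcl_diameter_summaries <- function() {
  data.frame(
    blend = c("100/0", "75/25", "50/50", "25/75", "0/100"),
    arithmetic_nm = c(85.87, 70.52, 63.76, 76.56, 99.37),
    rms_nm = c(91.29, 76.12, 71.91, 80.41, 110.18),
    harmonic_nm = c(79.49, 62.96, 57.11, 70.54, 88.62),
    stringsAsFactors = FALSE
  )
}
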