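#' Affine deformation state of the membrane
#'
#' Uniaxial stretch along the y axis maps the unit circle of fibers to an
#' ellipse: axial scale factor `lambda_y = 1 + strain`, transverse scale
#' factor `lambda_x` set by the shrinkage coefficient `v` under one of two
#' conventions. `"literal-eq2"` takes `lambda_x = v` — `v` acts directly as
#' the multiplicative transverse factor, faithful to the reorientation
#' formula `theta' = arctan[(1 + eps) sin(theta) / (v cos(theta))]`.
#' `"strain-ratio"` reads `v` as the transverse-to-axial strain ratio, giving
#' `lambda_x = 1 + v * strain`. Both are implemented because the two readings
#' give different numbers; the literal convention is the default.
#'
#' @param strain applied membrane strain along the stretch axis (>= 0).
#' @param v shrinkage coefficient (> 0).
#' @param convention `"literal-eq2"` or `"strain-ratio"`.
#' @return an object of class `deformation_state` with fields `strain`, `v`,
#'   `lambda_x`, `lambda_y`, `convention`.
#' @export
deformation_state <- function(strain, v,
                              convention = c("literal-eq2", "strain-ratio")) {
  check_scalar(strain, "strain", lower = 0)
  check_scalar(v, "v", lower = 0, strict_lower = TRUE)
  convention <- match.arg(convention)
  lambda_x <- switch(convention,
    "literal-eq2" = v,
    "strain-ratio" = 1 + v * strain
  )
  if (lambda_x <= 0) stop_domain("transverse scale factor must be positive")
  structure(list(strain = strain, v = v,
                 lambda_x = lambda_x, lambda_y = 1 + strain,
                 convention = convention),
            class = "deformation_state")
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop_domain("theta must be finite numeric")
  if (any(theta < 0) || any(theta > pi / 2))
    stop_domain("theta must lie in [0, pi/2]")
  theta
}

#' Reoriented fiber angle under stretch
#'
#' `theta' = arctan[lambda_y sin(theta) / (lambda_x cos(theta))]`, evaluated
#' with `atan2` so the transverse limit `theta = pi/2` maps to `pi/2`
#' exactly. Fibers rotate toward the stretch axis whenever
#' `lambda_y >= lambda_x`.
#'
#' @param theta initial inclination angle(s), radians in `[0, pi/2]`,
#'   measured from the transverse (x) axis.
#' @param state a [deformation_state()].
#' @return deformed angle(s) in `[0, pi/2]`.
#' @export
reorient_angle <- function(theta, state) {
  stopifnot(inherits(state, "deformation_state"))
  check_theta(theta)
  atan2(state$lambda_y * sin(theta), state$lambda_x * cos(theta))
}

#' Deformed fiber half-length
#'
#' The affine map scales a fiber of half-length `r0` at angle `theta` to
#' `r' = r0 * sqrt(lambda_x^2 cos^2 theta + lambda_y^2 sin^2 theta)`.
#'
#' @inheritParams reorient_angle
#' @param r0 undeformed fiber half-length (> 0), any length unit.
#' @return deformed half-length, same unit as `r0`.
#' @export
deformed_half_length <- function(theta, r0, state) {
  check_scalar(r0, "r0", lower = 0, strict_lower = TRUE)
  r0 * (1 + fiber_axial_strain(theta, state))
}

#' Fiber axial strain induced by the membrane deformation
#'
#' `eps_f = r'/r0 - 1 = sqrt(lambda_x^2 cos^2 theta + lambda_y^2 sin^2 theta) - 1`.
#' Negative for fibers near the transverse axis when the membrane shrinks
#' laterally (`lambda_x < 1`); such fibers are treated as buckled
#' (zero force) by the membrane model.
#'
#' @inheritParams reorient_angle
#' @return fiber axial strain(s), dimensionless.
#' @export
fiber_axial_strain <- function(theta, state) {
  stopifnot(inherits(state, "deformation_state"))
  check_theta(theta)
  sqrt(state$lambda_x^2 * cos(theta)^2 + state$lambda_y^2 * sin(theta)^2) - 1
}

#' Membrane strain recovered from a single fiber's axial projection
#'
#' Relates the change in a fiber's projection on the stretch axis to the
#' membrane strain. Two denominator conventions are kept: `"reference"`
#' (default) divides by the undeformed projection `r0 sin(theta)`, so an
#' axis-aligned fiber recovers the membrane strain exactly; `"deformed"`
#' divides by the deformed projection `r' sin(theta')`, which yields
#' `strain / (1 + strain)` instead. Neither is silently corrected into the
#' other.
#'
#' @inheritParams deformed_half_length
#' @param denominator `"reference"` or `"deformed"`.
#' @return projection strain(s), dimensionless.
#' @export
projection_strain <- function(theta, r0, state,
                              denominator = c("reference", "deformed")) {
  denominator <- match.arg(denominator)
  check_theta(theta)
  if (any(theta == 0))
    stop_domain("projection strain undefined at theta = 0 (zero projection)")
  rp <- deformed_half_length(theta, r0, state)
  tp <- reorient_angle(theta, state)
  num <- rp * sin(tp) - r0 * sin(theta)
  den <- switch(denominator,
    reference = r0 * sin(theta),
    deformed = rp * sin(tp)
  )
  num / den
}
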