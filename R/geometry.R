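#' Arithmetic, root-mean-square and harmonic diameter summaries
#'
#' The three diameter averages used to characterise an electrospun fiber
#' population. The harmonic mean `D = n / sum(1/d_i)` is the one the
#' membrane model uses (in the stress correction and in the fiber count);
#' the arithmetic and RMS means are reported for parity with standard
#' SEM-based characterisation. The ordering harmonic <= arithmetic <= RMS
#' (AM-QM-HM inequality) holds for every valid sample, with equality iff all
#' diameters are equal.
#'
#' @param diameters numeric vector of fiber diameters (nm, each > 0).
#' @return a list with elements `arithmetic`, `rms`, `harmonic` (nm) and `n`.
#' @export
diameter_statistics <- function(diameters) {
  if (!is.numeric(diameters) || length(diameters) == 0L)
    stop_domain("diameter sample must be a non-empty numeric vector")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop_domain("all diameters must be finite and positive")
  list(
    arithmetic = mean(diameters),
    rms = sqrt(mean(diameters^2)),
    harmonic = length(diameters) / sum(1 / diameters),
    n = length(diameters)
  )
}

#' Membrane unit-cell specification
#'
#' Collects the structural inputs of the membrane model: porosity `p`, fiber
#' half-length `r0`, cross-section area `A`, shrinkage coefficient `v` and
#' harmonic mean fiber diameter `D`. The unit-cell volume is fixed by the
#' convention `V = A * 2 r0` — a slab one fiber-length thick, so that every
#' fiber in the cell crosses the mid-plane and membrane stress is simply
#' `F_y / A` with no orientation-dependent crossing correction.
#'
#' @param porosity void volume fraction, in `[0, 1)`.
#' @param r0_nm fiber half-length (nm, > 0).
#' @param area_nm2 unit-cell cross-section area (nm^2, > 0).
#' @param shrinkage_v transverse shrinkage coefficient (> 0); see
#'   [deformation_state()].
#' @param harmonic_d_nm harmonic mean fiber diameter (nm, > 0).
#' @param mean_d_nm optional arithmetic mean diameter (nm), needed only for
#'   the `"expected"` diameter-correction option of [mean_fiber_force()].
#' @param v_convention `"literal-eq2"` (transverse scale factor `lambda_x = v`)
#'   or `"strain-ratio"` (`lambda_x = 1 + v * strain`); see
#'   [deformation_state()].
#' @return an object of class `membrane_spec`.
#' @export
membrane_spec <- function(porosity, r0_nm, area_nm2, shrinkage_v,
                          harmonic_d_nm, mean_d_nm = NULL,
                          v_convention = c("literal-eq2", "strain-ratio")) {
  check_scalar(porosity, "porosity", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(r0_nm, "r0_nm", lower = 0, strict_lower = TRUE)
  check_scalar(area_nm2, "area_nm2", lower = 0, strict_lower = TRUE)
  check_scalar(shrinkage_v, "shrinkage_v", lower = 0, strict_lower = TRUE)
  check_scalar(harmonic_d_nm, "harmonic_d_nm", lower = 0, strict_lower = TRUE)
  if (!is.null(mean_d_nm))
    check_scalar(mean_d_nm, "mean_d_nm", lower = 0, strict_lower = TRUE)
  v_convention <- match.arg(v_convention)
  structure(list(
    p = porosity, r0 = r0_nm, A = area_nm2,
    V = area_nm2 * 2 * r0_nm,   # slab convention
    v = shrinkage_v, D = harmonic_d_nm, d_bar = mean_d_nm,
    v_convention = v_convention
  ), class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<membrane_spec> p = %.3g, r0 = %g nm, A = %g nm^2, V = %g nm^3,\n",
    "  D = %g nm, v = %g (%s)\n"),
    x$p, x$r0, x$A, x$V, x$D, x$v, x$v_convention))
  invisible(x)
}

#' Number of fibers in the unit cell
#'
#' `n = 2 V (1 - p) / (r0 * pi * D^2)`: the fiber count that makes the total
#' fiber volume `n * (pi/4) D^2 * 2 r0` equal the solid volume `V (1 - p)`.
#'
#' @param spec a [membrane_spec()].
#' @return fiber count (dimensionless, not necessarily integer).
#' @export
fiber_count <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  2 * spec$V * (1 - spec$p) / (spec$r0 * pi * spec$D^2)
}

#' Solid volume fraction of the membrane
#'
#' Bookkeeping inverse of [fiber_count()]: returns `1 - p`.
#'
#' @inheritParams fiber_count
#' @return solid fraction in `(0, 1]`.
#' @export
solid_volume_fraction <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  1 - spec$p
}
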