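#' Construct a validated stress-strain curve
#'
#' A stress-strain curve is a two-column data frame (`strain`, `stress_mpa`)
#' with a strictly increasing, non-negative, finite strain grid. It is the
#' common currency of the package: single-fiber tensile records, synthetic
#' fixtures, membrane predictions and Monte-Carlo simulations all use it.
#'
#' @param strain numeric vector of strains (dimensionless, non-negative,
#'   strictly increasing).
#' @param stress_mpa numeric vector of engineering stresses (MPa), same length.
#' @return a data frame of class `ss_curve`.
#' @export
stress_strain_curve <- function(strain, stress_mpa) {
  if (!is.numeric(strain) || !is.numeric(stress_mpa))
    stop_domain("strain and stress must be numeric")
  if (length(strain) != length(stress_mpa))
    stop_domain("strain and stress must have equal length")
  if (length(strain) < 1L)
    stop_domain("curve must contain at least one point")
  if (any(!is.finite(strain)) || any(!is.finite(stress_mpa)))
    stop_domain("curve contains non-finite entries")
  if (any(strain < 0))
    stop_domain("strain values must be non-negative")
  if (length(strain) > 1L && any(diff(strain) <= 0))
    stop_domain("strain grid must be strictly increasing")
  structure(
    data.frame(strain = as.numeric(strain), stress_mpa = as.numeric(stress_mpa)),
    class = c("ss_curve", "data.frame")
  )
}

#' @export
print.ss_curve <- function(x, ...) {
  cat(sprintf("<ss_curve> %d points, strain [%g, %g], stress [%g, %g] MPa\n",
              nrow(x), min(x$strain), max(x$strain),
              min(x$stress_mpa), max(x$stress_mpa)))
  if (nrow(x) <= 10L) print.data.frame(x, ...) else {
    print.data.frame(utils::head(x, 4L), ...)
    cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  }
  invisible(x)
}

is_ss_curve <- function(x) inherits(x, "ss_curve")
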