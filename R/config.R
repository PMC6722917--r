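# Recognised config keys, their defaults (NULL = required / no default) and
# whether they are required. Paths are resolved relative to the config file.
config_schema <- function() {
  list(
    blend_label      = list(default = "unlabelled", required = FALSE),
    porosity         = list(default = NULL, required = TRUE),
    r0_nm            = list(default = NULL, required = TRUE),
    area_nm2         = list(default = NULL, required = TRUE),
    shrinkage_v      = list(default = NULL, required = TRUE),
    v_convention     = list(default = "literal-eq2", required = FALSE),
    quadrature_order = list(default = 64L, required = FALSE),
    clamp            = list(default = TRUE, required = FALSE),
    seed             = list(default = 1L, required = FALSE),
    diameter_file    = list(default = NULL, required = FALSE),
    harmonic_d_nm    = list(default = NULL, required = FALSE),
    mean_d_nm        = list(default = NULL, required = FALSE),
    params_file      = list(default = NULL, required = FALSE),
    curve_file       = list(default = NULL, required = FALSE),
    strain_max       = list(default = 0.5, required = FALSE),
    n_strain         = list(default = 26L, required = FALSE)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file, rejects unknown keys (typo safety), checks
#' every numeric field against its owning type's domain, fills defaults and
#' reports each applied default via `message()` so every run is reproducible
#' from its log. Relative file paths are resolved against the config file's
#' directory.
#'
#' @param path path to a YAML config file.
#' @param quiet suppress default-reporting messages.
#' @return a named list of class `run_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_domain(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_domain(sprintf("%s: not a key-value mapping", path))
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0L)
    stop_domain(sprintf("%s: unknown config key(s): %s", path,
                        paste(unknown, collapse = ", ")))
  cfg <- raw
  numeric_keys <- c("porosity", "r0_nm", "area_nm2", "shrinkage_v",
                    "quadrature_order", "seed", "harmonic_d_nm", "mean_d_nm",
                    "strain_max", "n_strain")
  for (key in intersect(numeric_keys, names(cfg))) {
    # YAML 1.1 reads exponents without a sign ("1.0e6") as strings
    if (is.character(cfg[[key]])) {
      val <- suppressWarnings(as.numeric(cfg[[key]]))
      if (is.na(val))
        stop_domain(sprintf("%s: key '%s' is not numeric", path, key))
      cfg[[key]] <- val
    }
  }
  for (key in names(schema)) {
    if (is.null(cfg[[key]])) {
      if (schema[[key]]$required)
        stop_domain(sprintf("%s: missing required key '%s'", path, key))
      if (!is.null(schema[[key]]$default)) {
        cfg[[key]] <- schema[[key]]$default
        if (!quiet)
          message(sprintf("config: using default %s = %s", key,
                          format(schema[[key]]$default)))
      }
    }
  }
  check_scalar(cfg$porosity, "porosity", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(cfg$r0_nm, "r0_nm", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$area_nm2, "area_nm2", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$shrinkage_v, "shrinkage_v", lower = 0, strict_lower = TRUE)
  if (!cfg$v_convention %in% c("literal-eq2", "strain-ratio"))
    stop_domain("`v_convention` must be 'literal-eq2' or 'strain-ratio'")
  check_scalar(cfg$quadrature_order, "quadrature_order", lower = 2)
  if (!is.logical(cfg$clamp) || length(cfg$clamp) != 1L || is.na(cfg$clamp))
    stop_domain("`clamp` must be TRUE or FALSE")
  check_scalar(cfg$seed, "seed")
  check_scalar(cfg$strain_max, "strain_max", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$n_strain, "n_strain", lower = 2)
  if (!is.null(cfg$harmonic_d_nm))
    check_scalar(cfg$harmonic_d_nm, "harmonic_d_nm", lower = 0, strict_lower = TRUE)
  if (is.null(cfg$diameter_file) && is.null(cfg$harmonic_d_nm))
    stop_domain(sprintf(
      "%s: need either 'diameter_file' or 'harmonic_d_nm'", path))
  cfg$.dir <- dirname(normalizePath(path))
  structure(cfg, class = "run_config")
}

#' Save a run configuration to YAML
#'
#' Inverse of [load_config()]; a save-load round trip is an identity on the
#' configuration values.
#'
#' @param config a `run_config` (or plain named list of valid keys).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$.dir <- NULL
  cfg <- Filter(Negate(is.null), cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

resolve_path <- function(config, path) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path
  else file.path(config$.dir %||% ".", path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a membrane spec from a run configuration
#'
#' Resolves the diameter sample (from `diameter_file` if given, otherwise
#' the stated `harmonic_d_nm`) and assembles the [membrane_spec()].
#'
#' @param config a `run_config` from [load_config()].
#' @return a [membrane_spec()].
#' @export
config_membrane_spec <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$diameter_file)) {
    d <- read_diameter_csv(resolve_path(config, config$diameter_file))
    stats <- diameter_statistics(d)
    D <- stats$harmonic
    d_bar <- stats$arithmetic
  } else {
    D <- config$harmonic_d_nm
    d_bar <- config$mean_d_nm
  }
  membrane_spec(config$porosity, config$r0_nm, config$area_nm2,
                config$shrinkage_v, D, mean_d_nm = d_bar,
                v_convention = config$v_convention)
}
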