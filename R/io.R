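parse_error <- function(path, line, msg) {
  stop_domain(sprintf("%s:%d: %s", path, line, msg))
}

#' Read a single-fiber or membrane stress-strain curve from CSV
#'
#' Expects a two-column CSV with mandatory header `strain,stress_mpa`
#' (comma separator, decimal point, UTF-8). Strictly increasing strain is
#' enforced; every parse error names the offending line.
#'
#' @param path file path.
#' @return a [stress_strain_curve()].
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) parse_error(path, 1L, "need a header and at least one data row")
  header <- trimws(strsplit(lines[1L], ",")[[1]])
  if (length(header) < 2L || header[1] != "strain" || header[2] != "stress_mpa")
    parse_error(path, 1L, "header must be 'strain,stress_mpa'")
  n <- length(lines) - 1L
  strain <- stress <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], ",")[[1]]
    if (length(fields) != 2L)
      parse_error(path, i + 1L, sprintf("expected 2 fields, found %d", length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      parse_error(path, i + 1L, sprintf("non-numeric value in '%s'", lines[i + 1L]))
    strain[i] <- vals[1]; stress[i] <- vals[2]
  }
  bad <- which(diff(strain) <= 0)
  if (length(bad) > 0L)
    parse_error(path, bad[1L] + 2L,
                "strain must be strictly increasing (duplicate or unsorted value)")
  if (any(strain < 0))
    parse_error(path, which(strain < 0)[1L] + 1L, "negative strain")
  stress_strain_curve(strain, stress)
}

#' Write a stress-strain curve to CSV
#'
#' Inverse of [read_curve_csv()]; values are written with 15 significant
#' digits so a write-read round trip is an identity to 12 significant
#' digits. Extra columns (e.g. the Monte-Carlo `se_mpa`) are preserved.
#'
#' @param curve a [stress_strain_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(is_ss_curve(curve))
  df <- as.data.frame(lapply(curve, function(col) format(col, digits = 15)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fiber diameter sample from CSV
#'
#' One-column CSV with mandatory header `diameter_nm`; all values must be
#' positive.
#'
#' @param path file path.
#' @return numeric vector of diameters (nm).
#' @export
read_diameter_csv <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) parse_error(path, 1L, "need a header and at least one data row")
  if (trimws(lines[1L]) != "diameter_nm")
    parse_error(path, 1L, "header must be 'diameter_nm'")
  vals <- suppressWarnings(as.numeric(lines[-1L]))
  if (any(is.na(vals)))
    parse_error(path, which(is.na(vals))[1L] + 1L, "non-numeric diameter")
  if (any(vals <= 0))
    parse_error(path, which(vals <= 0)[1L] + 1L, "diameter must be positive")
  vals
}

#' Write a diameter sample to CSV
#' @param diameters numeric vector of diameters (nm).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diameter_csv <- function(diameters, path) {
  writeLines(c("diameter_nm", format(diameters, digits = 15)), path)
  invisible(path)
}

#' Serialize fitted fiber-law parameters to a key-value record
#'
#' Plain-text `key = value` record holding `a`, `b`, `c`, `r_squared` and an
#' optional `blend_label`.
#'
#' @param params a [fiber_law()].
#' @param path output file path.
#' @param r_squared optional goodness of fit to record.
#' @param blend_label optional text label for the fiber batch.
#' @return `path`, invisibly.
#' @export
write_fiber_params <- function(params, path, r_squared = NULL,
                               blend_label = NULL) {
  stopifnot(inherits(params, "fiber_law"))
  lines <- c(
    sprintf("a = %.15g", params$a),
    sprintf("b = %.15g", params$b),
    sprintf("c = %.15g", params$c)
  )
  if (!is.null(r_squared)) lines <- c(lines, sprintf("r_squared = %.15g", r_squared))
  if (!is.null(blend_label)) lines <- c(lines, sprintf("blend_label = %s", blend_label))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fitted fiber-law parameter record
#' @param path file path written by [write_fiber_params()].
#' @return a list with `params` ([fiber_law()]), `r_squared` (or `NA`) and
#'   `blend_label` (or `NA`).
#' @export
read_fiber_params <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      parse_error(path, i, "expected 'key = value'")
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  for (k in c("a", "b", "c"))
    if (is.null(kv[[k]])) stop_domain(sprintf("%s: missing key '%s'", path, k))
  list(
    params = fiber_law(as.numeric(kv$a), as.numeric(kv$b), as.numeric(kv$c)),
    r_squared = if (is.null(kv$r_squared)) NA_real_ else as.numeric(kv$r_squared),
    blend_label = if (is.null(kv$blend_label)) NA_character_ else kv$blend_label
  )
}
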