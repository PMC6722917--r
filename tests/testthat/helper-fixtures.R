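# Shared fixtures: the five published SF/PCL single-fiber parameter sets and
# a default membrane spec factory used across the suite.

table_params <- function() {
  df <- sfpcl_fiber_params()
  lapply(seq_len(nrow(df)), function(i) fiber_law(df$a[i], df$b[i], df$c[i]))
}

default_spec <- function(porosity = 0.8, r0_nm = 1000, area_nm2 = 1e6,
                         shrinkage_v = 0.9, harmonic_d_nm = 79.49, ...) {
  membrane_spec(porosity, r0_nm, area_nm2, shrinkage_v, harmonic_d_nm, ...)
}

# Random admissible membrane spec / fiber law draws for property tests.
random_spec <- function() {
  membrane_spec(
    porosity = stats::runif(1, 0.5, 0.95),
    r0_nm = stats::runif(1, 500, 5000),
    area_nm2 = 10^stats::runif(1, 5, 7),
    shrinkage_v = stats::runif(1, 0.7, 1.0),
    harmonic_d_nm = stats::runif(1, 50, 110)
  )
}

random_law <- function() {
  fiber_law(a = stats::runif(1, 10, 30),
            b = -stats::runif(1, 1, 5),
            c = 10^stats::runif(1, -4, -2))
}

# Scratch paths for I/O tests (stable file names so parse errors are matchable).
temp_path <- function(name) {
  p <- file.path(tempdir(), name)
  if (file.exists(p)) unlink(p)
  p
}

temp_dir <- function() {
  d <- tempfile(pattern = "nanomech")
  dir.create(d)
  d
}
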