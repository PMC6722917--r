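test_that("logarithmic law evaluates, clamps and rejects bad input", {
  p <- fiber_law(27.207, -3.297, 1.006e-4)
  # ln(1) = 0 forces the bracket to a
  expect_equal(evaluate_fiber_stress(p, 1 - p$c), 27.207)
  # raw law is negative at zero strain; clamp zeroes it
  expect_lt(evaluate_fiber_stress(p, 0, clamp = FALSE), 0)
  expect_equal(evaluate_fiber_stress(p, 0, clamp = FALSE),
               27.207 + 3.297 * log(1.006e-4))
  expect_equal(evaluate_fiber_stress(p, 0), 0)
  # slope-free law is constant
  flat <- fiber_law(5, 0, 1e-3)
  expect_equal(evaluate_fiber_stress(flat, c(0, 0.3, 1)), rep(5, 3))
  expect_error(evaluate_fiber_stress(p, -0.1), "non-negative")
  expect_error(evaluate_fiber_stress(p, NA_real_), "finite")
  expect_error(fiber_law(1, 1, 0), "admissible")
})

test_that("law is non-decreasing in strain for hardening (b < 0) parameters", {
  grid <- seq(0, 1, length.out = 200)
  for (p in table_params()) {
    sig <- evaluate_fiber_stress(p, grid, clamp = FALSE)
    expect_true(all(diff(sig) > 0))
  }
})

test_that("harmonic stress applies the (1 + d/D)/2 diameter correction", {
  p <- fiber_law(26.576, -4.313, 1.290e-3)  # 50/50 blend
  withr_seed <- 421
  set.seed(withr_seed)
  # identity at d = D for random laws and strains
  for (i in 1:25) {
    q <- random_law()
    eps <- stats::runif(1, 0, 1)
    D <- stats::runif(1, 40, 120)
    expect_equal(harmonic_stress(q, eps, d = D, D = D),
                 evaluate_fiber_stress(q, eps))
  }
  # factor (1 + 3)/2 = 2 at d = 3D
  expect_equal(harmonic_stress(p, 0.3, d = 300, D = 100),
               2 * evaluate_fiber_stress(p, 0.3))
  # hand evaluation at the 50/50 blend's harmonic diameter
  expect_equal(harmonic_stress(p, 0.2, d = 57.11, D = 57.11),
               26.576 + 4.313 * log(0.2 + 1.290e-3))
  expect_error(harmonic_stress(p, 0.2, d = -1, D = 57.11), "admissible")
  expect_error(harmonic_stress(p, 0.2, d = 57.11, D = 0), "admissible")
})

test_that("fitting recovers noiseless parameters to 1e-6 relative with R2 = 1", {
  grid <- seq(0.01, 1.0, length.out = 50)
  for (p in table_params()) {
    curve <- stress_strain_curve(grid, evaluate_fiber_stress(p, grid, clamp = FALSE))
    fit <- fit_fiber_law(curve)
    expect_equal(fit$params$a, p$a, tolerance = 1e-6)
    expect_equal(fit$params$b, p$b, tolerance = 1e-6)
    expect_equal(fit$params$c, p$c, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  }
})

test_that("fitting recovers a within 2% under 0.1 MPa Gaussian noise", {
  truth <- fiber_law(17.130, -3.219, 8.120e-3)  # 0/100 blend
  curve <- generate_synthetic_fiber_curve(truth, noise_sd = 0.1, n_points = 50,
                                          strain_range = c(0.01, 1.0), seed = 7)
  fit <- fit_fiber_law(curve)
  expect_lt(abs(fit$params$a - truth$a) / truth$a, 0.02)
  expect_gt(fit$r_squared, 0.95)
})

test_that("degenerate curves are rejected with an explicit fitting error", {
  expect_error(fit_fiber_law(stress_strain_curve(c(0.1, 0.2, 0.3, 0.4),
                                                 rep(5, 4))), "constant")
  expect_error(fit_fiber_law(stress_strain_curve(c(0.1, 0.2, 0.3),
                                                 c(1, 2, 3))), "at least 4")
})

test_that("R-squared matches a direct two-pass computation and edge cases", {
  p <- fiber_law(22.669, -2.810, 2.663e-4)
  curve <- generate_synthetic_fiber_curve(p, noise_sd = 0.5, n_points = 40,
                                          strain_range = c(0.02, 0.8), seed = 11)
  pred <- p$a - p$b * log(curve$strain + p$c)
  ss_res <- sum((curve$stress_mpa - pred)^2)
  ss_tot <- sum((curve$stress_mpa - mean(curve$stress_mpa))^2)
  expect_equal(r_squared(curve, p), 1 - ss_res / ss_tot)
  # exact generation gives 1
  exact <- stress_strain_curve(curve$strain, pred)
  expect_equal(r_squared(exact, p), 1.0)
  # a flat law predicting the stress mean gives exactly 0
  flat <- fiber_law(mean(curve$stress_mpa), 0, 1e-3)
  expect_equal(r_squared(curve, flat), 0.0)
  expect_error(r_squared(stress_strain_curve(c(0.1, 0.2), c(3, 3)), p),
               "zero variance")
})

test_that("R-squared is invariant under affine rescaling of the stress unit", {
  p <- fiber_law(12.569, -1.802, 5.822e-4)
  curve <- generate_synthetic_fiber_curve(p, noise_sd = 0.3, n_points = 30,
                                          strain_range = c(0.01, 0.6), seed = 3)
  k <- 6.894757  # e.g. MPa -> ksi-scaled units
  scaled <- stress_strain_curve(curve$strain, k * curve$stress_mpa)
  p_scaled <- fiber_law(k * p$a, k * p$b, p$c)
  expect_equal(r_squared(scaled, p_scaled), r_squared(curve, p))
})
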