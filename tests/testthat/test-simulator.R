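test_that("network generation is seeded, bounded and degenerate-safe", {
  net1 <- build_network(5000, mu_ln = log(80), sigma_ln = 0.2, seed = 13)
  net2 <- build_network(5000, mu_ln = log(80), sigma_ln = 0.2, seed = 13)
  expect_identical(net1$theta, net2$theta)
  expect_identical(net1$d, net2$d)
  expect_true(all(net1$theta >= 0 & net1$theta <= pi / 2))
  expect_true(all(net1$d > 0))
  # sigma_ln = 0 collapses to equal diameters
  flat <- build_network(100, mu_ln = log(70), sigma_ln = 0, seed = 1)
  expect_equal(flat$d, rep(70, 100))
  # mean orientation near pi/4 at large N
  big <- build_network(1e5, mu_ln = log(80), sigma_ln = 0.2, seed = 5)
  se <- (pi / 2) / sqrt(12) / sqrt(1e5)
  expect_lt(abs(mean(big$theta) - pi / 4), 3 * se)
  expect_error(build_network(0, log(80), 0.2, 1), ">= 1")
  expect_error(build_network(10, log(80), -0.1, 1), "admissible")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(100)
  before <- .Random.seed
  invisible(build_network(10, log(80), 0.1, seed = 9))
  invisible(generate_diameter_sample(log(80), 0.2, 10, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("single aligned fiber reproduces the scaled clamped law", {
  p <- table_params()[[5]]  # 0/100 blend
  spec <- default_spec(harmonic_d_nm = 90)
  net <- build_network(1, mu_ln = log(90), sigma_ln = 0, seed = 1)
  net$theta <- pi / 2  # pin the single fiber along the stretch axis
  grid <- c(0.05, 0.2, 0.4)
  sim <- simulate_tension(net, spec, p, grid)
  # aligned fiber: eps_f = eps, theta' = pi/2, d = D -> correction 1
  expected <- fiber_count(spec) / spec$A * (pi / 4) * 90^2 *
    evaluate_fiber_stress(p, grid)
  expect_equal(sim$stress_mpa, expected, tolerance = 1e-12)
})

test_that("all-transverse fibers under lateral shrinkage carry nothing", {
  p <- table_params()[[1]]
  spec <- default_spec(shrinkage_v = 0.9)
  net <- build_network(50, mu_ln = log(80), sigma_ln = 0.1, seed = 4)
  net$theta <- rep(0, 50)
  sim <- simulate_tension(net, spec, p, c(0.1, 0.3))
  expect_equal(sim$stress_mpa, c(0, 0))
})

test_that("Monte-Carlo error shrinks toward the analytic value as N grows", {
  spec <- default_spec()
  p <- table_params()[[4]]
  target <- total_force(0.3, spec, p)$sigma_membrane
  err <- vapply(c(2e3, 8e3, 32e3), function(n) {
    sims <- vapply(1:8, function(s) {
      net <- build_network(n, log(spec$D), 0, seed = 1000 + s)
      simulate_tension(net, spec, p, 0.3)$stress_mpa
    }, numeric(1))
    sqrt(mean((sims - target)^2))
  }, numeric(1))
  # RMS error should fall roughly like 1/sqrt(N): x4 in N -> x2 in error
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
  expect_lt(err[3], err[1] / 2.2)
})

test_that("dispersed diameters raise the simulated stress above the d = D model", {
  # literal per-fiber (1 + d/D)/2 correction has expectation > 1 under
  # diameter dispersion, so the MC mean sits above the analytic d = D curve;
  # the two routes agree only for equal diameters
  spec <- default_spec(harmonic_d_nm = 80)
  p <- table_params()[[1]]
  net <- build_network(5e4, mu_ln = log(80), sigma_ln = 0.35, seed = 77)
  sim <- simulate_tension(net, spec, p, 0.3)
  analytic <- total_force(0.3, spec, p)$sigma_membrane
  expect_gt(sim$stress_mpa, analytic)
})

test_that("synthetic fiber curves follow the law exactly at zero noise", {
  p <- table_params()[[2]]
  curve <- generate_synthetic_fiber_curve(p, 0, 25, c(0.01, 0.9), seed = 1)
  expect_equal(curve$stress_mpa, evaluate_fiber_stress(p, curve$strain))
  # two seeds differ only in the noise
  c1 <- generate_synthetic_fiber_curve(p, 0.1, 25, c(0.01, 0.9), seed = 1)
  c2 <- generate_synthetic_fiber_curve(p, 0.1, 25, c(0.01, 0.9), seed = 2)
  expect_identical(c1$strain, c2$strain)
  expect_false(identical(c1$stress_mpa, c2$stress_mpa))
  expect_error(generate_synthetic_fiber_curve(p, 0.1, 3, c(0.01, 0.9), 1),
               ">= 4")
  expect_error(generate_synthetic_fiber_curve(p, 0.1, 10, c(0.9, 0.1), 1),
               "increasing")
})

test_that("diameter samples hit the lognormal mean and stay ordered", {
  d <- generate_diameter_sample(log(80), 0.2, 1e4, seed = 21)
  target <- 80 * exp(0.02)
  se <- stats::sd(d) / sqrt(1e4)
  expect_lt(abs(mean(d) - target), 3 * se)
  s <- diameter_statistics(d)
  expect_lte(s$harmonic, s$arithmetic)
  expect_lte(s$arithmetic, s$rms)
  expect_equal(generate_diameter_sample(log(75), 0, 5, seed = 3), rep(75, 5))
})
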