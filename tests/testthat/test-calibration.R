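test_that("engineering-to-true strain conversion is the logarithmic map", {
  # 100% biaxial engineering prestretch -> ln 2 = 69.31% true strain
  expect_equal(engineering_to_true_strain(1.0), 0.6931, tolerance = 1e-4)
  expect_identical(engineering_to_true_strain(0), 0)
  expect_equal(engineering_to_true_strain(0.5), log(1.5), tolerance = 1e-12)
  expect_error(engineering_to_true_strain(-1), "exceed -1")
})

test_that("the calibration curve matches its closed form and is monotone", {
  curve <- dea_curve()
  # at 0 kV the first Gaussian term is O(1e-13): the value is the a2 shoulder
  a2_term <- curve$a2 * exp(-((0 - curve$b2) / curve$c2)^2)
  expect_equal(strain_from_voltage(0, curve), a2_term, tolerance = 1e-6)
  # at 7.1 kV both terms are O(10); independent high-precision evaluation
  v <- 7.1
  expect_equal(strain_from_voltage(v, curve),
               curve$a1 * exp(-((v - curve$b1) / curve$c1)^2) +
                 curve$a2 * exp(-((v - curve$b2) / curve$c2)^2),
               tolerance = 1e-12)
  expect_gt(strain_from_voltage(7.1, curve), 69 - 0.5)
  expect_lt(strain_from_voltage(5, curve), strain_from_voltage(6, curve))
  # strict monotonicity via finite differences on a 1e4-point grid
  g <- seq(0, 7.1, length.out = 1e4)
  expect_true(all(diff(strain_from_voltage(g, curve)) > 0))
  expect_error(strain_from_voltage(7.2, curve), "operating range")
})

test_that("voltage_from_strain inverts the curve", {
  curve <- dea_curve()
  set.seed(7)
  v <- runif(100, 0, 7.1)
  expect_equal(voltage_from_strain(strain_from_voltage(v, curve), curve), v,
               tolerance = 1e-6)
  expect_equal(voltage_from_strain(strain_from_voltage(7.1, curve), curve),
               7.1, tolerance = 1e-6)
  # brute-force grid oracle at 1e6 points for mid-range strains
  grid <- seq(0, 7.1, length.out = 1e6)
  eg <- strain_from_voltage(grid, curve)
  for (eps in c(5, 20, 45)) {
    expect_equal(voltage_from_strain(eps, curve),
                 grid[which.min(abs(eg - eps))], tolerance = 1e-3)
  }
  expect_error(voltage_from_strain(1e4, curve), "reachable interval")
})

test_that("dual-Gaussian refit recovers the calibration from noiseless data", {
  curve <- dea_curve()
  V <- seq(0, 7.1, length.out = 50)
  eps <- strain_from_voltage(V, curve)
  fit <- fit_dual_gaussian(V, eps)
  expect_gte(fit$r_squared, 0.9998)
  # function recovery within 0.1% across the operating range
  g <- seq(0, 7.1, length.out = 500)
  expect_lt(max(abs(strain_from_voltage(g, fit$curve, NULL) /
                      strain_from_voltage(g, curve) - 1)), 1e-3)
})

test_that("dual-Gaussian fit handles degenerate and noisy data", {
  expect_warning(f0 <- fit_dual_gaussian(seq(0, 7.1, length.out = 10),
                                         rep(3, 10)), "constant")
  expect_true(is.na(f0$r_squared))
  curve <- dea_curve()
  set.seed(21)
  V <- runif(200, 0, 7.1)
  eps <- strain_from_voltage(V, curve) * (1 + 0.05 * rnorm(200))
  fit <- fit_dual_gaussian(V, eps)
  g <- seq(0, 7.1, length.out = 200)
  tv <- strain_from_voltage(g, curve)
  fv <- strain_from_voltage(g, fit$curve, NULL)
  # pointwise within 10%, except near zero strain where unweighted least
  # squares leaves only an absolute guarantee (the noise floor of the fit)
  expect_true(all(abs(fv / tv - 1) < 0.10 | abs(fv - tv) < 0.15))
  expect_lt(max(abs(fv / tv - 1)[tv > 1]), 0.10)
})
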