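test_that("SSIM identity, symmetry and boundedness", {
  set.seed(1)
  x <- matrix(runif(24 * 24), 24)
  y <- matrix(runif(24 * 24), 24)
  expect_equal(local_ssim_map(x, x), local_ssim_map(x, x) * 0 + 1,
               tolerance = 1e-12)
  expect_equal(mean_ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(local_ssim_map(x, y), local_ssim_map(y, x), tolerance = 1e-12)
  expect_true(all(local_ssim_map(x, y) <= 1 + 1e-12))
  # anti-correlated high-contrast pair scores well below 0.5
  hc <- matrix(rep(c(0, 1), 288), 24)
  expect_lt(mean_ssim(hc, 1 - hc), 0.5)
  expect_error(local_ssim_map(x, matrix(0, 10, 10)), "identical shape")
})

test_that("two-term and three-term formulations agree when C3 = C2/2", {
  set.seed(2)
  for (i in 1:5) {
    x <- matrix(runif(20 * 20), 20)
    y <- matrix(runif(20 * 20), 20)
    expect_equal(local_ssim_map(x, y, two_term = TRUE),
                 local_ssim_map(x, y, two_term = FALSE), tolerance = 1e-12)
  }
})

test_that("constant images reduce to the closed-form luminance term", {
  p <- ssim_params()
  a <- matrix(0.3, 16, 16)
  b <- matrix(0.5, 16, 16)
  lum <- (2 * 0.3 * 0.5 + p$C1) / (0.3^2 + 0.5^2 + p$C1)
  m <- local_ssim_map(a, b, p)
  expect_equal(m, m * 0 + lum, tolerance = 1e-12)
})

test_that("luminance term forgives a common additive shift", {
  set.seed(6)
  x <- matrix(runif(20 * 20), 20)
  expect_gt(mean_ssim(x, x + 0.001), mean_ssim(x, x + 0.2))
  expect_gt(mean_ssim(x + 0.3, x + 0.3 + 0.001), 0.99)
})

test_that("the Gaussian window is normalized and centre-weighted", {
  w <- ssim_window()
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gt(w[6, 6], w[1, 1])
  expect_true(all(w >= 0))
})

test_that("mean SSIM equals the mean of the local map", {
  set.seed(3)
  x <- matrix(runif(30 * 30), 30)
  y <- matrix(runif(30 * 30), 30)
  r <- ssim_report(x, y)
  expect_equal(r$mean_ssim, mean(r$local_map), tolerance = 1e-15)
})

test_that("SSIM agrees with an independent reference implementation", {
  # reference values frozen from scikit-image structural_similarity
  # (gaussian_weights = TRUE, sigma = 1.5, use_sample_covariance = FALSE,
  #  data_range = 1) on the LCG fixture pairs
  ref <- c(0.96735009, 0.96831762, 0.96734105, 0.96816883, 0.97167910,
           0.97031392, 0.97191670, 0.96803788, 0.97214620, 0.97341787)
  for (k in 1:10) {
    pr <- ssim_fixture_pair(k)
    expect_equal(mean_ssim(pr$a, pr$b), ref[k], tolerance = 1e-4)
  }
})

test_that("error grid matches a brute-force double loop", {
  cfg <- dea_config()
  set.seed(4)
  pred <- lapply(1:6, function(i) voltage_array(matrix(runif(81, 0, 7.1), 9)))
  truth <- lapply(1:6, function(i) voltage_array(matrix(runif(81, 0, 7.1), 9)))
  eg <- error_grid(pred, truth)
  brute <- matrix(0, 9, 9)
  for (r in 1:9) for (c in 1:9) {
    s <- 0
    for (i in 1:6) s <- s + abs(pred[[i]][r, c] - truth[[i]][r, c])
    brute[r, c] <- s / 6
  }
  expect_equal(eg, brute, tolerance = 1e-12)
  expect_equal(error_grid(truth, truth), matrix(0, 9, 9))
  one <- truth
  one[[1]][3, 4] <- one[[1]][3, 4] + 0.5
  g1 <- error_grid(one[1], truth[1])
  expect_equal(g1[3, 4], 0.5)
  expect_equal(sum(g1), 0.5)
  expect_error(error_grid(pred[1:2], truth), "equal length")
})
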