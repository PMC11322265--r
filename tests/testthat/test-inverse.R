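test_that("a toy inverse model overfits its training set", {
  ds <- build_dataset(50, 5, sampling_scheme(seed = 15))
  m <- train_inverse(ds, "x", inverse_config(epochs = 40, patience = 40,
                                             seed = 2))
  ev_tr <- evaluate_inverse(m, ds, split = "train")
  expect_lt(ev_tr$mse_kv2, 0.05)
  # training-image predictions within 0.2 kV elementwise for the typical
  # image (median of the per-image worst pixel over 10 training images; the
  # occasional worst pixel sits at the steep low-voltage calibration end)
  worst <- vapply(1:10, function(i) {
    v <- predict_voltages(m, unflatten_rm(ds$lr_x[i, ], ds$config$lr_size))
    max(abs(v - voltage_array(ds$voltages[i, ], ds$config)))
  }, numeric(1))
  expect_lt(stats::median(worst), 0.2)
  expect_lt(max(worst), 0.5)
})

test_that("prediction contracts: shape, range, determinism, axis warning", {
  m <- toy_inverse("x")
  ds <- toy_dataset()
  img <- unflatten_rm(ds$lr_x[301, ], ds$config$lr_size)
  v1 <- predict_voltages(m, img)
  v2 <- predict_voltages(m, img)
  expect_identical(unclass(v1), unclass(v2))
  expect_equal(dim(v1), c(9, 9))
  expect_true(all(v1 >= 0 & v1 <= 7.1))
  fld <- dea_simulate(v1, ds$config, resolution = 60)$y
  expect_warning(predict_voltages(m, fld), "axis")
})

test_that("training is seeded-deterministic with a sane loss history", {
  ds <- toy_dataset()
  cfg <- inverse_config(epochs = 6, seed = 9)
  m1 <- train_inverse(ds, "x", cfg)
  m2 <- train_inverse(ds, "x", cfg)
  expect_identical(m1$par, m2$par)
  h <- m1$history$train_mse
  expect_true(all(is.finite(h)))
  expect_lte(utils::tail(h, 1), h[1] * 1.05)
})

test_that("held-out evaluation and the error grid are coherent", {
  m <- toy_inverse("x")
  ds <- toy_dataset()
  ev <- evaluate_inverse(m, ds)
  expect_equal(ev$rmse_kv, sqrt(ev$mse_kv2), tolerance = 1e-12)
  expect_equal(dim(ev$error_grid), c(9, 9))
  expect_true(all(ev$error_grid >= 0))
  expect_equal(ev$n, 30)
  # even the toy model beats 0.3 kV held-out on the surrogate
  expect_lt(ev$rmse_kv, 0.3)
})

test_that("inverse-forward closed loop reconstructs held-out fields", {
  m <- toy_inverse("x")
  ds <- toy_dataset()
  cfg <- ds$config
  te <- which(ds$split == "test")[1:10]
  s <- vapply(te, function(i) {
    img <- unflatten_rm(ds$lr_x[i, ], cfg$lr_size)
    v <- predict_voltages(m, img)
    rec <- dea_simulate(v, cfg, ds$curve, resolution = cfg$lr_size)$x
    mean_ssim(preprocess_image(img, cfg, flatten = FALSE),
              preprocess_image(rec, cfg, flatten = FALSE))
  }, numeric(1))
  expect_gte(mean(s), 0.8)
})

test_that("edge pixels are predicted at least as well as interior pixels", {
  m <- toy_inverse("x")
  ev <- evaluate_inverse(m, toy_dataset())
  border <- matrix(FALSE, 9, 9)
  border[c(1, 9), ] <- TRUE
  border[, c(1, 9)] <- TRUE
  expect_lte(mean(ev$error_grid[border]), mean(ev$error_grid[!border]))
})
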