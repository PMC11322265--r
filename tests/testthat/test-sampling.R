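test_that("sampling schemes have the advertised marginals", {
  cfg <- dea_config()
  curve <- dea_curve()
  vs <- sample_voltage_arrays(1000, sampling_scheme("uniform_voltage", seed = 3),
                              curve, cfg)
  v <- unlist(lapply(vs, function(a) a[1, 1]))
  expect_gt(stats::ks.test(v, "punif", 0, 7.1)$p.value, 0.01)
  ss <- sample_voltage_arrays(1000, sampling_scheme("uniform_strain", seed = 3),
                              curve, cfg)
  rng <- reachable_strain_range(curve)
  eps <- strain_from_voltage(unlist(lapply(ss, function(a) a[1, 1])), curve)
  expect_gt(stats::ks.test(eps, "punif", rng[1], rng[2])$p.value, 0.01)
  # determinism
  again <- sample_voltage_arrays(5, sampling_scheme(seed = 3), curve, cfg)
  first <- sample_voltage_arrays(5, sampling_scheme(seed = 3), curve, cfg)
  expect_identical(lapply(first, unclass), lapply(again, unclass))
  expect_error(sample_voltage_arrays(2, sampling_scheme(strain_lo = -5,
                                                        strain_hi = 1)),
               "reachable")
})

test_that("centre-strain extraction matches the commanded plateaus", {
  cfg <- dea_config()
  expect_equal(extract_center_strains(matrix(3.3, 60, 60), cfg), rep(3.3, 81))
  # negligible coupling + no taper: centres recover the commanded strains
  cfg0 <- dea_config(coupling_sigma_parallel = 1e-3,
                     coupling_sigma_perpendicular = 1e-3, boundary_margin = 0)
  set.seed(4)
  V <- matrix(runif(81, 0, 7.1), 9)
  sim <- dea_simulate(voltage_array(V, cfg0), cfg0, resolution = cfg0$hr_size)
  got <- extract_center_strains(sim$x, cfg0)
  expect_equal(got, as.vector(t(strain_from_voltage(V))), tolerance = 1e-6)
  expect_length(got, 81)
})

test_that("uniformity metrics match their closed forms", {
  # equal occupancy of 7 bins
  vals <- rep(seq(0.5, 6.5) * 10 - 5 + 0.226, 10)
  m <- strain_distribution_metrics(vals, 7, range = c(0.226, 69.32))
  expect_equal(m$std_of_probabilities, 0, tolerance = 1e-12)
  expect_equal(m$entropy, log(7), tolerance = 1e-12)
  # all mass in one of 7 bins: hand evaluation of both formulas
  p <- c(1, rep(0, 6))
  m1 <- strain_distribution_metrics(rep(1, 50) + runif(50) * 1e-6, 7,
                                    range = c(0, 70))
  expect_equal(m1$std_of_probabilities, sqrt(sum((p - 1 / 7)^2) / 6),
               tolerance = 1e-6)
  expect_equal(m1$entropy, 0)
  # order invariance
  set.seed(2)
  x <- runif(500, 0, 70)
  a <- strain_distribution_metrics(x, 7, c(0, 70))
  b <- strain_distribution_metrics(sample(x), 7, c(0, 70))
  expect_identical(a, b)
  expect_warning(strain_distribution_metrics(rep(5, 10), 7, c(0, 70)),
                 "degenerate")
})

test_that("uniform-strain sampling yields near-uniform simulated centres", {
  cfg <- dea_config()
  curve <- dea_curve()
  rng <- reachable_strain_range(curve)
  pool_for <- function(kind) {
    vs <- sample_voltage_arrays(10, sampling_scheme(kind, seed = 42), curve, cfg)
    unlist(lapply(vs, function(v) {
      extract_center_strains(dea_simulate(v, cfg, curve,
                                          resolution = cfg$lr_size)$x, cfg)
    }))
  }
  opt <- strain_distribution_metrics(pool_for("uniform_strain"), 7, rng)
  expect_lte(opt$std_of_probabilities, 0.05)
  expect_gte(opt$entropy, 1.85)
  # strictly more uniform than the uniform-voltage baseline at several n_bins
  pool_o <- pool_for("uniform_strain")
  pool_b <- pool_for("uniform_voltage")
  for (nb in c(3, 5, 7)) {
    mo <- strain_distribution_metrics(pool_o, nb, rng)
    mb <- strain_distribution_metrics(pool_b, nb, rng)
    expect_lt(mo$std_of_probabilities, mb$std_of_probabilities)
    expect_gt(mo$entropy, mb$entropy)
  }
})

test_that("dataset bookkeeping and persistence are consistent", {
  cfg <- dea_config(lr_size = 20L, hr_size = 160L)
  ds <- build_dataset(20, 5, sampling_scheme(seed = 8), cfg)
  expect_equal(dim(ds$voltages), c(25, 81))
  expect_equal(dim(ds$lr_x), c(25, 400))
  expect_equal(as.vector(table(ds$split)), c(20, 5))
  ds2 <- build_dataset(20, 5, sampling_scheme(seed = 8), cfg)
  expect_identical(ds$stamp, ds2$stamp)
  expect_identical(ds$lr_y, ds2$lr_y)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_equal(back$voltages, ds$voltages, tolerance = 1e-10)
  # images survive the 16-bit round trip
  expect_lt(max(abs(back$lr_x - ds$lr_x)), 1 / 65535)
  expect_identical(back$stamp, ds$stamp)
})
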