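# Shared fixtures, built once per test run and memoized in an environment.
# Everything is generated in code; sizes are chosen so the whole suite stays
# within a CPU-only budget.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

toy_dataset <- function() {
  memo("toy_dataset", function() {
    build_dataset(300, 30, sampling_scheme(seed = 42))
  })
}

toy_inverse <- function(axis = "x") {
  memo(paste0("toy_inverse_", axis), function() {
    train_inverse(toy_dataset(), axis, inverse_config(epochs = 12, seed = 1))
  })
}

toy_forward <- function() {
  memo("toy_forward", function() {
    train_forward_lr(toy_dataset(), forward_config(epochs = 5, seed = 1))
  })
}

sr_model_desk <- function() {
  memo("sr_model_desk", function() {
    train_super_resolution(sr_dataset(), "x", sr_config_desk(epochs = 8L,
                                                             seed = 2L))
  })
}

sr_dataset <- function() {
  memo("sr_dataset", function() {
    build_dataset(96, 6, sampling_scheme(seed = 11),
                  config = dea_config(lr_size = 10L, hr_size = 80L),
                  include_hr = TRUE)
  })
}

# deterministic pseudo-random images shared with the frozen scikit-image
# reference values in test-ssim.R (plain LCG, independent of R's RNG)
lcg_runif <- function(n, seed) {
  out <- numeric(n)
  s <- seed
  for (i in seq_len(n)) {
    s <- (1103515245 * s + 12345) %% 2147483648
    out[i] <- s / 2147483648
  }
  out
}

ssim_fixture_pair <- function(k) {
  a <- matrix(lcg_runif(32 * 32, 17 + k), 32)
  b <- pmin(pmax(a + 0.25 * matrix(lcg_runif(32 * 32, 99 + k), 32) - 0.125, 0), 1)
  list(a = a, b = b)
}
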