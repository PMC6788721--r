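# Synthetic envelope / raster generators: the injected statistics are the
# ground truth the estimators are validated against, so they get their own
# oracle checks here.

test_that("exponential-kernel latent process has the requested ACF", {
  tau <- 0.02
  coch <- gen_correlated_envelopes(texture_spec(1, 60, 1000, matrix(1),
                                                kernel_exponential(tau),
                                                seed = 21))
  z <- log(coch$envelopes[, 1])
  expect_equal(mean(z), 0, tolerance = 0.05)
  expect_equal(sd(z), 1, tolerance = 0.05)
  for (lag_s in c(0.005, 0.02, 0.06)) {
    k <- round(lag_s * 1000)
    emp <- cor(z[1:(length(z) - k)], z[(k + 1):length(z)])
    expect_lt(abs(emp - exp(-lag_s / tau)), 0.06)  # MC error, absolute
  }
})

test_that("periodic-kernel latent process has a damped-cosine ACF", {
  period <- 0.05; tau <- 4 * period
  coch <- gen_correlated_envelopes(texture_spec(1, 60, 1000, matrix(1),
                                                kernel_periodic(period),
                                                seed = 22))
  z <- log(coch$envelopes[, 1])
  for (lag_s in c(period / 2, period, 2 * period)) {
    k <- round(lag_s * 1000)
    emp <- cor(z[1:(length(z) - k)], z[(k + 1):length(z)])
    expect_lt(abs(emp - exp(-lag_s / tau) * cos(2 * pi * lag_s / period)),
              0.07)
  }
})

test_that("cross-channel latent correlation and envelope correlation match", {
  C <- diag(4); C[abs(row(C) - col(C)) == 1] <- 0.5
  coch <- gen_correlated_envelopes(texture_spec(4, 60, 1000, C,
                                                kernel_exponential(0.01),
                                                seed = 23))
  z <- log(coch$envelopes)
  emp_latent <- cor(z)
  expect_lt(abs(emp_latent[1, 2] - 0.5), 0.05)
  expect_lt(abs(emp_latent[1, 3]), 0.05)
  emp_env <- cor(coch$envelopes)
  ach <- attr(coch, "achieved_corr")
  expect_equal(ach[1, 2], (exp(0.5) - 1) / (exp(1) - 1), tolerance = 1e-12)
  expect_lt(abs(emp_env[1, 2] - ach[1, 2]), 0.07)  # envelopes are noisier
})

test_that("non-positive-definite correlation targets are rejected by name", {
  C <- matrix(-0.9, 3, 3); diag(C) <- 1
  expect_error(gen_correlated_envelopes(texture_spec(3, 1, 1000, C,
                                                     kernel_exponential(0.01),
                                                     seed = 1)),
               "eigenvalue")
  expect_error(texture_spec(2, 1, 1000, matrix(c(1, 0.5, 0.4, 1), 2),
                            kernel_exponential(0.01)),
               "symmetric")
})

test_that("regime switching alternates the correlation structure", {
  C_hi <- matrix(0.8, 3, 3); diag(C_hi) <- 1
  spec <- texture_spec(3, 4, 1000, C_hi, kernel_exponential(0.01),
                       regime = regime_switching(0.5, list(
                         list(),
                         list(target_spectral_corr = diag(3)))),
                       seed = 31)
  coch <- gen_correlated_envelopes(spec)
  z <- log(coch$envelopes)
  seg <- function(i) z[((i - 1) * 500 + 1):(i * 500), ]
  odd <- mean(vapply(c(1, 3, 5, 7), function(i) cor(seg(i))[1, 2],
                     numeric(1)))
  even <- mean(vapply(c(2, 4, 6, 8), function(i) cor(seg(i))[1, 2],
                      numeric(1)))
  expect_gt(odd, 0.55)
  expect_lt(abs(even), 0.3)
})

test_that("ensemble raster noise honours gain, spatial reach and truth attrs", {
  C <- diag(5)
  env <- gen_correlated_envelopes(texture_spec(5, 10, 1000, C,
                                               kernel_exponential(0.01),
                                               seed = 41))
  ns <- noise_spec(noise_gain = 0.5, spatial_reach = 1, spatial_rho = 0.5,
                   temporal_width = 0.003, seed = 42)
  raster <- gen_ensemble_raster(env, n_trials = 6, noise = ns)
  expect_s3_class(raster, "ensemble_raster")
  expect_equal(dim(raster), c(10000, 5, 6))
  truth <- attr(raster, "truth")
  eps <- sweep(unclass(raster), c(1, 2), truth$signal)
  # per-channel noise sd = noise_gain * sd(signal)
  for (k in 1:5)
    expect_equal(sd(eps[, k, ]), 0.5 * sd(truth$signal[, k]),
                 tolerance = 0.05)
  # spatial correlation: rho at offset 1, ~0 beyond the reach
  ec <- cor(eps[, , 1])
  expect_equal(mean(ec[abs(row(ec) - col(ec)) == 1]), 0.5, tolerance = 0.06)
  expect_lt(max(abs(ec[abs(row(ec) - col(ec)) >= 2])), 0.06)
  # noise is independent across trials
  expect_lt(abs(cor(as.numeric(eps[, 1, 1]), as.numeric(eps[, 1, 2]))), 0.05)
})

test_that("category dataset is reproducible, labelled and archetype-distinct", {
  ds1 <- gen_category_dataset(3, 2, within_jitter = 0.1, seed = 7,
                              duration = 2, n_channels = 5)
  ds2 <- gen_category_dataset(3, 2, within_jitter = 0.1, seed = 7,
                              duration = 2, n_channels = 5)
  expect_identical(ds1$labels, rep(1:3, each = 2))
  expect_length(ds1$envelopes, 6)
  expect_equal(ds1$envelopes[[1]]$envelopes, ds2$envelopes[[1]]$envelopes)
  expect_false(isTRUE(all.equal(ds1$envelopes[[1]]$envelopes,
                                ds1$envelopes[[2]]$envelopes)))
  expect_length(ds1$category_names, 3)
  expect_true(all(vapply(ds1$envelopes, function(e)
    all(e$envelopes >= 0), logical(1))))
})

test_that("waveform synthesis normalizes RMS and enforces Nyquist", {
  env <- gen_correlated_envelopes(texture_spec(3, 1, 1000, diag(3),
                                               kernel_exponential(0.01),
                                               seed = 51))
  bank <- design_filterbank(400, 1600, 1)
  x <- gen_waveform_from_envelopes(env, bank, 8000, seed = 2)
  expect_length(x, 8000)
  expect_equal(sqrt(mean(x^2)), 0.05, tolerance = 1e-12)
  expect_error(gen_waveform_from_envelopes(env, bank, 2000, seed = 2),
               "Nyquist")
})
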