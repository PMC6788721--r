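# Trial-shuffled ensemble correlation estimators.

make_toy_raster <- function(n_time = 800, L = 3, N = 4, rate = 1000,
                            seed = 13) {
  set.seed(seed)
  t <- seq_len(n_time) / rate
  sig <- sapply(seq_len(L), function(k)
    1 + 0.5 * sin(2 * pi * (2 + k) * t))
  R <- array(0, c(n_time, L, N))
  for (m in seq_len(N)) R[, , m] <- sig + 0.3 * matrix(rnorm(n_time * L),
                                                       n_time, L)
  ensemble_raster(R, rate = rate)
}

test_that("windowed pair correlation equals the direct triple loop", {
  r <- make_toy_raster()
  R <- corrcode:::center_raster(r)
  t_idx <- c(200, 500); lags <- -4:4
  got <- windowed_pair_correlation(R[, , 1], R[, , 2], 0.101, t_idx, lags,
                                   rate = 1000)
  w2 <- corrcode:::rect_window(0.101, 1000)
  want <- brute_windowed_corr(R[, , 1], R[, , 2], w2, t_idx, lags)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("fast shuffled correlogram equals the O(N^2) double sum", {
  r <- make_toy_raster()
  t_idx <- c(250, 400, 550); lags <- -3:3
  fast <- shuffled_correlation(r, 0.101, lags = lags, t_idx = t_idx)
  slow <- brute_shuffled(r, 0.101, t_idx, lags)
  expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-12)
})

test_that("c_total = c_stim + c_noise and is 1 on the zero-lag diagonal", {
  r <- make_toy_raster()
  ce <- ensemble_correlation(r, 0.101, lags = -3:3)
  expect_equal(ce$c_total, ce$c_stim + ce$c_noise, tolerance = 1e-10)
  li0 <- which(abs(ce$lags) < 1e-12)
  for (k in 1:3)
    expect_equal(max(abs(ce$c_total[, li0, k, k] - 1)), 0,
                 tolerance = 1e-10)
  expect_lte(max(abs(ce$c_total), na.rm = TRUE), 1 + 1e-9)
})

test_that("a noise-free raster has zero noise correlation", {
  r <- make_toy_raster()
  R0 <- unclass(r)
  for (m in 2:dim(R0)[3]) R0[, , m] <- R0[, , 1]
  r0 <- ensemble_raster(R0, rate = 1000)
  ce <- ensemble_correlation(r0, 0.101, lags = -2:2)
  expect_lt(max(abs(ce$Phi_noise)), 1e-10 * max(abs(ce$Phi_stim)))
  expect_equal(ce$c_stim, ce$c_total, tolerance = 1e-10)
})

test_that("single-trial correlograms are unit-diagonal and bounded", {
  r <- make_toy_raster()
  v <- single_trial_correlation(r, 2, 0.101, lags = -3:3)
  li0 <- 4
  for (k in 1:3)
    expect_equal(max(abs(v[, li0, k, k] - 1)), 0, tolerance = 1e-10)
  expect_lte(max(abs(v), na.rm = TRUE), 1 + 1e-9)
})

test_that("unshuffled/noise estimators agree with their definitions", {
  r <- make_toy_raster()
  t_idx <- c(300, 500); lags <- -2:2
  un <- unshuffled_correlation(r, 0.101, lags = lags, t_idx = t_idx)
  R <- corrcode:::center_raster(r)
  w2 <- corrcode:::rect_window(0.101, 1000)
  acc <- 0
  for (m in 1:4)
    acc <- acc + brute_windowed_corr(R[, , m], R[, , m], w2, t_idx, lags)
  expect_equal(un, acc / 4, tolerance = 1e-10)
  sh <- shuffled_correlation(r, 0.101, lags = lags, t_idx = t_idx)
  expect_equal(noise_correlation(un, sh), un - sh)
  expect_error(noise_correlation(un, sh[, 1:3, , , drop = FALSE]),
               "do not match")
})

test_that("normalization returns NA for zero-power channels", {
  r <- make_toy_raster()
  R <- unclass(r)
  R[, 2, ] <- 5                       # constant channel: zero variance
  r2 <- ensemble_raster(R, rate = 1000)
  ce <- ensemble_correlation(r2, 0.101, lags = 0L)
  expect_true(all(is.na(ce$c_total[, 1, 2, 2])))
  expect_false(anyNA(ce$c_total[, 1, 1, 1]))
  expect_error(ensemble_correlation(ensemble_raster(R[, , 1, drop = FALSE],
                                                    rate = 1000), 0.101),
               "fewer than 2 trials")
})

test_that("collapse_correlations produces offset and lag profiles", {
  M <- outer(1:4, 1:4, function(i, j) 0.5^abs(i - j))
  prof <- collapse_correlations(M, "spectral")
  expect_equal(as.numeric(prof), 0.5^(0:3))
  expect_error(collapse_correlations(matrix(1, 2, 3), "spectral"), "square")
  X <- cbind(c(1, 2), c(3, 4))
  expect_equal(as.numeric(collapse_correlations(X, "temporal")), c(2, 3))
})
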