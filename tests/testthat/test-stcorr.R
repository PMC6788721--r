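# Short-term spectro-temporal correlation estimator.

test_that("normalized short-term correlation matches a brute-force oracle", {
  set.seed(11)
  S <- matrix(abs(rnorm(400 * 3)), 400, 3)
  w <- window_spec(0.05)
  rate <- 1000
  lags <- -5:5
  t_idx <- c(100, 200, 300)
  stc <- short_term_correlation(S, w, t_idx = t_idx, lags = lags,
                                rate = rate)
  W <- kaiser_window_from_resolution(w$resolution, w$beta, rate, w$kind)
  w2 <- attr(W, "w2")
  Phi <- brute_windowed_corr(S, S, w2, t_idx, lags)
  h <- (length(w2) - 1) / 2
  for (ti in seq_along(t_idx)) {
    for (li in seq_along(lags)) {
      for (k in 1:3) {
        for (l in 1:3) {
          rows <- (t_idx[ti] - h):(t_idx[ti] + h)
          sk <- sum(w2 * S[rows, k]^2)
          sl <- sum(w2 * S[rows - lags[li], l]^2)
          expect_equal(stc$values[ti, li, k, l],
                       Phi[ti, li, k, l] / sqrt(sk * sl),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("window solver honours the 2-SD resolution definition", {
  for (res in c(0.025, 0.1, 0.566)) {
    W <- kaiser_window_from_resolution(res, sample_rate = 1000)
    expect_equal(attr(W, "realized"), res, tolerance = 0.02)
    expect_true(length(W) %% 2 == 1)
    expect_equal(as.numeric(W)^2, as.numeric(attr(W, "w2")), tolerance = 1e-12)
  }
  Wr <- kaiser_window_from_resolution(0.1, sample_rate = 1000,
                                      kind = "rectangular")
  n0 <- round(sqrt(3) * 100)                  # odd length ~ sqrt(3) * n
  expect_equal(length(Wr), n0 + (n0 %% 2 == 0))
  expect_error(kaiser_window_from_resolution(0.001, sample_rate = 1000),
               "unattainable")
})

test_that("default lag grid has 99 lags for a 100 ms window at 1 kHz", {
  w <- window_spec(0.1)
  lags <- corrcode:::lag_grid(w, 1000)
  expect_length(lags, 99)
  expect_equal(range(lags), c(-49, 49))
})

test_that("autocorrelation is 1 at zero lag and |c| is bounded by 1", {
  C <- 0.6^abs(outer(1:4, 1:4, "-")); diag(C) <- 1
  coch <- gen_correlated_envelopes(texture_spec(4, 4, 1000, C,
                                                kernel_exponential(0.01),
                                                seed = 5))
  stc <- short_term_correlation(coch, window_spec(0.1))
  li0 <- which(abs(stc$lags) < 1e-12)
  for (k in 1:4)
    expect_equal(max(abs(stc$values[, li0, k, k] - 1)), 0, tolerance = 1e-8)
  expect_lte(max(abs(stc$values)), 1 + 1e-9)
  expect_identical(stc$n_zero_power, 0L)
})

test_that("a shared envelope yields near-unit correlation, an independent one less", {
  set.seed(3)
  t <- seq(0, 4, by = 1e-3)[-1]
  common <- 1 + 0.8 * sin(2 * pi * 3 * t)
  S <- cbind(common, 0.5 * common, abs(rnorm(length(t))) + 0.2)
  stc <- short_term_correlation(S, window_spec(0.1), lags = 0L, rate = 1000)
  expect_gt(min(stc$values[, 1, 1, 2]), 0.99)
  # envelopes are not mean-removed, so independent positive channels keep a
  # baseline ~ mu1*mu2 / sqrt(m2_1 * m2_2) < 1; just require clear separation
  expect_lt(mean(stc$values[, 1, 1, 3]), 0.9)
  expect_gt(mean(stc$values[, 1, 1, 2]) - mean(stc$values[, 1, 1, 3]), 0.2)
})

test_that("decompositions have the documented shapes", {
  set.seed(4)
  S <- matrix(abs(rnorm(2000 * 3)), 2000, 3)
  stc <- short_term_correlation(S, window_spec(0.1), lags = -4:4,
                                rate = 1000)
  nt <- dim(stc$values)[1]
  sp <- decompose_correlation(stc, "spectral")
  expect_equal(dim(sp), c(nt, 3 * 4 / 2))
  tm <- decompose_correlation(stc, "temporal")
  expect_equal(dim(tm), c(nt * 3, 5))             # nonnegative lags only
  expect_equal(attr(tm, "lags"), (0:4) / 1000)
  st <- decompose_correlation(stc, "spectrotemporal")
  expect_equal(dim(st), c(nt, 9 * 3 * 3))
  # spectral view at zero lag contains the unit diagonal entries
  diag_cols <- cumsum(1:3)                        # positions of (k,k) in upper tri
  expect_equal(max(abs(sp[, diag_cols] - 1)), 0, tolerance = 1e-8)
})

test_that("time-averaged temporal width grows with the envelope timescale", {
  C <- diag(3)
  w <- window_spec(0.1)
  widths <- vapply(c(0.002, 0.01), function(tau) {
    coch <- gen_correlated_envelopes(texture_spec(3, 6, 1000, C,
                                                  kernel_exponential(tau),
                                                  seed = 8))
    ta <- time_average_correlation(short_term_correlation(coch, w))
    mean(ta$width50)
  }, numeric(1))
  expect_false(anyNA(widths))
  expect_gt(widths[2], widths[1])
})

test_that("correlation similarity behaves and rejects degenerate input", {
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(correlation_similarity(m, m), 1)
  expect_error(correlation_similarity(m, diag(3)), "matched shapes")
  expect_error(correlation_similarity(diag(2), diag(2),
                                      exclude_diagonal = TRUE),
               "constant")
  a <- matrix(c(1, 0.2, 0.2, 1), 2); b <- matrix(c(1, -0.2, -0.2, 1), 2)
  expect_equal(correlation_similarity(a, b, exclude_diagonal = FALSE),
               cor(as.numeric(a), as.numeric(b)))
})

test_that("evaluation too near the record edge is an error", {
  S <- matrix(abs(rnorm(300 * 2)), 300, 2)
  expect_error(short_term_correlation(S, window_spec(0.1), t_idx = c(5),
                                      lags = 0L, rate = 1000),
               "too near the record edges")
  expect_error(short_term_correlation(S[1:50, ], window_spec(0.1),
                                      rate = 1000),
               "window longer than the signal")
})
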