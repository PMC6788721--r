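# PCA, naive-Bayes / GMM MAP classifiers, model averaging, controls.

test_that("PCA matches prcomp and honours both retention modes", {
  set.seed(61)
  x <- matrix(rnorm(50 * 6), 50) %*% diag(c(4, 3, 2, 1, 0.5, 0.1))
  p <- fit_pca(x, retain = 3)
  expect_equal(p$n_components, 3L)
  ref <- prcomp(x, center = TRUE)
  expect_equal(abs(predict(p, x)), abs(ref$x[, 1:3]), tolerance = 1e-10)
  pf <- fit_pca(x, retain = 0.9)
  expect_gte(sum(pf$explained[seq_len(pf$n_components)]), 0.9)
  expect_lt(sum(pf$explained[seq_len(pf$n_components - 1)]), 0.9)
  expect_error(fit_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("Gaussian naive Bayes separates blobs and matches dnorm scores", {
  set.seed(62)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c("a", "b"), each = 20)
  mod <- fit_gaussian_bayes(x, y)
  pr <- map_classify(mod, x, combine_n = 1)
  expect_equal(pr$class, y)
  # log-likelihood agrees with a hand computation for one observation
  ll <- corrcode:::class_loglik(mod, x[1, , drop = FALSE])
  want <- sapply(1:2, function(ci)
    sum(dnorm(x[1, ], mod$means[ci, ], sqrt(mod$vars[ci, ]), log = TRUE)))
  expect_equal(as.numeric(ll), want, tolerance = 1e-12)
  expect_error(fit_gaussian_bayes(x[c(1, 21, 22), ], y[c(1, 21, 22)]),
               "at least 2 observations")
})

test_that("MAP ties break to the lowest class index and blocks combine", {
  x <- matrix(c(0, 1, 0, 1), 4, 2)
  mod <- fit_gaussian_bayes(rbind(x, x), rep(c("a", "b"), each = 4))
  pr <- map_classify(mod, x[1:2, , drop = FALSE], combine_n = 1)
  expect_equal(pr$class, c("a", "a"))          # identical classes: tie -> first
  # combine_n = 2 sums the per-row log-likelihoods of each block
  set.seed(63)
  x2 <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 3), 10))
  y2 <- rep(c("a", "b"), each = 10)
  m2 <- fit_gaussian_bayes(x2, y2)
  r1 <- map_classify(m2, x2, combine_n = 5)
  expect_length(r1$class, 4)
  ll <- corrcode:::class_loglik(m2, x2)
  expect_equal(r1$loglik[1, ], colSums(ll[1:5, ]), tolerance = 1e-12)
  expect_equal(unname(rowSums(exp(r1$log_posterior))), rep(1, 4),
               tolerance = 1e-10)
})

test_that("diagonal GMM density matches a manual mixture computation", {
  model <- structure(list(
    weights = c(0.3, 0.7),
    means = rbind(c(0, 0), c(2, -1)),
    vars = rbind(c(1, 0.5), c(0.2, 2))), class = "diag_gmm")
  set.seed(64)
  X <- matrix(rnorm(20), 10, 2)
  got <- corrcode:::gmm_log_density(model, X)
  want <- log(0.3 * dnorm(X[, 1], 0, 1) * dnorm(X[, 2], 0, sqrt(0.5)) +
              0.7 * dnorm(X[, 1], 2, sqrt(0.2)) * dnorm(X[, 2], -1, sqrt(2)))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("EM recovers well-separated components and rivals mclust", {
  library(mclust)
  set.seed(65)
  X <- rbind(matrix(rnorm(120, 0, 0.5), 60, 2),
             sweep(matrix(rnorm(120, 0, 0.5), 60, 2), 2, c(4, 0), "+"),
             sweep(matrix(rnorm(120, 0, 0.5), 60, 2), 2, c(0, 4), "+"))
  fit <- fit_diag_gmm(X, 3, seed = 1)
  mu <- fit$means[order(fit$means[, 1] - fit$means[, 2]), ]
  expect_equal(mu, rbind(c(0, 4), c(0, 0), c(4, 0)), tolerance = 0.25)
  expect_equal(sort(fit$weights), rep(1 / 3, 3), tolerance = 0.05)
  # achieved log-likelihood is as good as mclust's diagonal-covariance EM
  mc <- mclust::Mclust(X, G = 3, modelNames = "VVI", verbose = FALSE)
  expect_gte(fit$loglik, mc$loglik - abs(mc$loglik) * 0.01)
})

test_that("cross-validated likelihood selects the true component count", {
  set.seed(66)
  X <- rbind(matrix(rnorm(100, 0, 0.4), 50, 2),
             sweep(matrix(rnorm(100, 0, 0.4), 50, 2), 2, c(3, 3), "+"))
  sel <- select_gmm_components(X, grid = 1:4, seed = 2)
  expect_equal(sel$n_components, 2L)
  expect_s3_class(sel$model, "diag_gmm")
})

test_that("model averaging interpolates between the two views", {
  set.seed(67)
  xs <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
  xt <- matrix(rnorm(40), 20)                  # uninformative temporal view
  y <- rep(c("a", "b"), each = 10)
  ms <- fit_gaussian_bayes(xs, y); mt <- fit_gaussian_bayes(xt, y)
  r <- model_average_classify(ms, mt, 1, xs, xt, combine_n = 5)
  expect_equal(r$class, c("a", "a", "b", "b"))
  a <- optimize_alpha(ms, mt, xs, xt, y[seq(1, 20, 5)], combine_n = 5)
  expect_gt(a, 0.5)                            # spectral view carries the info
  expect_error(model_average_classify(ms, mt, 1.5, xs, xt), "0, 1")
})

test_that("tonotopy shuffling permutes channel blocks intact", {
  x <- matrix(rep(1:4, each = 3), 2, 12, byrow = TRUE)   # 4 blocks of 3 lags
  s <- shuffle_tonotopy(x, 4, seed = 3)
  for (i in 1:2) {
    blocks <- matrix(s[i, ], nrow = 3)
    expect_true(all(apply(blocks, 2, function(b) length(unique(b)) == 1)))
    expect_setequal(blocks[1, ], 1:4)
  }
  expect_error(shuffle_tonotopy(x, 5, seed = 1), "channel-blocked")
})

test_that("spectrum features separate two tones at different channels", {
  fs <- 16000
  bank <- design_filterbank(400, 3200, 1 / 2)
  t <- seq(0, 2, by = 1 / fs)[-1]
  c1 <- compute_cochleogram(0.1 * sin(2 * pi * bank$center_freqs[2] * t),
                            fs, bank)
  c2 <- compute_cochleogram(0.1 * sin(2 * pi * bank$center_freqs[6] * t),
                            fs, bank)
  w <- window_spec(0.1)
  f1 <- spectrum_features(c1, w); f2 <- spectrum_features(c2, w)
  y <- rep(c("t1", "t2"), c(nrow(f1), nrow(f2)))
  mod <- fit_gaussian_bayes(rbind(f1, f2), y)
  pr <- map_classify(mod, rbind(f1, f2), combine_n = 1)
  expect_equal(mean(pr$class == y), 1)
})

test_that("window ladder and performance curve follow their definitions", {
  expect_equal(window_count_ladder(16), c(1, 2, 3, 4, 6, 8, 11, 16))
  pc <- performance_curve(c(0.1, 0.2, 0.4, 0.8), c(50, 80, 90, 100))
  expect_equal(pc$asymptote, 100)
  expect_equal(pc$tau_c, 0.4, tolerance = 1e-12)
  expect_warning(performance_curve(c(0.1, 0.2, 0.4), c(80, 70, 90)),
                 "non-monotone")
  # crossing below the first grid point returns the first duration
  pc2 <- performance_curve(c(0.1, 0.2, 0.4), c(95, 98, 100))
  expect_equal(pc2$tau_c, 0.1)
})

test_that("leave-one-out classification on trivially separable sounds", {
  set.seed(68)
  feats <- c(lapply(1:3, function(i) matrix(rnorm(40, 0), 10)),
             lapply(1:3, function(i) matrix(rnorm(40, 5), 10)))
  labs <- rep(c("lo", "hi"), each = 3)
  res <- classify_loo(feats, labs, n_windows = c(1, 4), retain = 2, seed = 1)
  expect_equal(as.numeric(res$accuracy), c(100, 100))
  expect_equal(dim(res$predictions), c(6, 2))
  expect_error(classify_loo(feats[c(1, 4)], labs[c(1, 4)]), "2 sounds per")
  expect_warning(classify_loo(feats, labs, n_windows = 50, seed = 1),
                 "truncating")
})
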