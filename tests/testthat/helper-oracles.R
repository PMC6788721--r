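# Independent reference implementations used to validate the fast estimators,
# plus small shared utilities for the statistical tests.

# Direct triple-loop windowed cross-correlation:
# Phi[t, tau, k, l] = sum_j X[t+j, k] * Y[t+j-tau, l] * w2[j + h + 1]
brute_windowed_corr <- function(X, Y, w2, t_idx, lags) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  h <- (length(w2) - 1) / 2
  out <- array(0, c(length(t_idx), length(lags), ncol(X), ncol(Y)))
  for (ti in seq_along(t_idx)) {
    for (li in seq_along(lags)) {
      for (k in seq_len(ncol(X))) {
        for (l in seq_len(ncol(Y))) {
          s <- 0
          for (j in -h:h) {
            g <- t_idx[ti] + j
            s <- s + X[g, k] * Y[g - lags[li], l] * w2[j + h + 1]
          }
          out[ti, li, k, l] <- s
        }
      }
    }
  }
  out
}

# O(N^2) shuffled correlogram: average of windowed cross-trial correlations
# over all ordered pairs of distinct trials, on the globally centered raster.
brute_shuffled <- function(raster, duration, t_idx, lags) {
  rate <- attr(raster, "rate")
  R <- unclass(raster)
  mu <- colMeans(R)
  R <- sweep(R, c(2, 3), mu)
  N <- dim(R)[3]
  acc <- 0
  for (m in seq_len(N)) {
    for (n in seq_len(N)) {
      if (m == n) next
      acc <- acc + windowed_pair_correlation(R[, , m], R[, , n], duration,
                                             t_idx, lags, rate)
    }
  }
  acc / (N * (N - 1))
}

# Monte-Carlo chance distribution: accuracy of uniform guessing over
# n_decisions balanced-label decisions, as (mean, sd) over `draws` repeats.
mc_chance <- function(n_decisions, n_classes, draws = 10000, seed = 99) {
  truth <- rep_len(seq_len(n_classes), n_decisions)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  acc <- replicate(draws,
                   mean(sample.int(n_classes, n_decisions, TRUE) == truth))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  c(mean = mean(acc), sd = stats::sd(acc))
}

# Exemplar generator for the spectrum-invariance experiment: three classes
# that differ in cross-channel envelope correlation (rho) and in spectral
# tilt; the tilt is the only long-term spectral cue and is removed by 1/f
# equalization. Returns waveforms at fs.
make_tilted_texture_set <- function(base_seed, bank, fs, duration = 3,
                                    n_exemplars = 8, envelope_rate = 1000) {
  Lc <- bank$n_channels
  rhos <- c(0.1, 0.45, 0.8)
  gains <- list(seq(1, 0.3, length.out = Lc),
                seq(0.3, 1, length.out = Lc),
                c(seq(0.3, 1, length.out = ceiling(Lc / 2)),
                  seq(1, 0.3, length.out = floor(Lc / 2))))
  make_wave <- function(ci, ei) {
    s <- base_seed + 37 * ci + ei
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(s)
    jit <- list(r = stats::rnorm(1, 0, 0.1), t = stats::rnorm(1, 0, 0.2),
                g = stats::rnorm(Lc, 0, 0.1))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    rho <- stats::plogis(stats::qlogis(rhos[ci]) + jit$r)
    tau <- 0.02 * exp(jit$t)
    C <- rho^abs(outer(seq_len(Lc), seq_len(Lc), "-")); diag(C) <- 1
    env <- gen_correlated_envelopes(texture_spec(
      Lc, duration, envelope_rate, C, kernel_exponential(tau), seed = s))
    env$envelopes <- sweep(env$envelopes, 2, gains[[ci]] * exp(jit$g), "*")
    gen_waveform_from_envelopes(env, bank, fs, envelope_rate, seed = s + 7)
  }
  waves <- unlist(lapply(1:3, function(ci)
    lapply(seq_len(n_exemplars), function(ei) make_wave(ci, ei))),
    recursive = FALSE)
  list(waves = waves, labels = rep(1:3, each = n_exemplars))
}

# Whole-record features for the spectrum-invariance experiment (one row per
# exemplar kills window-to-window fluctuation cues, isolating the long-term
# spectral profile vs. the correlation structure).
whole_record_spectrum <- function(coch, w = window_spec(0.1)) {
  matrix(colMeans(spectrum_features(coch, w)), 1)
}
whole_record_spectral_corr <- function(coch, w = window_spec(0.1)) {
  stc <- short_term_correlation(coch, w, lags = 0L)
  matrix(colMeans(decompose_correlation(stc, "spectral")), 1)
}

# Leave-one-exemplar-out Gaussian naive-Bayes accuracy (percent) on a list
# of one-row feature matrices.
loo_exemplar_accuracy <- function(feature_rows, labels) {
  x <- do.call(rbind, feature_rows)
  pred <- vapply(seq_len(nrow(x)), function(i) {
    mod <- fit_gaussian_bayes(x[-i, , drop = FALSE], labels[-i])
    map_classify(mod, x[i, , drop = FALSE], combine_n = 1)$class
  }, character(1))
  100 * mean(pred == as.character(labels))
}
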