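# Correlation feature vectors for the neural classifiers: windowed shuffled
# (noiseless) or single-trial correlations about randomly selected time
# points, in spectral / temporal / spectrum (rate) views.

vec_upper <- function(M) M[upper.tri(M, diag = TRUE)]

#' Extract neural correlation feature vectors
#'
#' Draws `n_samples` random evaluation times (and, for single-trial
#' provenance, random trials jointly) and returns one feature row per draw:
#' `spectral` = vectorized zero-lag correlation matrix (upper triangle with
#' diagonal), `temporal` = concatenated per-channel lag profiles (tonotopy
#' preserved by block position), `spectrum` = per-channel windowed mean
#' amplitude (rate code). Shuffled provenance uses the noise-free
#' stimulus-driven correlations; single-trial provenance uses normalized
#' same-trial correlograms (signal + noise).
#'
#' @param raster an [ensemble_raster()].
#' @param mode `"spectral"`, `"temporal"` or `"spectrum"`.
#' @param provenance `"shuffled"` (noiseless) or `"single_trial"`.
#' @param n_samples feature vectors to draw.
#' @param duration correlation window duration, seconds.
#' @param max_lag largest temporal-correlation lag, seconds.
#' @param lag_step lag grid step in samples (coarser grids shrink the
#'   temporal feature dimension).
#' @param seed integer seed.
#' @return observation x feature matrix with attribute `n_channels`.
#' @export
neural_features <- function(raster,
                            mode = c("spectral", "temporal", "spectrum"),
                            provenance = c("shuffled", "single_trial"),
                            n_samples = 100, duration = 0.5, max_lag = 0.1,
                            lag_step = 1, seed = 1L) {
  mode <- match.arg(mode)
  provenance <- match.arg(provenance)
  rate <- raster_rate(raster)
  L <- dim(raster)[2]; N <- dim(raster)[3]
  w2 <- rect_window(duration, rate)
  h <- (length(w2) - 1) / 2
  lags <- if (mode == "temporal") {
    half <- round(max_lag * rate)
    unique(c(rev(seq(0, -half, by = -lag_step)), seq(0, half, by = lag_step)))
  } else 0L
  margin <- h + max(abs(lags))
  lo <- margin + 1; hi <- dim(raster)[1] - margin
  if (hi < lo) stop("window exceeds the record")
  draws <- with_seed(seed, list(t = sample(lo:hi, n_samples, replace = TRUE),
                                m = sample(N, n_samples, replace = TRUE)))
  if (mode == "spectrum") {
    src <- if (provenance == "shuffled") psth(raster) else NULL
    x <- t(vapply(seq_len(n_samples), function(i) {
      seg <- if (provenance == "shuffled")
        src[(draws$t[i] - h):(draws$t[i] + h), , drop = FALSE]
      else unclass(raster)[(draws$t[i] - h):(draws$t[i] + h), ,
                           draws$m[i], drop = FALSE][, , 1]
      colMeans(as.matrix(seg))
    }, numeric(L)))
    attr(x, "n_channels") <- L
    return(x)
  }
  featurize <- function(vals, ti) {
    if (mode == "spectral") {
      vec_upper(array(vals[ti, 1, , ], c(L, L)))
    } else {
      as.numeric(vapply(seq_len(L), function(k) vals[ti, , k, k],
                        numeric(length(lags))))
    }
  }
  if (provenance == "shuffled") {
    ce <- ensemble_correlation(raster, duration, lags = lags,
                               t_idx = draws$t)
    vals <- ce$c_stim
    vals[!is.finite(vals)] <- 0
    x <- t(vapply(seq_len(n_samples), function(i) featurize(vals, i),
                  numeric(if (mode == "spectral") L * (L + 1) / 2
                          else L * length(lags))))
  } else {
    x <- matrix(0, n_samples, if (mode == "spectral") L * (L + 1) / 2
                else L * length(lags))
    for (m in sort(unique(draws$m))) {
      sel <- which(draws$m == m)
      vals <- single_trial_correlation(raster, m, duration, lags = lags,
                                       t_idx = draws$t[sel])
      vals[!is.finite(vals)] <- 0
      for (j in seq_along(sel)) x[sel[j], ] <- featurize(vals, j)
    }
  }
  attr(x, "n_channels") <- L
  attr(x, "lags") <- lags / rate
  x
}
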