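# Short-term (running) spectro-temporal correlation statistics of
# cochleograms: Kaiser-windowed correlograms normalized as correlation
# coefficients, spectral/temporal decompositions, and time averages.

#' Analysis window specification
#'
#' The squared window W^2 is a Kaiser window (beta = 3.4 by default) whose
#' temporal resolution tau_w equals twice the standard deviation of the
#' window treated as a density. Maximum correlation lag defaults to half the
#' resolution.
#'
#' @param resolution window resolution tau_w in seconds (2 SD of W^2).
#' @param beta Kaiser shape parameter.
#' @param kind `"kaiser"` or `"rectangular"`.
#' @param max_lag largest correlation lag in seconds.
#' @export
window_spec <- function(resolution, beta = 3.4, kind = "kaiser",
                        max_lag = resolution / 2) {
  stopifnot(resolution > 0, max_lag > 0)
  structure(list(kind = kind, beta = beta, resolution = resolution,
                 max_lag = max_lag), class = "window_spec")
}

window_sd_samples <- function(w) {
  i <- seq_along(w) - (length(w) + 1) / 2
  sqrt(sum(w * i^2) / sum(w))
}

#' Solve a Kaiser window length for a target temporal resolution
#'
#' Returns the window amplitude W (so that W^2 is the Kaiser window) whose
#' squared-window 2-SD width equals `resolution` at the given sample rate;
#' the length is solved numerically. `kind = "rectangular"` yields a flat
#' window of length ~ sqrt(3) * resolution.
#'
#' @param resolution target 2-SD width, seconds.
#' @param beta Kaiser shape parameter.
#' @param sample_rate Hz.
#' @param kind window type.
#' @return numeric window amplitudes W (odd length) with attribute `w2`.
#' @export
kaiser_window_from_resolution <- function(resolution, beta = 3.4,
                                          sample_rate, kind = "kaiser") {
  if (resolution < 4 / sample_rate)
    stop("resolution unattainable at this sample rate (< 4 sample periods)")
  target <- resolution * sample_rate / 2    # target SD in samples
  if (kind == "rectangular") {
    n <- round(sqrt(3) * resolution * sample_rate)
    n <- n + (n %% 2 == 0)
    w2 <- rep(1, n)
  } else {
    n_ref <- 257
    s_ref <- window_sd_samples(signal::kaiser(n_ref, beta))
    n0 <- round(n_ref * target / s_ref)
    n0 <- n0 + (n0 %% 2 == 0)               # odd lengths only
    cand <- seq(max(5, n0 - 6), n0 + 6, by = 2)
    err <- vapply(cand, function(n)
      abs(window_sd_samples(signal::kaiser(n, beta)) - target), numeric(1))
    n <- cand[which.min(err)]
    w2 <- as.numeric(signal::kaiser(n, beta))
  }
  structure(sqrt(w2), w2 = w2, resolution = resolution,
            realized = 2 * window_sd_samples(w2) / sample_rate)
}

# lag grid in samples for a window spec at a sample rate
lag_grid <- function(window, sample_rate) {
  half <- ceiling(window$max_lag * sample_rate) - 1
  seq(-half, half)
}

#' Running short-term spectro-temporal correlation of a cochleogram
#'
#' Discrete implementation of
#' `Phi_kl(t, tau) = sum_g S_k(g) S_l(g - tau) W^2(t - g)`,
#' normalized by the windowed second moments of each channel (the tau-shifted
#' moment for channel l) so that values lie in `[-1, 1]` (Cauchy-Schwarz) and
#' `c_kk(t, 0) = 1` wherever the channel has power. Envelopes are not
#' mean-removed. Time points whose window or lag support overhangs the record
#' are excluded; points with zero windowed power yield 0 and are counted in
#' attribute `n_zero_power`.
#'
#' @param coch a [cochleogram] (or time x channel matrix with `rate`).
#' @param window a [window_spec()].
#' @param t_step spacing of evaluation times in seconds; defaults to the
#'   window resolution (successive non-overlapping segments).
#' @param t_idx optional explicit evaluation sample indices.
#' @param lags optional integer lag vector in samples (defaults to the
#'   symmetric grid implied by `max_lag`).
#' @param rate sample rate when `coch` is a bare matrix.
#' @return object of class `short_term_correlation` with `values`
#'   (time x lag x channel x channel), `times`, `lags` (seconds),
#'   `channel_freqs`, `window`.
#' @export
short_term_correlation <- function(coch, window, t_step = window$resolution,
                                   t_idx = NULL, lags = NULL, rate = NULL) {
  if (inherits(coch, "cochleogram")) {
    S <- coch$envelopes; rate <- coch$envelope_rate
    cf <- coch$channel_freqs
  } else {
    S <- as.matrix(coch); cf <- seq_len(ncol(S))
    stopifnot(!is.null(rate))
  }
  if (ncol(S) < 2) stop("need at least 2 channels")
  W <- kaiser_window_from_resolution(window$resolution, window$beta, rate,
                                     window$kind)
  w2 <- attr(W, "w2")
  if (length(w2) >= nrow(S)) stop("window longer than the signal")
  if (is.null(lags)) lags <- lag_grid(window, rate)
  h <- (length(w2) - 1) / 2
  if (is.null(t_idx))
    t_idx <- default_time_grid(nrow(S), h, max(abs(lags)),
                               round(t_step * rate))
  Phi <- windowed_corr_engine(S, S, w2, t_idx, lags)
  sig_l <- windowed_power_engine(S, w2, t_idx, lags)         # [t, lag, l]
  sig_k <- windowed_power_engine(S, w2, t_idx, 0L)[, 1, ]    # [t, k]
  sig_k <- matrix(sig_k, nrow = length(t_idx))
  cvals <- Phi
  n_zero <- 0L
  for (ti in seq_along(t_idx)) {
    for (li in seq_along(lags)) {
      den <- sqrt(outer(sig_k[ti, ], sig_l[ti, li, ]))
      x <- Phi[ti, li, , ] / den
      bad <- !is.finite(x)
      n_zero <- n_zero + sum(bad)
      x[bad] <- 0
      cvals[ti, li, , ] <- x
    }
  }
  structure(list(values = cvals, times = (t_idx - 1) / rate,
                 lags = lags / rate, channel_freqs = cf, window = window,
                 rate = rate, n_zero_power = n_zero),
            class = "short_term_correlation")
}

#' @export
print.short_term_correlation <- function(x, ...) {
  d <- dim(x$values)
  cat("Short-term correlation:", d[1], "time points x", d[2], "lags x",
      d[3], "x", d[4], "channels\n")
  cat(sprintf("  window %s tau_w = %g ms, lags %g..%g ms\n", x$window$kind,
              1000 * x$window$resolution, 1000 * min(x$lags),
              1000 * max(x$lags)))
  invisible(x)
}

#' Decompose a short-term correlation into feature views
#'
#' `spectral`: zero-lag correlations between channels, vectorized upper
#' triangle including the diagonal, one observation per time point.
#' `temporal`: same-channel correlations across nonnegative lags, with time
#' points and channels both treated as observations. `spectrotemporal`: the
#' full tensor vectorized per time point.
#'
#' @param stc a [short_term_correlation()].
#' @param mode one of `"spectral"`, `"temporal"`, `"spectrotemporal"`.
#' @return observation x feature matrix with attributes describing the view.
#' @export
decompose_correlation <- function(stc,
                                  mode = c("spectral", "temporal",
                                           "spectrotemporal")) {
  mode <- match.arg(mode)
  v <- stc$values
  d <- dim(v)
  L <- d[3]
  if (mode == "spectral") {
    li <- which(abs(stc$lags) < 1e-12)
    if (length(li) != 1) stop("spectral view needs a zero-lag estimate")
    ut <- upper.tri(matrix(0, L, L), diag = TRUE)
    x <- t(vapply(seq_len(d[1]), function(ti) {
      m <- array(v[ti, li, , ], c(L, L))
      m[ut]
    }, numeric(sum(ut))))
    attr(x, "mode") <- "spectral"
  } else if (mode == "temporal") {
    keep <- which(stc$lags >= 0)
    x <- do.call(rbind, lapply(seq_len(L), function(k)
      matrix(v[, keep, k, k], nrow = d[1])))
    attr(x, "mode") <- "temporal"
    attr(x, "channel") <- rep(seq_len(L), each = d[1])
    attr(x, "lags") <- stc$lags[keep]
  } else {
    x <- matrix(v, nrow = d[1])
    attr(x, "mode") <- "spectrotemporal"
  }
  attr(x, "times") <- stc$times
  x
}

#' Time-averaged correlation and temporal half-widths
#'
#' Averages the short-term correlation over (valid) time points and reports,
#' per channel, the full width of the time-averaged temporal correlation at
#' 50% and 10% of its maximum (linear interpolation between lag samples; NA
#' when the level is never crossed inside the lag range).
#'
#' @param stc a [short_term_correlation()].
#' @return list with `average` (lag x channel x channel array), `spectral`
#'   (zero-lag channel matrix, when available), `temporal` (lag x channel),
#'   `width50`, `width10` (seconds per channel).
#' @export
time_average_correlation <- function(stc) {
  avg <- apply(stc$values, c(2, 3, 4), mean)
  L <- dim(avg)[2]
  temporal <- sapply(seq_len(L), function(k) avg[, k, k])
  width_at <- function(frac) {
    vapply(seq_len(L), function(k) {
      ck <- temporal[, k]
      pos <- which(stc$lags >= 0)
      ck <- ck[pos]; lg <- stc$lags[pos]
      thr <- frac * max(ck)
      below <- which(ck < thr)
      if (!length(below)) return(NA_real_)
      i <- below[1]
      if (i == 1) return(0)
      x0 <- lg[i - 1] + (lg[i] - lg[i - 1]) *
        (ck[i - 1] - thr) / (ck[i - 1] - ck[i])
      2 * x0
    }, numeric(1))
  }
  li0 <- which(abs(stc$lags) < 1e-12)
  list(average = avg,
       spectral = if (length(li0) == 1) avg[li0, , ] else NULL,
       temporal = temporal, lags = stc$lags,
       width50 = width_at(0.5), width10 = width_at(0.1))
}

#' Pearson similarity between two correlation structures
#'
#' Compares corresponding entries of two equally shaped correlation arrays
#' or matrices, optionally excluding diagonal terms (k = l entries of a
#' square matrix, or the zero-lag column of a lag-indexed view).
#'
#' @param c_a,c_b matched correlation matrices/arrays.
#' @param exclude_diagonal drop k = l (square matrix) entries before
#'   correlating.
#' @return Pearson correlation coefficient.
#' @export
correlation_similarity <- function(c_a, c_b, exclude_diagonal = FALSE) {
  if (!all(dim(as.array(c_a)) == dim(as.array(c_b))))
    stop("correlation structures must have matched shapes")
  a <- as.array(c_a); b <- as.array(c_b)
  if (exclude_diagonal) {
    if (length(dim(a)) == 2 && nrow(a) == ncol(a)) {
      keep <- row(a) != col(a)
      a <- a[keep]; b <- b[keep]
    } else stop("exclude_diagonal needs a square matrix")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson similarity undefined for constant inputs")
  stats::cor(as.numeric(a), as.numeric(b))
}
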