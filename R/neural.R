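# Trial-shuffled neural ensemble correlation estimators: stimulus-driven
# (shuffled), unshuffled, and noise correlograms with correlation-coefficient
# normalization, for channel x trial x time aMUA rasters.

#' Construct an ensemble raster
#'
#' @param responses time x channel x trial array of aMUA envelopes.
#' @param rate sampling rate, Hz (2000 for aMUA).
#' @param channel_order optional tonotopic (best-frequency) channel order.
#' @export
ensemble_raster <- function(responses, rate = 2000, channel_order = NULL) {
  responses <- as.array(responses)
  stopifnot(length(dim(responses)) == 3)
  structure(responses, rate = rate,
            channel_order = channel_order %||% seq_len(dim(responses)[2]),
            class = "ensemble_raster")
}

raster_rate <- function(raster) attr(raster, "rate") %||% 2000

# per-channel, per-trial mean removal over the whole record
center_raster <- function(raster) {
  R <- unclass(raster)
  mu <- colMeans(R)                       # channel x trial means
  sweep(R, c(2, 3), mu)
}

rect_window <- function(duration, rate) {
  n <- round(duration * rate)
  n <- n + (n %% 2 == 0)
  rep(1, n)
}

# default lag grid: +/- 100 ms inclusive (401 lags at 2 kHz)
neural_lags <- function(rate, max_lag = 0.1) {
  half <- round(max_lag * rate)
  seq(-half, half)
}

#' Windowed cross-correlation between two response trials
#'
#' `phi_kl,mn(t, tau) = sum_g r_km(g) r_ln(g - tau) W^2(t - g)` for a unit
#' rectangular window of the given duration centered on each evaluation
#' time. Inputs are assumed mean-removed.
#'
#' @param r_km,r_ln mean-removed single-trial responses (vectors or time x
#'   channel matrices).
#' @param duration window duration, seconds.
#' @param t_idx evaluation sample indices.
#' @param lags integer lags in samples.
#' @param rate sampling rate, Hz.
#' @return array time x lag x k-channels x l-channels.
#' @export
windowed_pair_correlation <- function(r_km, r_ln, duration, t_idx, lags,
                                      rate = 2000) {
  windowed_corr_engine(as.matrix(r_km), as.matrix(r_ln),
                       rect_window(duration, rate), t_idx, lags)
}

psth <- function(raster) apply(unclass(raster), c(1, 2), mean)

# shared computation of PSTH/same-trial correlograms and windowed variances
neural_phi_parts <- function(raster, duration, t_idx, lags) {
  rate <- raster_rate(raster)
  R <- center_raster(raster)
  N <- dim(R)[3]
  w2 <- rect_window(duration, rate)
  P <- apply(R, c(1, 2), mean)
  Phi_psth <- windowed_corr_engine(P, P, w2, t_idx, lags)
  Phi_mm <- 0; sig_k <- 0; sig_l <- 0
  for (m in seq_len(N)) {
    Rm <- R[, , m]
    Phi_mm <- Phi_mm + windowed_corr_engine(Rm, Rm, w2, t_idx, lags)
    sig_k <- sig_k + windowed_power_engine(Rm, w2, t_idx, 0L)[, 1, ,
                                                             drop = FALSE]
    sig_l <- sig_l + windowed_power_engine(Rm, w2, t_idx, lags)
  }
  list(N = N, Phi_psth = Phi_psth, Phi_mm = Phi_mm,
       sig_k = array(sig_k / N, dim(sig_k)[c(1, 3)]),
       sig_l = sig_l / N)
}

norm_by_power <- function(Phi, sig_k, sig_l) {
  out <- Phi
  for (ti in seq_len(dim(Phi)[1])) {
    for (li in seq_len(dim(Phi)[2])) {
      den <- sqrt(outer(sig_k[ti, ], sig_l[ti, li, ]))
      x <- Phi[ti, li, , ] / den
      x[!is.finite(x)] <- NA
      out[ti, li, , ] <- x
    }
  }
  out
}

#' Ensemble correlation estimate (stimulus-driven, noise, total)
#'
#' Computes the trial-shuffled (stimulus-driven) correlogram with the fast
#' PSTH-based algorithm
#' `Phi_stim = (N^2 Phi_PSTH - sum_m phi_mm) / (N (N - 1))`
#' (N + 1 windowed correlations per channel pair instead of N(N-1)), the
#' unshuffled correlogram `mean_m phi_mm`, and the noise correlogram as
#' their difference. All three are normalized by the trial-averaged windowed
#' response power `sigma_k^2(t)`, `sigma_l^2(t, tau)` so that the total
#' correlation satisfies `c_total = c_stim + c_noise` entrywise and equals 1
#' on the zero-lag diagonal wherever there is power.
#'
#' @param raster an [ensemble_raster()] (time x channel x trial, >= 2
#'   trials).
#' @param duration rectangular window duration, seconds.
#' @param lags integer lags in samples (default +/- 100 ms).
#' @param t_idx evaluation sample indices (default: uniform grid excluding
#'   half-window + lag margins, stepped by one window).
#' @param t_step grid step in seconds when `t_idx` is NULL.
#' @return object of class `correlation_estimate` with raw `Phi_*` and
#'   normalized `c_stim`, `c_noise`, `c_total` arrays (time x lag x k x l),
#'   `lags` (seconds), `times` (seconds).
#' @export
ensemble_correlation <- function(raster, duration, lags = NULL, t_idx = NULL,
                                 t_step = duration) {
  rate <- raster_rate(raster)
  N <- dim(raster)[3]
  if (N < 2) stop("shuffled estimator undefined for fewer than 2 trials")
  if (is.null(lags)) lags <- neural_lags(rate)
  w2 <- rect_window(duration, rate)
  if (is.null(t_idx))
    t_idx <- default_time_grid(dim(raster)[1], (length(w2) - 1) / 2,
                               max(abs(lags)), round(t_step * rate))
  p <- neural_phi_parts(raster, duration, t_idx, lags)
  Phi_stim <- (p$N^2 * p$Phi_psth - p$Phi_mm) / (p$N * (p$N - 1))
  Phi_unshuffled <- p$Phi_mm / p$N
  Phi_noise <- Phi_unshuffled - Phi_stim
  structure(list(
    Phi_stim = Phi_stim, Phi_unshuffled = Phi_unshuffled,
    Phi_noise = Phi_noise,
    c_stim = norm_by_power(Phi_stim, p$sig_k, p$sig_l),
    c_noise = norm_by_power(Phi_noise, p$sig_k, p$sig_l),
    c_total = norm_by_power(Phi_unshuffled, p$sig_k, p$sig_l),
    sig_k = p$sig_k, sig_l = p$sig_l,
    lags = lags / rate, times = (t_idx - 1) / rate, duration = duration,
    n_trials = p$N), class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  d <- dim(x$c_stim)
  cat("Ensemble correlation estimate:", d[3], "x", d[4], "channels,",
      d[2], "lags,", d[1], "time points,", x$n_trials, "trials\n")
  cat(sprintf("  window %g ms, lags %g..%g ms\n", 1000 * x$duration,
              1000 * min(x$lags), 1000 * max(x$lags)))
  invisible(x)
}

#' Trial-shuffled (stimulus-driven) correlogram
#'
#' Fast PSTH-based implementation; see [ensemble_correlation()] for the
#' full normalized decomposition.
#'
#' @inheritParams ensemble_correlation
#' @return raw correlogram array time x lag x k x l.
#' @export
shuffled_correlation <- function(raster, duration, lags = NULL,
                                 t_idx = NULL, t_step = duration) {
  ensemble_correlation(raster, duration, lags, t_idx, t_step)$Phi_stim
}

#' Unshuffled (same-trial) correlogram
#'
#' Mean over trials of the same-trial windowed correlograms; defined for a
#' single trial as that trial's windowed correlation.
#'
#' @inheritParams ensemble_correlation
#' @export
unshuffled_correlation <- function(raster, duration, lags = NULL,
                                   t_idx = NULL, t_step = duration) {
  rate <- raster_rate(raster)
  if (is.null(lags)) lags <- neural_lags(rate)
  w2 <- rect_window(duration, rate)
  if (is.null(t_idx))
    t_idx <- default_time_grid(dim(raster)[1], (length(w2) - 1) / 2,
                               max(abs(lags)), round(t_step * rate))
  R <- center_raster(raster)
  N <- dim(R)[3]
  Phi <- 0
  for (m in seq_len(N))
    Phi <- Phi + windowed_corr_engine(R[, , m], R[, , m], w2, t_idx, lags)
  Phi / N
}

#' Noise correlogram by subtraction
#'
#' @param Phi_unshuffled,Phi_stim matched correlogram arrays.
#' @export
noise_correlation <- function(Phi_unshuffled, Phi_stim) {
  if (!all(dim(Phi_unshuffled) == dim(Phi_stim)))
    stop("correlogram shapes do not match")
  Phi_unshuffled - Phi_stim
}

#' Normalize a correlogram as a correlation coefficient
#'
#' Divides by the square root of the product of the trial-averaged windowed
#' response powers `sigma_k^2(t)` and `sigma_l^2(t, tau)` computed from the
#' (globally mean-removed) raster. Zero-power points are returned as NA.
#'
#' @param Phi correlogram array time x lag x k x l.
#' @param raster the [ensemble_raster()] the correlogram came from.
#' @param duration window duration, seconds.
#' @param t_idx,lags the evaluation grid used for `Phi`.
#' @export
normalize_correlation <- function(Phi, raster, duration, t_idx, lags) {
  rate <- raster_rate(raster)
  R <- center_raster(raster)
  w2 <- rect_window(duration, rate)
  N <- dim(R)[3]
  sig_k <- 0; sig_l <- 0
  for (m in seq_len(N)) {
    sig_k <- sig_k + windowed_power_engine(R[, , m], w2, t_idx, 0L)[, 1, ,
                                                                    drop = FALSE]
    sig_l <- sig_l + windowed_power_engine(R[, , m], w2, t_idx, lags)
  }
  sig_k <- array(sig_k / N, dim(sig_k)[c(1, 3)])
  sig_l <- sig_l / N
  if (all(sig_k == 0)) stop("zero response variance everywhere")
  norm_by_power(Phi, sig_k, sig_l)
}

#' Normalized single-trial correlogram
#'
#' Windowed correlation of one trial with itself, normalized by that trial's
#' windowed powers (signal + noise mixture; bounded in [-1, 1]). These are
#' the features of the single-trial classifier.
#'
#' @inheritParams ensemble_correlation
#' @param trial trial index.
#' @export
single_trial_correlation <- function(raster, trial, duration, lags = NULL,
                                     t_idx = NULL, t_step = duration) {
  rate <- raster_rate(raster)
  if (is.null(lags)) lags <- neural_lags(rate)
  w2 <- rect_window(duration, rate)
  if (is.null(t_idx))
    t_idx <- default_time_grid(dim(raster)[1], (length(w2) - 1) / 2,
                               max(abs(lags)), round(t_step * rate))
  Rm <- center_raster(raster)[, , trial]
  Phi <- windowed_corr_engine(Rm, Rm, w2, t_idx, lags)
  sig_k <- array(windowed_power_engine(Rm, w2, t_idx, 0L)[, 1, ,
                                                          drop = FALSE],
                 c(length(t_idx), ncol(Rm)))
  sig_l <- windowed_power_engine(Rm, w2, t_idx, lags)
  norm_by_power(Phi, sig_k, sig_l)
}

#' Collapse correlation structure across its principal dimension
#'
#' `mode = "spectral"`: average a channel x channel matrix along its
#' diagonals into a channel-offset profile (offset 0 .. L-1).
#' `mode = "temporal"`: average a lag x channel matrix of same-channel
#' correlations across channels into a lag profile. Enables averaging across
#' ensembles with mismatched frequency ranges.
#'
#' @param x matrix (see above) or [ensemble_correlation()] slice.
#' @param mode `"spectral"` or `"temporal"`.
#' @return named numeric profile.
#' @export
collapse_correlations <- function(x, mode = c("spectral", "temporal")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "spectral") {
    if (nrow(x) != ncol(x)) stop("spectral collapse needs a square matrix")
    L <- nrow(x)
    off <- abs(row(x) - col(x))
    prof <- vapply(0:(L - 1), function(d) mean(x[off == d]), numeric(1))
    names(prof) <- 0:(L - 1)
    prof
  } else {
    rowMeans(x)
  }
}
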