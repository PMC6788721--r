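# Internal helpers: seeded RNG scoping, FIR design/filtering, analytic signal,
# windowed correlation engine shared by the sound and neural estimators.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded generators leave the
#' caller's RNG stream untouched (no global state).
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

vec_norm <- function(x) sqrt(sum(x^2))

#' Geometric half-octave ladder
#'
#' @param from,to range endpoints (inclusive; `to` is the largest value not
#'   exceeded).
#' @return numeric vector `from * 2^(0, 0.5, 1, ...)` truncated at `to`.
#' @noRd
half_octave_ladder <- function(from, to) {
  n <- floor(2 * log2(to / from) + 1e-9)
  from * 2^(seq(0, n) / 2)
}

#' Analytic signal via FFT
#'
#' Returns `x + i*H{x}` computed by zeroing negative frequencies.
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Linear-phase FIR design meeting a cutoff/transition/attenuation contract
#'
#' Kaiser-window design. `band` is c(lo, hi) in Hz; use lo = 0 for low-pass.
#' Transition width and stop-band attenuation are honoured via
#' `signal::kaiserord`. Returns odd-length coefficients (integer group delay).
#' @noRd
design_fir <- function(fs, band, transition, atten_db = 60) {
  stopifnot(band[2] < fs / 2, transition > 0)
  dev <- 10^(-atten_db / 20)
  if (band[1] <= 0) {
    f <- c(band[2], band[2] + transition)
    ord <- signal::kaiserord(f, c(1, 0), c(dev, dev), fs)
    n <- ord$n + (ord$n %% 2 == 1)  # force even order -> odd length
    h <- signal::fir1(n, (band[2] + transition / 2) / (fs / 2), type = "low",
                      window = signal::kaiser(n + 1, ord$beta))
  } else {
    f <- c(band[1] - transition, band[1], band[2], band[2] + transition)
    stopifnot(f[1] > 0, f[4] < fs / 2)
    ord <- signal::kaiserord(f, c(0, 1, 0), c(dev, dev, dev), fs)
    n <- ord$n + (ord$n %% 2 == 1)
    w <- c(band[1] - transition / 2, band[2] + transition / 2) / (fs / 2)
    h <- signal::fir1(n, w, type = "pass",
                      window = signal::kaiser(n + 1, ord$beta))
  }
  as.numeric(h)
}

#' Apply an odd-length linear-phase FIR with group-delay compensation
#'
#' Output has the same length and alignment as the input (edges zero-padded).
#' @noRd
filter_delay_comp <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  d <- (length(h) - 1) / 2
  y <- signal::fftfilt(h, c(x, numeric(2 * d)))
  y[(d + 1):(d + length(x))]
}

#' Windowed cross-correlation engine
#'
#' Computes Phi[t, tau, k, l] = sum_i w2[i] * X[t+i-h-1, k] * Y[t+i-h-1-tau, l]
#' for a symmetric window weight vector `w2` of odd length, evaluation times
#' `t_idx` (sample indices into the rows of X/Y) and integer lags `lags`
#' (samples). Errors if any window+lag support falls outside the record.
#'
#' @param X,Y time x channel matrices (same number of rows).
#' @param w2 squared-window weights, odd length.
#' @param t_idx integer sample indices.
#' @param lags integer lags in samples.
#' @return array [time, lag, k, l].
#' @noRd
windowed_corr_engine <- function(X, Y = X, w2, t_idx, lags) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nt <- nrow(X)
  stopifnot(nrow(Y) == nt, length(w2) %% 2 == 1)
  h <- (length(w2) - 1) / 2
  lo <- min(t_idx) - h - max(lags); hi <- max(t_idx) + h - min(lags)
  if (min(t_idx) - h < 1 || max(t_idx) + h > nt || lo < 1 || hi > nt)
    stop("evaluation time too near the record edges for this window/lag range")
  out <- array(0, dim = c(length(t_idx), length(lags), ncol(X), ncol(Y)))
  for (ti in seq_along(t_idx)) {
    rows <- (t_idx[ti] - h):(t_idx[ti] + h)
    U <- X[rows, , drop = FALSE] * w2
    for (li in seq_along(lags)) {
      V <- Y[rows - lags[li], , drop = FALSE]
      out[ti, li, , ] <- crossprod(U, V)
    }
  }
  out
}

#' Windowed power (second moment) per channel, with lag shift
#'
#' sigma2[t, tau, l] = sum_i w2[i] * Y[t+i-h-1-tau, l]^2
#' @noRd
windowed_power_engine <- function(Y, w2, t_idx, lags) {
  Y <- as.matrix(Y)
  h <- (length(w2) - 1) / 2
  out <- array(0, dim = c(length(t_idx), length(lags), ncol(Y)))
  for (ti in seq_along(t_idx)) {
    rows <- (t_idx[ti] - h):(t_idx[ti] + h)
    for (li in seq_along(lags)) {
      V <- Y[rows - lags[li], , drop = FALSE]
      out[ti, li, ] <- crossprod(w2, V^2)
    }
  }
  out
}

#' Default evaluation-time grid excluding half-window + max-lag margins
#' @noRd
default_time_grid <- function(n_time, half_win, max_lag, step) {
  lo <- half_win + max_lag + 1
  hi <- n_time - half_win - max_lag
  if (hi < lo) stop("record shorter than window + lag support")
  seq(lo, hi, by = max(1L, as.integer(step)))
}
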