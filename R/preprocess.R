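# aMUA envelope extraction from raw voltage traces and 1/f spectrum
# equalization of sounds.

#' Extract analog multiunit activity (aMUA) envelopes
#'
#' Band-passes the raw extracellular voltage to the action-potential band
#' (325-3000 Hz; linear phase, 125 Hz transitions, 60 dB stop band),
#' full-wave rectifies, low-pass filters at 475 Hz (125 Hz transition,
#' 60 dB) and resamples to 2 kHz. All filters are delay-compensated.
#'
#' @param trace voltage samples (vector, or time x channel matrix).
#' @param fs acquisition rate, Hz (>= 6 kHz and an integer multiple of
#'   2000).
#' @return envelope at 2 kHz (same shape class as the input).
#' @export
extract_amua <- function(trace, fs) {
  if (fs < 6000) stop("fs must be at least 6 kHz")
  if (fs %% 2000 != 0) stop("fs must be an integer multiple of 2000")
  one <- function(x) {
    bp <- design_fir(fs, c(325, 3000), transition = 125, atten_db = 60)
    y <- abs(filter_delay_comp(x, bp))
    lp <- design_fir(fs, c(0, 475), transition = 125, atten_db = 60)
    y <- filter_delay_comp(y, lp)
    y[seq(1, length(y), by = fs / 2000)]
  }
  if (is.matrix(trace)) apply(trace, 2, one) else one(as.numeric(trace))
}

#' Welch average periodogram
#'
#' Magnitude spectrum estimated by averaging windowed periodograms
#' (50% overlap) with a Kaiser window whose side lobes are at least
#' `sidelobe_db` down; segment length set by the frequency resolution.
#'
#' @param sound numeric waveform.
#' @param fs sampling rate, Hz.
#' @param resolution frequency resolution (bin spacing), Hz.
#' @param sidelobe_db window side-lobe suppression, dB.
#' @return list with `freq` (Hz), `power` (one-sided PSD) and `magnitude`
#'   (= sqrt(power)).
#' @export
welch_spectrum <- function(sound, fs, resolution = 10, sidelobe_db = 40) {
  n <- round(fs / resolution)
  if (length(sound) < 3 * n)
    stop("input too short for the requested frequency resolution")
  A <- sidelobe_db
  beta <- if (A > 50) 0.1102 * (A - 8.7)
  else 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  w <- as.numeric(signal::kaiser(n, beta))
  starts <- seq(1, length(sound) - n + 1, by = max(1, floor(n / 2)))
  acc <- numeric(n)
  for (s in starts) {
    seg <- sound[s:(s + n - 1)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / length(starts) / (fs * sum(w^2))
  half <- seq_len(floor(n / 2) + 1)
  psd <- psd[half]
  psd[-c(1, length(half))] <- 2 * psd[-c(1, length(half))]
  list(freq = (half - 1) * fs / n, power = psd, magnitude = sqrt(psd))
}

#' Equalize a sound to a 1/f power spectrum
#'
#' Builds a zero-phase inversion filter whose amplitude response is
#' `C * S(f)^-1 * f^(-1/2)` (with `S(f)` the Welch magnitude spectrum of
#' the input), so the output's power spectral density follows 1/f — equal
#' power per octave, which activates a tonotopic axis uniformly. The gain
#' `C` is set so the output RMS equals the input RMS. The equalized band is
#' `[50 Hz, 0.45 fs]` with half-octave cosine roll-offs outside; spectral
#' bins below `max(S)/1e5` are floored (with a warning) before inversion.
#'
#' @param sound numeric waveform.
#' @param fs sampling rate, Hz.
#' @param band equalized frequency band, Hz.
#' @return equalized waveform with the input's RMS.
#' @export
equalize_spectrum_1f <- function(sound, fs, band = c(50, 0.45 * fs)) {
  n <- length(sound)
  ws <- welch_spectrum(sound, fs, resolution = 10)
  S <- ws$magnitude
  floor_v <- max(S) / 1e5
  if (any(S[ws$freq >= band[1] & ws$freq <= band[2]] < floor_v))
    warning("zero/near-zero spectral bins inside the band; floored")
  S <- pmax(S, floor_v)
  f <- (0:(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]          # fold to two-sided magnitudes
  Sg <- stats::approx(ws$freq, S, xout = pmin(f, max(ws$freq)), rule = 2)$y
  H <- numeric(n)
  pos <- f > 0
  H[pos] <- f[pos]^(-0.5) / Sg[pos]
  # half-octave cosine roll-offs outside the band
  ramp <- function(x, lo, hi) {
    y <- (log2(pmax(x, 1e-12)) - log2(lo)) / (log2(hi) - log2(lo))
    0.5 - 0.5 * cos(pi * pmin(pmax(y, 0), 1))
  }
  g <- ramp(f, band[1] / sqrt(2), band[1]) *
    (1 - ramp(f, band[2], min(band[2] * sqrt(2), fs / 2)))
  H <- H * g
  y <- Re(stats::fft(stats::fft(sound) * H, inverse = TRUE)) / n
  r_in <- sqrt(mean(sound^2)); r_out <- sqrt(mean(y^2))
  if (r_out > 0) y <- y * r_in / r_out
  y
}
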