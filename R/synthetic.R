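# Synthetic sounds, envelope ensembles and multi-trial neural rasters with
# known correlation structure. Latent Gaussian processes with exact temporal
# kernels (AR recursions), cross-channel mixing by a symmetric square root of
# the target correlation matrix, and a log-normal (exponential) nonnegativity
# transform, so every downstream estimator can be checked against analytic or
# Monte-Carlo oracles.

#' Temporal kernel constructors
#'
#' Autocorrelation kernels for the latent Gaussian processes behind synthetic
#' envelopes. `kernel_exponential` decays as exp(-lag/tau); `kernel_periodic`
#' is a damped cosine exp(-lag/tau) * cos(2*pi*lag/period), emulating
#' periodic modulations (e.g. a ~20 Hz rattle corresponds to period = 0.05).
#'
#' @param tau decay time constant in seconds.
#' @param period oscillation period in seconds.
#' @return a kernel description used by [texture_spec()].
#' @export
kernel_exponential <- function(tau) {
  stopifnot(tau > 0)
  structure(list(kind = "exponential", tau = tau), class = "corr_kernel")
}

#' @rdname kernel_exponential
#' @export
kernel_periodic <- function(period, tau = 4 * period) {
  stopifnot(period > 0, tau > 0)
  structure(list(kind = "periodic", period = period, tau = tau),
            class = "corr_kernel")
}

#' Specification of a synthetic correlated texture
#'
#' Describes a frequency-organized envelope ensemble: number of channels,
#' duration, target cross-channel (spectral) correlation matrix of the latent
#' Gaussian processes, temporal kernel, and optionally a deterministic
#' regime-switching schedule emulating nonstationary (speech-like) dynamics.
#'
#' @param n_channels number of envelope channels.
#' @param duration record duration in seconds.
#' @param envelope_rate sampling rate of the envelopes in Hz.
#' @param target_spectral_corr channel x channel latent correlation matrix;
#'   must be symmetric with unit diagonal and positive semidefinite.
#' @param temporal_kernel a [kernel_exponential()] / [kernel_periodic()]
#'   kernel shared by all channels.
#' @param regime either `"stationary"` or the result of
#'   [regime_switching()].
#' @param seed integer seed; all randomness in the generators flows from
#'   explicit seeds (no global state).
#' @return an object of class `texture_spec`.
#' @export
texture_spec <- function(n_channels, duration, envelope_rate = 1000,
                         target_spectral_corr = diag(n_channels),
                         temporal_kernel = kernel_exponential(0.01),
                         regime = "stationary", seed = 1L) {
  stopifnot(duration > 0, envelope_rate > 0, n_channels >= 1)
  C <- as.matrix(target_spectral_corr)
  stopifnot(nrow(C) == n_channels, ncol(C) == n_channels)
  if (max(abs(C - t(C))) > 1e-10) stop("target_spectral_corr must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-10)
    stop("target_spectral_corr must have unit diagonal")
  structure(list(n_channels = n_channels, duration = duration,
                 envelope_rate = envelope_rate, target_spectral_corr = C,
                 temporal_kernel = temporal_kernel, regime = regime,
                 seed = as.integer(seed)),
            class = "texture_spec")
}

#' Deterministic regime-switching schedule
#'
#' Regimes alternate deterministically every `switch_period` seconds, giving
#' reproducible nonstationarity. Each regime is a list that may override
#' `temporal_kernel` and/or `target_spectral_corr`.
#'
#' @param switch_period seconds per regime segment.
#' @param regimes list of regime overrides, cycled in order.
#' @export
regime_switching <- function(switch_period, regimes) {
  stopifnot(switch_period > 0, length(regimes) >= 2)
  structure(list(kind = "switching", switch_period = switch_period,
                 regimes = regimes), class = "corr_regime")
}

#' Neural-noise specification
#'
#' Trial-to-trial variability added to a stimulus-locked signal: spatially
#' correlated only within `spatial_reach` neighboring channels (correlation
#' `spatial_rho` at offset 1, tapering linearly to 0 beyond the reach) and
#' temporally correlated over a brief window (`temporal_width` = full width
#' at half maximum of the noise autocorrelation, Gaussian shaped).
#'
#' @param noise_gain noise standard deviation relative to the per-channel
#'   signal standard deviation.
#' @param spatial_reach number of neighboring channels sharing noise.
#' @param temporal_width FWHM of the noise autocorrelation, seconds.
#' @param spatial_rho noise correlation at channel offset 1.
#' @param seed integer seed.
#' @export
noise_spec <- function(noise_gain = 0.5, spatial_reach = 1,
                       temporal_width = 0.003, spatial_rho = 0.5, seed = 1L) {
  stopifnot(spatial_reach >= 0, temporal_width >= 0, noise_gain >= 0,
            spatial_rho >= 0, spatial_rho < 1)
  structure(list(noise_gain = noise_gain, spatial_reach = spatial_reach,
                 temporal_width = temporal_width, spatial_rho = spatial_rho,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# exact-ACF latent Gaussian process, unit variance, one channel per column
latent_gp <- function(n, n_channels, kernel, dt) {
  if (kernel$kind == "exponential") {
    phi <- exp(-dt / kernel$tau)
    Z <- matrix(stats::rnorm(n * n_channels), n, n_channels)
    if (n > 1) {
      s <- sqrt(1 - phi^2)
      for (t in 2:n) Z[t, ] <- phi * Z[t - 1, ] + s * Z[t, ]
    }
    Z
  } else if (kernel$kind == "periodic") {
    # complex AR(1): Re part has acf r^k cos(theta k)
    r <- exp(-dt / kernel$tau)
    theta <- 2 * pi * dt / kernel$period
    a <- complex(modulus = r, argument = theta)
    s <- sqrt(1 - r^2) / sqrt(2)
    E <- matrix(complex(real = stats::rnorm(n * n_channels),
                        imaginary = stats::rnorm(n * n_channels)),
                n, n_channels) * s
    U <- E
    U[1, ] <- E[1, ] / sqrt(1 - r^2)  # stationary start, E|u|^2 = 1
    if (n > 1) for (t in 2:n) U[t, ] <- a * U[t - 1, ] + E[t, ]
    sqrt(2) * Re(U)
  } else stop("unknown temporal kernel: ", kernel$kind)
}

# symmetric PSD square root; errors on clearly non-PSD input
psd_sqrt <- function(C, tol = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values)))
    stop("target correlation matrix is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(e$values)), ")")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate correlated log-normal envelopes
#'
#' Draws latent Gaussian processes with the requested temporal kernel, mixes
#' them across channels through a square root of the target spectral
#' correlation matrix, and maps through an exponential nonnegativity
#' transform (log-normal envelopes). The achieved envelope correlation for a
#' latent correlation rho is (exp(rho)-1)/(exp(1)-1); the achieved matrix is
#' attached as attribute `achieved_corr`.
#'
#' @param spec a [texture_spec()].
#' @return a [cochleogram] whose `envelopes` are the generated channels, with
#'   attributes `achieved_corr` (analytic envelope-correlation target) and
#'   `latent_corr`.
#' @export
gen_correlated_envelopes <- function(spec) {
  stopifnot(inherits(spec, "texture_spec"))
  dt <- 1 / spec$envelope_rate
  n <- round(spec$duration * spec$envelope_rate)
  segs <- resolve_regimes(spec)
  Z <- with_seed(spec$seed, {
    do.call(rbind, lapply(segs, function(sg) {
      latent_gp(sg$n, spec$n_channels, sg$kernel, dt) %*% psd_sqrt(sg$corr)
    }))
  })
  Z <- Z[seq_len(n), , drop = FALSE]
  env <- exp(Z)
  achieved <- (exp(spec$target_spectral_corr) - 1) / (exp(1) - 1)
  coch <- cochleogram(env, envelope_rate = spec$envelope_rate,
                      channel_freqs = 100 * 2^(seq_len(spec$n_channels) / 2))
  attr(coch, "achieved_corr") <- achieved
  attr(coch, "latent_corr") <- spec$target_spectral_corr
  coch
}

# expand a texture_spec regime schedule into per-segment lengths/kernels
resolve_regimes <- function(spec) {
  n <- round(spec$duration * spec$envelope_rate)
  if (!inherits(spec$regime, "corr_regime"))
    return(list(list(n = n, kernel = spec$temporal_kernel,
                     corr = spec$target_spectral_corr)))
  per <- round(spec$regime$switch_period * spec$envelope_rate)
  k <- length(spec$regime$regimes)
  segs <- list()
  done <- 0; i <- 0
  while (done < n) {
    rg <- spec$regime$regimes[[i %% k + 1]]
    segs[[length(segs) + 1]] <- list(
      n = min(per, n - done),
      kernel = rg$temporal_kernel %||% spec$temporal_kernel,
      corr = rg$target_spectral_corr %||% spec$target_spectral_corr)
    done <- done + per; i <- i + 1
  }
  segs
}

#' Synthesize a waveform from envelope channels
#'
#' Each envelope channel modulates an independent narrowband noise carrier
#' centered at the corresponding filter frequency (carriers are white noise
#' passed through the bank's gammatone filters); channels are summed and the
#' waveform RMS-normalized. Provides audio input for the cochlear front-end.
#'
#' @param envelopes a [cochleogram] or time x channel matrix of envelopes.
#' @param bank a [design_filterbank()] gammatone bank with as many channels
#'   as the envelope matrix.
#' @param fs output sampling rate, Hz; must exceed twice the highest center
#'   frequency.
#' @param envelope_rate envelope sampling rate (taken from a cochleogram
#'   input automatically).
#' @param seed integer seed for the noise carriers.
#' @return numeric waveform of length `nrow(envelopes) * fs / envelope_rate`.
#' @export
gen_waveform_from_envelopes <- function(envelopes, bank, fs,
                                        envelope_rate = NULL, seed = 1L) {
  if (inherits(envelopes, "cochleogram")) {
    envelope_rate <- envelopes$envelope_rate
    envelopes <- envelopes$envelopes
  }
  stopifnot(!is.null(envelope_rate))
  L <- ncol(envelopes)
  if (L != length(bank$center_freqs))
    stop("envelope channel count must equal the filter-bank size")
  if (fs < 2 * max(bank$center_freqs))
    stop("fs below Nyquist of the highest carrier frequency (aliasing)")
  n_out <- round(nrow(envelopes) * fs / envelope_rate)
  t_env <- (seq_len(nrow(envelopes)) - 1) / envelope_rate
  t_out <- (seq_len(n_out) - 1) / fs
  x <- numeric(n_out)
  with_seed(seed, {
    for (k in seq_len(L)) {
      h <- gammatone_impulse_response(bank$center_freqs[k],
                                      bank$bandwidths[k], bank$order,
                                      bank$phase, fs)
      carrier <- signal::fftfilt(as.numeric(h), stats::rnorm(n_out))
      sdc <- stats::sd(carrier)
      if (sdc > 0) carrier <- carrier / sdc
      ek <- stats::approx(t_env, envelopes[, k], xout = t_out, rule = 2)$y
      x <- x + carrier * ek
    }
  })
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r * 0.05
  x
}

#' Generate a multi-trial neural ensemble raster
#'
#' Builds `r[k,m](t) = signal_k(t) + eps[k,m](t)` with noise independent
#' across trials, spatially correlated only within `spatial_reach` channels
#' and temporally correlated over `temporal_width`. The true signal, true
#' spatial noise correlation matrix and true noise autocorrelation are kept
#' in a `truth` attribute for oracle tests.
#'
#' @param signal_envelopes [cochleogram] or time x channel matrix of
#'   stimulus-locked envelopes (signal component, identical on every trial).
#' @param n_trials number of trials (>= 2; the shuffled estimator is
#'   undefined for a single trial).
#' @param noise a [noise_spec()].
#' @param rate sampling rate in Hz (taken from a cochleogram input).
#' @return an `ensemble_raster`: array time x channel x trial with
#'   attributes `rate` and `truth`.
#' @export
gen_ensemble_raster <- function(signal_envelopes, n_trials,
                                noise = noise_spec(), rate = 2000) {
  if (inherits(signal_envelopes, "cochleogram")) {
    rate <- signal_envelopes$envelope_rate
    signal_envelopes <- signal_envelopes$envelopes
  }
  if (n_trials < 2) stop("n_trials must be >= 2 (shuffled estimator undefined)")
  S <- as.matrix(signal_envelopes)
  n <- nrow(S); L <- ncol(S)
  ref <- apply(S, 2, stats::sd)
  if (all(ref == 0)) ref[] <- 1 else ref[ref == 0] <- mean(ref[ref > 0])
  sdn <- noise$noise_gain * ref

  # banded spatial correlation: rho at offset 1, linear taper to 0 past reach
  Cn <- diag(L)
  if (noise$spatial_reach >= 1 && noise$spatial_rho > 0) {
    for (d in seq_len(min(noise$spatial_reach, L - 1))) {
      v <- noise$spatial_rho * (1 - (d - 1) / noise$spatial_reach)
      Cn[row(Cn) == col(Cn) + d] <- v
      Cn[col(Cn) == row(Cn) + d] <- v
    }
  }
  Sq <- psd_sqrt(Cn)
  C_true <- Sq %*% t(Sq)

  # Gaussian temporal smoothing: FWHM of g*g equals temporal_width
  sig_acf <- noise$temporal_width / (2 * sqrt(2 * log(2)))  # SD of target ACF
  sig_g <- sig_acf / sqrt(2) * rate                          # samples
  g <- if (sig_g > 0.25) {
    gg <- stats::dnorm(seq(-ceiling(5 * sig_g), ceiling(5 * sig_g)), sd = sig_g)
    gg / sqrt(sum(gg^2))
  } else 1

  R <- array(0, dim = c(n, L, n_trials))
  with_seed(noise$seed, {
    for (m in seq_len(n_trials)) {
      E <- matrix(stats::rnorm(n * L), n, L)
      if (length(g) > 1) E <- apply(E, 2, filter_delay_comp, h = g)
      E <- E %*% Sq
      R[, , m] <- S + E * rep(sdn, each = n)
    }
  })
  lag_s <- seq(0, length.out = max(2, ceiling(8 * sig_acf * rate) + 1))
  truth <- list(signal = S, spatial_corr = C_true,
                noise_sd = sdn,
                acf_lags = lag_s / rate,
                acf = if (sig_acf > 0) exp(-(lag_s / rate)^2 /
                                             (2 * sig_acf^2)) else
                  c(1, numeric(length(lag_s) - 1)))
  structure(R, rate = rate, truth = truth, class = "ensemble_raster")
}

#' @export
print.ensemble_raster <- function(x, ...) {
  d <- dim(x)
  cat("Ensemble raster:", d[2], "channels x", d[3], "trials x", d[1],
      "samples @", attr(x, "rate"), "Hz\n")
  invisible(x)
}

#' Generate a labeled synthetic category dataset
#'
#' Builds categories that contrast in spectral-correlation extent and
#' temporal-kernel timescale, emulating fire-like (broad spectral
#' correlations, fast), water-like (near-diagonal, very fast) and
#' speech-like (broad, slow, regime-switching) textures. Exemplars within a
#' category share a base [texture_spec()] perturbed by `within_jitter`
#' (log-normal jitter on time constants and correlation extent).
#'
#' @param n_categories number of categories (archetypes cycled if > 3).
#' @param n_exemplars exemplars per category (>= 2).
#' @param within_jitter relative spread of exemplar parameters (0 = all
#'   exemplars statistically identical).
#' @param seed integer master seed; exemplar seeds are derived from it.
#' @param duration,n_channels,envelope_rate passed to each [texture_spec()].
#' @return list with `specs` (list of texture_spec), `labels` (integer
#'   category per exemplar), `category_names`, and `envelopes` (list of
#'   cochleograms) when `generate = TRUE`.
#' @export
gen_category_dataset <- function(n_categories = 3, n_exemplars = 6,
                                 within_jitter = 0.1, seed = 1L,
                                 duration = 12, n_channels = 8,
                                 envelope_rate = 1000, generate = TRUE) {
  if (n_exemplars < 2) stop("need at least 2 exemplars per category")
  base_corr <- function(rho, L) {
    C <- rho^abs(outer(seq_len(L), seq_len(L), "-")); diag(C) <- 1; C
  }
  archetypes <- list(
    fire   = list(rho = 0.7,  tau = 0.005, switching = FALSE),
    water  = list(rho = 0.15, tau = 0.003, switching = FALSE),
    speech = list(rho = 0.6,  tau = 0.060, switching = TRUE))
  nm <- names(archetypes)[(seq_len(n_categories) - 1) %% 3 + 1]
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1,
                                    n_categories * n_exemplars))
  specs <- list(); labels <- integer(0)
  idx <- 0
  for (ci in seq_len(n_categories)) {
    a <- archetypes[[nm[ci]]]
    for (ei in seq_len(n_exemplars)) {
      idx <- idx + 1
      js <- sub_seeds[idx]
      jit <- with_seed(js, stats::rnorm(3))
      rho <- stats::plogis(stats::qlogis(min(max(a$rho, 1e-3), 1 - 1e-3)) +
                             within_jitter * 2 * jit[1])
      tau <- a$tau * exp(within_jitter * jit[2])
      C <- base_corr(rho, n_channels)
      regime <- if (a$switching) {
        regime_switching(0.5, list(
          list(temporal_kernel = kernel_exponential(tau)),
          list(temporal_kernel = kernel_exponential(tau / 4),
               target_spectral_corr = base_corr(rho * 0.5, n_channels))))
      } else "stationary"
      specs[[idx]] <- texture_spec(
        n_channels = n_channels, duration = duration,
        envelope_rate = envelope_rate, target_spectral_corr = C,
        temporal_kernel = kernel_exponential(tau), regime = regime,
        seed = js)
      labels[idx] <- ci
    }
  }
  out <- list(specs = specs, labels = labels,
              category_names = nm[seq_len(n_categories)])
  if (generate) out$envelopes <- lapply(specs, gen_correlated_envelopes)
  out
}
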