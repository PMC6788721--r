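---
title: "Correlation codes for sound recognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation codes for sound recognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

```{r setup}
library(corrcode)
```

## Motivation

Natural sounds — fire crackling, running water, speech — drive the auditory
periphery with amplitude envelopes whose *joint* statistics carry category
information that the long-term power spectrum does not. Two working
hypotheses organize this package:

1. The **short-term correlation structure** of cochlear frequency-channel
   envelopes (correlations *between* channels, and *across time lags* within
   channels) is a compact, discriminative signature of a sound.
2. Downstream neural ensembles can represent this signature in their own
   pairwise correlations, which can be decomposed into a **stimulus-driven**
   part (reproducible across stimulus repeats) and a **noise** part
   (trial-to-trial covariability), and decoded.

The package implements the full chain: a cochlear front-end, windowed
correlation estimators for sounds and for multi-trial neural recordings,
summary indices, probabilistic decoders, and a synthetic-sound generator
with *known* correlation structure that serves as ground truth throughout.

## Cochlear front-end

`design_filterbank()` builds a bank of gammatone filters (impulse response
$t^{n-1} e^{-2\pi b t}\cos(2\pi f t)$, order $n = 3$) with center
frequencies on a 1/8-octave ladder from 100 Hz and bandwidths following the
critical-band formula $b = 25 + 75\,(1 + 1.4 F^2)^{0.69}$ ($F$ in kHz).
`compute_cochleogram()` filters a waveform through the bank, extracts each
channel's Hilbert envelope, compensates each channel's group delay (the
gamma-envelope peak at $(n-1)/(2\pi b)$), low-passes at 500 Hz and
resamples to 1 kHz:

```{r cochleogram}
fs <- 16000
bank <- design_filterbank(400, 3200, step = 1/2)
t <- seq(0, 1, by = 1/fs)[-1]
tone <- 0.1 * sin(2 * pi * bank$center_freqs[4] * t)
coch <- compute_cochleogram(tone, fs, bank)
coch
round(colMeans(coch$envelopes), 4)   # energy concentrates in channel 4
```

## Short-term spectro-temporal correlation

For channel envelopes $S_k(t)$, the running correlogram is

$$\Phi_{kl}(t, \tau) = \sum_\gamma S_k(\gamma)\, S_l(\gamma - \tau)\,
W^2(t - \gamma),$$

with $W^2$ a Kaiser window ($\beta = 3.4$) whose length is solved so that
twice the standard deviation of $W^2$ (treated as a density) equals the
nominal resolution $\tau_W$. Normalizing by the windowed second moments of
each channel (the $\tau$-shifted moment for channel $l$) yields a
correlation coefficient $c_{kl}(t,\tau)$ with $|c| \le 1$
(Cauchy–Schwarz) and $c_{kk}(t, 0) = 1$:

```{r stc}
C <- 0.6^abs(outer(1:6, 1:6, "-")); diag(C) <- 1
env <- gen_correlated_envelopes(
  texture_spec(6, 8, 1000, C, kernel_exponential(0.01), seed = 4))
stc <- short_term_correlation(env, window_spec(0.1))
stc
range(stc$values)
```

`decompose_correlation()` turns the 4-D array into observation-by-feature
matrices in three views: `"spectral"` (zero-lag channel-pair correlations),
`"temporal"` (same-channel lag profiles) and `"spectrotemporal"` (the full
tensor). `time_average_correlation()` reports the mean structure and the
50%/10% temporal widths per channel.

Two scalar indices summarize ensembles of such trajectories.
`stationarity_index()` is $1 - \langle\lVert c(t) - \langle c\rangle\rVert
\rangle / \lVert\langle c\rangle\rVert$ — near 1 for textures with stable
statistics (water), lower for switching sounds (speech-like).
`category_diversity_index()` applies the same normalized-deviation idea
across the members of a sound category.

## Neural ensemble correlations

For a raster $r_{km}(t)$ (channel $k$, trial $m$) the same windowed
correlation is computed with a rectangular window, after removing each
channel's global mean. Correlating *different* trials removes within-trial
noise covariance; the package uses the algebraically identical fast form

$$\Phi^{stim}_{kl} = \frac{N^2 \Phi^{PSTH}_{kl} - \sum_m \phi_{kl,mm}}
{N (N - 1)},$$

which needs $N + 1$ windowed correlations instead of $N(N-1)$. The
unshuffled (same-trial) correlogram minus the shuffled one is the noise
correlogram. All three are normalized by the trial-averaged windowed power,
so that exactly

$$c^{total}_{kl}(t,\tau) = c^{stim}_{kl}(t,\tau) + c^{noise}_{kl}(t,\tau),
\qquad c^{total}_{kk}(t, 0) = 1.$$

```{r neural}
noise <- noise_spec(noise_gain = 0.5, spatial_reach = 1, spatial_rho = 0.5,
                    seed = 9)
raster <- gen_ensemble_raster(env, n_trials = 8, noise = noise)
ce <- ensemble_correlation(raster, duration = 0.25, lags = -10:10)
ce
li0 <- which(ce$lags == 0)
# the zero-lag diagonal identity:
max(abs(ce$c_stim[, li0, 3, 3] + ce$c_noise[, li0, 3, 3] - 1))
```

`collapse_correlations()` reduces channel-pair matrices to channel-offset
profiles and lag matrices to population lag profiles, which is how
ensembles with different frequency coverage are averaged.

## Decoding

Correlation features (from `decompose_correlation()` for sounds, or
`neural_features()` for rasters, in spectral / temporal / spectrum-rate
views and shuffled / single-trial provenance) are reduced with `fit_pca()`
and classified with a MAP rule: per-class axis-aligned Gaussians
(`fit_gaussian_bayes()`) or diagonal-covariance Gaussian mixtures
(`fit_diag_gmm()`, component count by cross-validated held-out likelihood
via `select_gmm_components()`). `map_classify()` sums log-likelihoods over
windows, so evidence accumulates with stimulus duration;
`model_average_classify()` mixes spectral and temporal posteriors with a
coefficient chosen by `optimize_alpha()`. `classify_loo()` wraps the
leave-one-sound-out protocol over a half-octave ladder of durations, and
`performance_curve()` extracts the asymptote and the 90% integration rise
time $\tau_c$. `shuffle_tonotopy()` destroys channel identity while keeping
each within-channel lag profile — the control separating spatial from
temporal information.

```{r decode}
ds <- gen_category_dataset(3, 4, within_jitter = 0.1, seed = 7,
                           duration = 6, n_channels = 6)
feats <- lapply(ds$envelopes, function(coch) {
  stc <- short_term_correlation(coch, window_spec(0.1),
                                lags = seq(-10, 10, by = 5))
  decompose_correlation(stc, "spectrotemporal")
})
classify_loo(feats, ds$labels, n_windows = c(1, 4, 10), seed = 1)$accuracy
```

## Controls: spectrum classifier and 1/f equalization

`spectrum_features()` (windowed per-channel mean amplitude — a rate code)
is the baseline against which the correlation code is compared.
`equalize_spectrum_1f()` imposes the *same* $1/f$ power spectrum on every
sound (inverse filtering by the sound's own Welch spectrum,
`welch_spectrum()`, times $f^{-1/2}$ in amplitude, with band-edge rolloffs
and exact RMS preservation). After equalization the long-term spectrum
carries no information, while envelope correlation structure survives —
the key dissociation between spectral and correlation codes.

A subtlety worth knowing when building spectrum baselines on synthetic
textures: *windowed* channel-amplitude features fluctuate, and their
window-to-window covariance is itself the spectral correlation. A
per-window "spectrum" classifier can therefore decode correlation structure
even with perfectly equalized spectra. To isolate purely spectral cues,
compare whole-record averaged profiles across exemplars (as the acceptance
suite does).

## Synthetic ground truth

`texture_spec()` + `gen_correlated_envelopes()` draw log-normal envelopes
from latent Gaussian processes with exact exponential
(`kernel_exponential()`) or damped-cosine (`kernel_periodic()`)
autocorrelations and an exact latent cross-channel correlation matrix;
`regime_switching()` alternates parameter sets for nonstationary,
speech-like sounds. `gen_ensemble_raster()` adds trial-independent noise
with a banded spatial correlation (reach-limited), Gaussian temporal
autocorrelation, and per-channel variance proportional to the signal — the
injected values are kept in a `truth` attribute. `gen_category_dataset()`
produces labelled fire / water / speech-like archetype categories with
controlled within-category jitter. `gen_waveform_from_envelopes()` converts
envelopes to audio by modulating gammatone-filtered noise carriers, closing
the loop through the front-end. `run_sound_pipeline()` and
`run_neural_pipeline()` chain everything into JSON-serializable reports.

## Estimator conventions

* Envelopes are *not* mean-removed in the sound estimator (envelopes are
  nonnegative; their windowed second moment is the natural scale); neural
  rasters *are* globally mean-removed per channel and trial.
* The lag grid at resolution $\tau_W$ spans
  $\pm(\lceil \tau_W/2 \cdot \text{rate}\rceil - 1)$ samples — 99 lags at
  $\tau_W = 100$ ms and 1 kHz.
* $c_{kl}(t,\tau) = c_{lk}(t,-\tau)$ holds exactly only at $\tau = 0$: at
  nonzero lags, the window stays centered on $t$ for both orderings, so the
  samples of the lagged channel falling under the window differ slightly.
* Evaluation points whose window-plus-lag support overruns the record are
  excluded rather than zero-padded.
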