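# corrcode

Correlation codes for sound recognition: analyse the short-term
spectro-temporal correlation structure of sounds (through a gammatone
cochlear model) and of multichannel neural ensemble recordings (through
trial-shuffled correlograms that split correlations into stimulus-driven
and noise components), and decode sound identity and category from those
correlations.

## What's inside

- **Cochlear front-end** — `design_filterbank()`, `compute_cochleogram()`:
  gammatone filterbank (1/8-octave ladder, critical bandwidths), Hilbert
  envelopes, delay compensation, 1 kHz envelope sampling.
- **Sound correlations** — `short_term_correlation()` with a Kaiser window
  whose squared-window 2-SD width defines the resolution τ\_W;
  `decompose_correlation()` (spectral / temporal / spectrotemporal views),
  `time_average_correlation()`, `stationarity_index()`,
  `category_diversity_index()`.
- **Neural correlations** — `ensemble_correlation()`: fast PSTH-based
  trial-shuffled correlograms, with the exact decomposition
  `c_total = c_stim + c_noise` (and `c_total = 1` on the zero-lag
  diagonal); `single_trial_correlation()`, `collapse_correlations()`.
- **Decoders** — `fit_pca()`, `fit_gaussian_bayes()`, `fit_diag_gmm()` /
  `select_gmm_components()`, MAP classification with evidence accumulation
  over windows (`map_classify()`), spectral/temporal model averaging,
  tonotopy shuffling, `classify_loo()`, `performance_curve()`.
- **Preprocessing** — `extract_amua()` (analog multiunit activity),
  `welch_spectrum()`, `equalize_spectrum_1f()` (imposes an identical 1/f
  power spectrum on all sounds while preserving RMS), minimal WAV I/O.
- **Synthetic ground truth** — log-normal envelope textures with exact
  latent autocorrelation and cross-channel correlation
  (`texture_spec()`, `gen_correlated_envelopes()`, `regime_switching()`),
  multi-trial rasters with reach-limited correlated noise
  (`gen_ensemble_raster()`), labelled category datasets
  (`gen_category_dataset()`), and envelope-to-waveform synthesis.
- **Pipelines** — `run_sound_pipeline()`, `run_neural_pipeline()`:
  end-to-end JSON-serializable reports.

## Worked example

```r
library(corrcode)

# 1. Synthetic sound categories with known correlation structure
ds <- gen_category_dataset(3, 4, within_jitter = 0.1, seed = 7,
                           duration = 6, n_channels = 6)
ds$category_names
#> [1] "fire"   "water"  "speech"

# 2. Short-term spectro-temporal correlation of one sound
stc <- short_term_correlation(ds$envelopes[[1]], window_spec(0.1))
stc
#> Short-term correlation: 57 time points x 99 lags x 6 x 6 channels
#>   window kaiser tau_w = 100 ms, lags -49..49 ms
round(stationarity_index(stc), 3)
#> [1] 0.77

# 3. Neural ensemble: signal + correlated noise, shuffled decomposition
noise <- noise_spec(noise_gain = 0.5, spatial_reach = 1, spatial_rho = 0.5,
                    seed = 9)
raster <- gen_ensemble_raster(ds$envelopes[[1]], n_trials = 8, noise = noise)
ce <- ensemble_correlation(raster, duration = 0.25, lags = -10:10)
ce
#> Ensemble correlation estimate: 6 x 6 channels, 21 lags, 23 time points, 8 trials
#>   window 250 ms, lags -10..10 ms
li0 <- which(ce$lags == 0)
max(abs(ce$c_stim[, li0, 3, 3] + ce$c_noise[, li0, 3, 3] - 1))
#> [1] 2.220446e-16

# 4. Category decoding from spectro-temporal correlation features
feats <- lapply(ds$envelopes, function(coch) {
  s <- short_term_correlation(coch, window_spec(0.1),
                              lags = seq(-10, 10, by = 5))
  decompose_correlation(s, "spectrotemporal")
})
classify_loo(feats, ds$labels, n_windows = c(1, 4, 10), seed = 1)$accuracy
#>         1         4        10
#>  91.66667 100.00000 100.00000
```

Accuracy rises with the number of 100 ms windows the MAP rule accumulates:
at 1 s (10 windows), the three planted categories are decoded perfectly.

## Methods vignette

See `vignettes/correlation-codes.Rmd` for the estimator definitions
(windowed correlogram, normalization, the shuffled-correlation algebra),
the decoding protocols, and the estimator conventions.

## Tests

```r
testthat::test_dir("tests/testthat", package = "corrcode",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds the acceptance suite (oracle
equivalence, identity checks, chance calibration, parameter recovery,
planted-category decoding, spectrum-invariance after 1/f equalization,
equalizer checks). `scripts/acceptance.R` recomputes the two numeric
acceptance targets and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
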