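# End-to-end pipelines: synthetic data -> correlation statistics ->
# classification -> reports. Reports are plain lists of scalars, vectors and
# matrices, directly serializable to JSON/CSV.

#' Sweep PCA component counts by cross-validated training accuracy
#'
#' Picks the retained-component count maximizing k-fold cross-validated
#' naive-Bayes accuracy on the training observations.
#'
#' @param x training observation x feature matrix.
#' @param labels class per observation.
#' @param grid candidate component counts.
#' @param n_folds cross-validation folds.
#' @param seed integer seed.
#' @return best component count.
#' @export
sweep_pca_components <- function(x, labels, grid = c(2, 4, 8, 16, 32),
                                 n_folds = 3, seed = 1L) {
  x <- as.matrix(x); labels <- as.factor(labels)
  grid <- grid[grid <= nrow(x) - 1]
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), nrow(x))))
  acc <- vapply(grid, function(q) {
    ok <- 0; tot <- 0
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (any(table(labels[tr]) < 2)) next
      pca <- fit_pca(x[tr, , drop = FALSE], retain = q)
      mod <- fit_gaussian_bayes(predict(pca, x[tr, , drop = FALSE]),
                                labels[tr])
      pr <- map_classify(mod, predict(pca, x[!tr, , drop = FALSE]),
                         combine_n = 1)
      ok <- ok + sum(pr$class == as.character(labels[!tr]))
      tot <- tot + sum(!tr)
    }
    if (tot == 0) 0 else ok / tot
  }, numeric(1))
  grid[which.max(acc)]
}

sound_feature_sets <- function(envs, tau_w, mode, lag_step = 1) {
  lapply(envs, function(coch) {
    rate <- coch$envelope_rate
    w <- window_spec(tau_w)
    half <- ceiling(w$max_lag * rate) - 1
    lags <- unique(c(rev(seq(0, -half, by = -lag_step)),
                     seq(0, half, by = lag_step)))
    stc <- short_term_correlation(coch, w, lags = lags)
    decompose_correlation(stc, mode)
  })
}

#' Run the sound-analysis pipeline on synthetic categories
#'
#' Generates a labeled synthetic category dataset, computes short-term
#' correlations at each requested resolution, stationarity (SI) and
#' category-diversity (CDI) indices, and leave-one-out categorization
#' accuracy as a function of sound duration and of the correlation
#' resolution, including the classifier integration rise time.
#'
#' @param config named list overriding the defaults (see the function body:
#'   dataset size, channel count, `tau_w` ladder, feature `mode`, PCA
#'   retention, GMM components, `lag_step`, `seed`).
#' @return report list (JSON-serializable).
#' @export
run_sound_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_categories = 3, n_exemplars = 6, within_jitter = 0.1,
    duration = 8, n_channels = 8, envelope_rate = 1000,
    tau_w = c(0.05, 0.1, 0.2), si_tau_w = 0.1,
    mode = "spectrotemporal", retain = 0.9, n_components = 1,
    lag_step = 5, n_windows = NULL, seed = 1L), config)
  ds <- gen_category_dataset(cfg$n_categories, cfg$n_exemplars,
                             cfg$within_jitter, seed = cfg$seed,
                             duration = cfg$duration,
                             n_channels = cfg$n_channels,
                             envelope_rate = cfg$envelope_rate)
  # stationarity / diversity at the index resolution
  stcs <- lapply(ds$envelopes, function(coch)
    short_term_correlation(coch, window_spec(cfg$si_tau_w),
                           lags = seq(-12, 12, by = 2)))
  si <- vapply(stcs, stationarity_index, numeric(1))
  tavg <- lapply(stcs, function(s) as.numeric(apply(s$values, c(2, 3, 4),
                                                    mean)))
  cdi <- vapply(seq_len(cfg$n_categories), function(ci)
    category_diversity_index(do.call(rbind, tavg[ds$labels == ci])),
    numeric(1))
  # classification sweep over resolution
  sweeps <- lapply(cfg$tau_w, function(tw) {
    feats <- sound_feature_sets(ds$envelopes, tw, cfg$mode, cfg$lag_step)
    classify_loo(feats, ds$labels, n_windows = cfg$n_windows,
                 retain = cfg$retain, n_components = cfg$n_components,
                 seed = cfg$seed)
  })
  acc_by_res <- vapply(sweeps, function(s) s$accuracy[length(s$accuracy)],
                       numeric(1))
  best <- which.max(acc_by_res)
  durations <- sweeps[[best]]$n_windows * cfg$tau_w[best]
  pc <- if (length(durations) >= 3)
    performance_curve(durations, sweeps[[best]]$accuracy) else NULL
  list(config = cfg,
       si = as.numeric(si), labels = ds$labels,
       category_names = ds$category_names, cdi = as.numeric(cdi),
       accuracy_vs_duration = lapply(sweeps, function(s)
         list(n_windows = s$n_windows, accuracy = as.numeric(s$accuracy))),
       tau_w = cfg$tau_w,
       accuracy_vs_resolution = as.numeric(acc_by_res),
       best_tau_w = cfg$tau_w[best],
       asymptote = pc$asymptote, tau_c = pc$tau_c)
}

neural_accuracy <- function(train_x, train_y, val_x, val_y, retain = 0.9) {
  pca <- fit_pca(train_x, retain)
  mod <- fit_gaussian_bayes(predict(pca, train_x), train_y)
  pr <- map_classify(mod, predict(pca, val_x), combine_n = 1)
  100 * mean(pr$class == as.character(val_y))
}

#' Run the neural-decoding pipeline on synthetic ensembles
#'
#' Generates one multi-trial raster per synthetic "sound", computes the
#' stimulus-driven / noise / total correlation decomposition with population
#' collapses, and runs the noiseless (shuffled) and single-trial classifiers
#' over a half-octave ladder of window durations, plus tonotopy-shuffle and
#' spectrum (rate) controls. Model features come from the first half of each
#' record, validation features from the second half.
#'
#' @param config named list overriding defaults (sound count, channels,
#'   trials, noise, durations ladder, sample counts, seed).
#' @param rasters optional list of [ensemble_raster()]s replacing the
#'   synthetic sounds.
#' @param validation_rasters optional matched list recorded under a
#'   different sound variant (e.g. 1/f-equalized); when supplied the models
#'   are trained on `rasters` and validated on these.
#' @return report list (JSON-serializable).
#' @export
run_neural_pipeline <- function(config = list(), rasters = NULL,
                                validation_rasters = NULL) {
  cfg <- utils::modifyList(list(
    n_sounds = 5, n_channels = 8, n_trials = 10, duration = 12,
    rate = 500, noise = noise_spec(noise_gain = 0.5, spatial_reach = 1,
                                   temporal_width = 0.004),
    durations = c(0.0625, 0.125, 0.25, 0.5, 1),
    train_duration_noiseless = 0.5, train_duration_single = 1,
    n_samples = 60, max_lag = 0.05, lag_step = 2, retain = 0.9,
    seed = 1L), config)
  if (is.null(rasters)) {
    seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1,
                                            2 * cfg$n_sounds))
    rasters <- lapply(seq_len(cfg$n_sounds), function(i) {
      rho <- seq(0.1, 0.8, length.out = cfg$n_sounds)[i]
      tau <- exp(seq(log(0.003), log(0.08),
                     length.out = cfg$n_sounds))[i]
      C <- rho^abs(outer(seq_len(cfg$n_channels),
                         seq_len(cfg$n_channels), "-")); diag(C) <- 1
      env <- gen_correlated_envelopes(texture_spec(
        cfg$n_channels, cfg$duration, cfg$rate, C,
        kernel_exponential(tau), seed = seeds[i]))
      ns <- cfg$noise; ns$seed <- seeds[cfg$n_sounds + i]
      gen_ensemble_raster(env, cfg$n_trials, ns)
    })
  }
  if (dim(rasters[[1]])[3] < 2) stop("need at least 2 trials")
  val_src <- validation_rasters %||% rasters
  n_time <- dim(rasters[[1]])[1]
  h1 <- seq_len(floor(n_time / 2)); h2 <- (floor(n_time / 2) + 1):n_time
  take <- function(r, idx) ensemble_raster(unclass(r)[idx, , , drop = FALSE],
                                           rate = raster_rate(r))
  # population correlation summary on the first sound
  ce <- ensemble_correlation(rasters[[1]], duration = 0.25,
                             lags = seq(-20, 20, by = cfg$lag_step),
                             t_step = 1)
  t_avg <- function(a) apply(a, c(2, 3, 4), mean, na.rm = TRUE)
  cs <- t_avg(ce$c_stim); cn <- t_avg(ce$c_noise)
  li0 <- which.min(abs(ce$lags))
  summary_corr <- list(
    lags = ce$lags,
    stim_offset_profile = as.numeric(collapse_correlations(cs[li0, , ],
                                                           "spectral")),
    noise_offset_profile = as.numeric(collapse_correlations(cn[li0, , ],
                                                            "spectral")),
    stim_lag_profile = as.numeric(collapse_correlations(
      sapply(seq_len(dim(cs)[2]), function(k) cs[, k, k]), "temporal")),
    noise_lag_profile = as.numeric(collapse_correlations(
      sapply(seq_len(dim(cn)[2]), function(k) cn[, k, k]), "temporal")))

  labels <- factor(rep(seq_along(rasters), each = cfg$n_samples))
  get_feats <- function(src, idx, mode, prov, dur, seed_off)
    do.call(rbind, lapply(seq_along(src), function(i)
      neural_features(take(src[[i]], idx), mode, prov,
                      n_samples = cfg$n_samples, duration = dur,
                      max_lag = cfg$max_lag, lag_step = cfg$lag_step,
                      seed = cfg$seed + seed_off + 131 * i)))
  res <- list()
  for (prov in c("shuffled", "single_trial")) {
    tr_dur <- if (prov == "shuffled") cfg$train_duration_noiseless
    else cfg$train_duration_single
    for (mode in c("spectral", "temporal", "spectrum")) {
      tr <- get_feats(rasters, h1, mode, prov, tr_dur, 0)
      acc <- vapply(cfg$durations, function(T) {
        va <- get_feats(val_src, h2, mode, prov, T, 977)
        neural_accuracy(tr, labels, va, labels, cfg$retain)
      }, numeric(1))
      res[[paste(prov, mode, sep = "_")]] <-
        list(durations = cfg$durations, accuracy = as.numeric(acc))
    }
  }
  # tonotopy-shuffle control on the noiseless temporal classifier
  tr <- get_feats(rasters, h1, "temporal", "shuffled",
                  cfg$train_duration_noiseless, 0)
  Tmax <- max(cfg$durations)
  va <- get_feats(val_src, h2, "temporal", "shuffled", Tmax, 977)
  va_shuf <- shuffle_tonotopy(va, cfg$n_channels, seed = cfg$seed + 5)
  res$tonotopy_control <- list(
    duration = Tmax,
    intact = neural_accuracy(tr, labels, va, labels, cfg$retain),
    shuffled = neural_accuracy(tr, labels, va_shuf, labels, cfg$retain))
  list(config = cfg[setdiff(names(cfg), "noise")],
       correlation_summary = summary_corr, classifiers = res)
}
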