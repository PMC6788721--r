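# Decoders: PCA feature reduction, naive-Bayes (axis-aligned Gaussian) and
# GMM MAP classifiers over correlation features, model averaging of spectral
# and temporal evidence, tonotopy shuffling, leave-one-out categorization
# and performance curves.

#' Principal-component reduction of correlation features
#'
#' Centered PCA fitted on training observations only. Components are
#' retained either to reach a target explained-variance fraction
#' (`retain < 1`, e.g. 0.9) or as a fixed count (`retain >= 1`).
#'
#' @param x training observation x feature matrix.
#' @param retain explained-variance fraction in (0, 1) or component count.
#' @return object of class `corr_pca`.
#' @export
fit_pca <- function(x, retain = 0.9) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations for PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  q <- if (retain < 1) which(cumsum(ev) >= retain - 1e-12)[1]
  else min(as.integer(retain), length(ev))
  structure(list(center = p$center,
                 rotation = p$rotation[, seq_len(q), drop = FALSE],
                 sdev = p$sdev, explained = ev, n_components = q),
            class = "corr_pca")
}

#' @export
predict.corr_pca <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
}

#' @export
print.corr_pca <- function(x, ...) {
  cat("PCA basis:", x$n_components, "components,",
      sprintf("%.1f%% variance explained\n",
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}

#' Fit an axis-aligned Gaussian naive-Bayes classifier
#'
#' Per-class, per-dimension means and variances (with a variance floor of
#' `1e-6 * pooled feature variance`) and uniform class priors.
#'
#' @param x observation x feature matrix (typically PCA scores).
#' @param labels class label per observation.
#' @return object of class `corr_bayes`.
#' @export
fit_gaussian_bayes <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (any(table(labels) < 2))
    stop("every class needs at least 2 observations")
  floor_v <- pmax(1e-6 * apply(x, 2, stats::var), 1e-12)
  classes <- levels(labels)
  mu <- matrix(0, length(classes), ncol(x))
  v <- matrix(0, length(classes), ncol(x))
  for (ci in seq_along(classes)) {
    xc <- x[labels == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(xc)
    v[ci, ] <- pmax(apply(xc, 2, stats::var), floor_v)
  }
  structure(list(classes = classes, means = mu, vars = v,
                 priors = rep(1 / length(classes), length(classes))),
            class = "corr_bayes")
}

#' @export
print.corr_bayes <- function(x, ...) {
  cat("Gaussian naive-Bayes classifier:", length(x$classes), "classes,",
      ncol(x$means), "dimensions\n")
  invisible(x)
}

# obs x class log-likelihood matrix
class_loglik <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop("feature dimension does not match the model")
  if (inherits(model, "corr_bayes")) {
    sapply(seq_along(model$classes), function(ci)
      colSums(stats::dnorm(t(x), mean = model$means[ci, ],
                           sd = sqrt(model$vars[ci, ]), log = TRUE)))
  } else if (inherits(model, "corr_gmm")) {
    sapply(model$models, function(m) gmm_log_density(m, x))
  } else stop("unsupported model class")
}

#' MAP classification from summed log-likelihoods
#'
#' Sums per-observation class log-likelihoods over consecutive blocks of
#' `combine_n` observations (features at each time sample treated as
#' conditionally independent, classes equiprobable a priori) and picks the
#' class with the largest posterior; ties break to the lowest class index.
#'
#' @param model a `corr_bayes` or `corr_gmm` model.
#' @param x observation x feature matrix (on the model's PCA scale).
#' @param combine_n observations per decision (default: all rows, one
#'   decision).
#' @return list with `class` (predicted label per block), `log_posterior`
#'   (block x class, normalized), `loglik` (block x class summed
#'   log-likelihoods).
#' @export
map_classify <- function(model, x, combine_n = NULL) {
  x <- as.matrix(x)
  classes <- model$classes
  ll <- class_loglik(model, x)
  ll <- matrix(ll, nrow(x))
  combine_n <- combine_n %||% nrow(x)
  grp <- ceiling(seq_len(nrow(x)) / combine_n)
  sums <- rowsum(ll, grp)
  lp <- sums + rep(log(model$priors %||% rep(1 / ncol(sums), ncol(sums))),
                   each = nrow(sums))
  lpost <- t(apply(lp, 1, function(r) r - log_sum_exp(r)))
  idx <- apply(lp, 1, which.max)
  list(class = classes[idx], index = idx, log_posterior = lpost,
       loglik = sums)
}

#' Model-averaged spectro-temporal classification
#'
#' Combines spectral and temporal log-posteriors as
#' `L = alpha * log P_spec(m|x) + (1 - alpha) * log P_temp(m|x)`.
#'
#' @param model_spec,model_temp fitted classifiers for the two views.
#' @param alpha mixing coefficient in `[0, 1]`.
#' @param x_spec,x_temp matched observation blocks for the two views.
#' @param combine_n observations per decision.
#' @return list with `class`, `index`, `log_posterior`.
#' @export
model_average_classify <- function(model_spec, model_temp, alpha,
                                   x_spec, x_temp, combine_n = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  a <- map_classify(model_spec, x_spec, combine_n)
  b <- map_classify(model_temp, x_temp, combine_n)
  L <- alpha * a$log_posterior + (1 - alpha) * b$log_posterior
  idx <- apply(L, 1, which.max)
  list(class = model_spec$classes[idx], index = idx, log_posterior = L)
}

#' Optimize the spectral/temporal mixing coefficient
#'
#' Grid search over `alpha` maximizing the summed combined log-posterior of
#' the true classes on training data; ties break to the smaller alpha.
#'
#' @param model_spec,model_temp fitted classifiers.
#' @param x_spec,x_temp training observations for the two views.
#' @param labels true class per decision block.
#' @param combine_n observations per decision.
#' @param grid candidate alphas.
#' @export
optimize_alpha <- function(model_spec, model_temp, x_spec, x_temp, labels,
                           combine_n = NULL, grid = seq(0, 1, by = 0.05)) {
  scores <- vapply(grid, function(a) {
    r <- model_average_classify(model_spec, model_temp, a, x_spec, x_temp,
                                combine_n)
    li <- match(as.character(labels), model_spec$classes)
    sum(r$log_posterior[cbind(seq_along(li), li)])
  }, numeric(1))
  grid[which.max(scores)]
}

#' Shuffle tonotopy of temporal-correlation validation features
#'
#' Randomly permutes the channel blocks of each validation observation
#' (features laid out as consecutive per-channel lag profiles), destroying
#' tonotopic identity while preserving each within-channel lag profile.
#' Training features are left untouched by the caller.
#'
#' @param x observation x (n_channels * lags-per-channel) matrix.
#' @param n_channels number of channel blocks.
#' @param seed integer seed.
#' @export
shuffle_tonotopy <- function(x, n_channels, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) %% n_channels != 0)
    stop("feature layout is not channel-blocked")
  p <- ncol(x) / n_channels
  with_seed(seed, {
    t(apply(x, 1, function(r) {
      blocks <- matrix(r, nrow = p)
      as.numeric(blocks[, sample.int(n_channels)])
    }))
  })
}

#' Per-window spectrum (mean amplitude) features
#'
#' Windowed per-channel average amplitude of a cochleogram or raster slice:
#' the rate/spectrum control features for the spectrum-based classifier.
#'
#' @param coch a [cochleogram] or time x channel matrix.
#' @param window a [window_spec()] (its squared window is used as the
#'   averaging kernel).
#' @param t_idx evaluation sample indices (default: non-overlapping grid).
#' @param rate sample rate for bare matrices.
#' @return observation x channel matrix of mean amplitudes.
#' @export
spectrum_features <- function(coch, window, t_idx = NULL, rate = NULL) {
  if (inherits(coch, "cochleogram")) {
    S <- coch$envelopes; rate <- coch$envelope_rate
  } else {
    S <- as.matrix(coch); stopifnot(!is.null(rate))
  }
  W <- kaiser_window_from_resolution(window$resolution, window$beta, rate,
                                     window$kind)
  w2 <- attr(W, "w2")
  h <- (length(w2) - 1) / 2
  if (is.null(t_idx))
    t_idx <- default_time_grid(nrow(S), h, 0,
                               round(window$resolution * rate))
  out <- t(vapply(t_idx, function(t0) {
    seg <- S[(t0 - h):(t0 + h), , drop = FALSE]
    as.numeric(crossprod(w2, seg) / sum(w2))
  }, numeric(ncol(S))))
  attr(out, "times") <- (t_idx - 1) / rate
  out
}

#' Half-octave ladder of window counts
#'
#' `N = 1, 1.41, 2, ...` rounded and deduplicated, capped at `n_max`.
#' @param n_max largest usable window count.
#' @export
window_count_ladder <- function(n_max) {
  unique(pmin(round(2^(seq(0, log2(n_max) + 0.25, by = 0.5))), n_max))
}

#' Leave-one-out category classification versus duration
#'
#' For each held-out sound, fits PCA (on training observations only) and a
#' per-category likelihood model (axis-aligned Gaussian when
#' `n_components = 1`, otherwise a diagonal GMM with the component count
#' fixed or selected by cross-validated likelihood), then classifies the
#' held-out sound from its first `N` consecutive non-overlapping windows for
#' each `N` in `n_windows`. Each iteration scores 0 or 100%; accuracies are
#' averaged over held-out sounds.
#'
#' @param features list of observation x feature matrices, one per sound
#'   (windows in temporal order).
#' @param labels category label per sound (>= 2 sounds per category).
#' @param n_windows vector of window counts N (default: half-octave ladder
#'   up to the shortest sound).
#' @param retain PCA retention (fraction or count).
#' @param n_components GMM component count, or vector = selection grid.
#' @param seed integer seed.
#' @return list with `accuracy` (per N, in percent), `n_windows`,
#'   `predictions` (sound x N matrix), `confusion` (at the largest N).
#' @export
classify_loo <- function(features, labels, n_windows = NULL, retain = 0.9,
                         n_components = 1, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stop("need >= 2 sounds per category")
  n_sounds <- length(features)
  min_obs <- min(vapply(features, nrow, integer(1)))
  if (is.null(n_windows)) n_windows <- window_count_ladder(min_obs)
  if (max(n_windows) > min_obs) {
    warning("requested duration exceeds sound length; truncating")
    n_windows <- unique(pmin(n_windows, min_obs))
  }
  preds <- matrix(NA_integer_, n_sounds, length(n_windows))
  for (i in seq_len(n_sounds)) {
    tr_x <- do.call(rbind, features[-i])
    tr_y <- rep(labels[-i], vapply(features[-i], nrow, integer(1)))
    pca <- fit_pca(tr_x, retain)
    z <- predict(pca, tr_x)
    model <- if (length(n_components) == 1 && n_components == 1) {
      fit_gaussian_bayes(z, tr_y)
    } else {
      ms <- lapply(levels(labels), function(cl) {
        zc <- z[tr_y == cl, , drop = FALSE]
        if (length(n_components) > 1)
          select_gmm_components(zc, grid = n_components, seed = seed)$model
        else fit_diag_gmm(zc, n_components, seed = seed)
      })
      structure(list(models = ms, classes = levels(labels),
                     priors = rep(1 / nlevels(labels), nlevels(labels))),
                class = "corr_gmm")
    }
    zv <- predict(pca, features[[i]])
    for (ni in seq_along(n_windows)) {
      r <- map_classify(model, zv[seq_len(n_windows[ni]), , drop = FALSE])
      preds[i, ni] <- r$index
    }
  }
  acc <- 100 * colMeans(preds == as.integer(labels))
  conf <- table(truth = labels,
                predicted = levels(labels)[preds[, length(n_windows)]])
  list(accuracy = stats::setNames(acc, n_windows), n_windows = n_windows,
       predictions = preds, confusion = conf)
}

#' Asymptote and integration rise time of a performance curve
#'
#' The asymptote is the accuracy at the longest duration; the rise time
#' tau_c is the first duration at which accuracy reaches 90% of the
#' asymptote, log-linearly interpolated between grid points. A warning is
#' issued for non-monotone curves (first crossing is used).
#'
#' @param durations increasing durations, seconds.
#' @param accuracies matching accuracies.
#' @return list with `asymptote`, `tau_c` (seconds).
#' @export
performance_curve <- function(durations, accuracies) {
  stopifnot(length(durations) == length(accuracies), length(durations) >= 3)
  o <- order(durations)
  durations <- unname(durations[o]); accuracies <- unname(accuracies[o])
  if (any(diff(accuracies) < 0))
    warning("non-monotone performance curve; using first crossing")
  asym <- accuracies[length(accuracies)]
  thr <- 0.9 * asym
  i <- which(accuracies >= thr)[1]
  tau_c <- if (i == 1) durations[1] else {
    f <- (thr - accuracies[i - 1]) / (accuracies[i] - accuracies[i - 1])
    exp(log(durations[i - 1]) + f * (log(durations[i]) - log(durations[i - 1])))
  }
  list(asymptote = asym, tau_c = tau_c)
}
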