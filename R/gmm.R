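# Diagonal-covariance Gaussian mixture models fitted by EM with k-means
# initialization, restarts, a variance floor, and component-count selection
# by cross-validated held-out log-likelihood.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# obs x component matrix of log N(x; mu_k, diag(v_k)) + log weight
gmm_log_comp <- function(X, model) {
  K <- length(model$weights)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    out[, k] <- log(model$weights[k]) +
      colSums(stats::dnorm(t(X), mean = model$means[k, ],
                           sd = sqrt(model$vars[k, ]), log = TRUE))
  }
  out
}

#' Log-density under a diagonal GMM
#'
#' @param model a fitted [fit_diag_gmm()] model.
#' @param X observation x feature matrix.
#' @return log-likelihood per observation.
#' @export
gmm_log_density <- function(model, X) {
  X <- as.matrix(X)
  lc <- gmm_log_comp(X, model)
  apply(lc, 1, log_sum_exp)
}

em_once <- function(X, K, var_floor, tol, max_iter, seed) {
  n <- nrow(X); p <- ncol(X)
  km <- with_seed(seed, tryCatch(
    suppressWarnings(stats::kmeans(X, centers = min(K, n), nstart = 1,
                                   iter.max = 30)),
    error = function(e) {
      # duplicate rows can defeat random-row initialization; fall back to
      # assigning observations to components round-robin
      cl <- rep_len(seq_len(min(K, n)), n)
      list(cluster = cl,
           centers = rowsum(X, cl) / as.numeric(table(cl)))
    }))
  model <- list(
    weights = pmax(tabulate(km$cluster, K), 1) / sum(pmax(tabulate(km$cluster, K), 1)),
    means = {
      M <- matrix(0, K, p)
      M[seq_len(nrow(km$centers)), ] <- km$centers
      if (K > nrow(km$centers))
        M[(nrow(km$centers) + 1):K, ] <- km$centers[
          sample.int(nrow(km$centers), K - nrow(km$centers), replace = TRUE), ]
      M
    },
    vars = matrix(rep(pmax(apply(X, 2, stats::var), var_floor), each = K),
                  K, p))
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    lc <- gmm_log_comp(X, model)
    lse <- apply(lc, 1, log_sum_exp)
    ll <- mean(lse)
    resp <- exp(lc - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8) || !is.finite(ll)) return(NULL)  # degenerate
    model$weights <- nk / n
    model$means <- (t(resp) %*% X) / nk
    for (k in seq_len(ncol(resp))) {
      d2 <- sweep(X, 2, model$means[k, ])^2
      model$vars[k, ] <- pmax(colSums(resp[, k] * d2) / nk[k], var_floor)
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  model$loglik <- sum(apply(gmm_log_comp(X, model), 1, log_sum_exp))
  model
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' K-means-style initialization, `n_restarts` random restarts keeping the
#' best log-likelihood, per-feature variance floor of
#' `1e-6 * var(feature)`, and convergence tolerance 1e-6 on the mean
#' log-likelihood. Degenerate runs (empty components) are discarded; if all
#' restarts degenerate an error is raised.
#'
#' @param X observation x feature matrix.
#' @param n_components number of mixture components.
#' @param n_restarts random restarts.
#' @param tol convergence tolerance on mean log-likelihood.
#' @param max_iter EM iteration cap.
#' @param seed integer seed.
#' @return list with `weights`, `means`, `vars`, `loglik`; class `diag_gmm`.
#' @export
fit_diag_gmm <- function(X, n_components, n_restarts = 5, tol = 1e-6,
                         max_iter = 200, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < n_components)
    stop("fewer observations than mixture components")
  var_floor <- pmax(1e-6 * apply(X, 2, stats::var), 1e-12)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_restarts))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    m <- em_once(X, n_components, var_floor, tol, max_iter, seeds[r])
    if (!is.null(m) && (is.null(best) || m$loglik > best$loglik)) best <- m
  }
  if (is.null(best)) stop("all EM restarts degenerated")
  best$n_components <- n_components
  class(best) <- "diag_gmm"
  best
}

#' Select the GMM component count by cross-validated likelihood
#'
#' For each candidate component count, fits the mixture on training folds
#' and evaluates the held-out log-likelihood (5-fold); returns the count
#' maximizing the mean held-out log-likelihood and the final model refitted
#' on all data.
#'
#' @param X observation x feature matrix.
#' @param grid candidate component counts.
#' @param n_folds cross-validation folds.
#' @param seed integer seed.
#' @return list `model` (final [fit_diag_gmm()] fit), `n_components`,
#'   `cv_loglik` (per grid value).
#' @export
select_gmm_components <- function(X, grid = 1:20, n_folds = 5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  grid <- grid[grid <= floor(n * (1 - 1 / n_folds))]
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  cv <- vapply(grid, function(K) {
    ll <- 0
    for (f in seq_len(n_folds)) {
      tr <- X[folds != f, , drop = FALSE]
      te <- X[folds == f, , drop = FALSE]
      m <- tryCatch(fit_diag_gmm(tr, K, seed = seed + f),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      ll <- ll + sum(gmm_log_density(m, te))
    }
    ll / n
  }, numeric(1))
  K_best <- grid[which.max(cv)]
  list(model = fit_diag_gmm(X, K_best, seed = seed),
       n_components = K_best,
       cv_loglik = stats::setNames(cv, grid))
}
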