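# Stationarity index (SI) and category diversity index (CDI) over vectorized
# short-term correlation trajectories.

# coerce an stc or matrix into a time x dimension trajectory
as_trajectory <- function(x) {
  if (inherits(x, "short_term_correlation"))
    x <- decompose_correlation(x, "spectrotemporal")
  as.matrix(x)
}

#' Stationarity index of a short-term correlation trajectory
#'
#' `SI = 1 - <||c(t) - <c(t)>||> / ||<c(t)>||` where `<.>` averages over
#' time points and `||.||` is the vector norm; the short-term correlation at
#' each time point is treated as one vector of dimension M*L^2. SI is
#' clipped to `[0, 1]`: 1 means the moment-to-moment variability of the
#' correlation structure is zero (wide-sense stationary), values near 0 mean
#' highly nonstationary statistics.
#'
#' @param traj a [short_term_correlation()] or a time x dimension matrix of
#'   vectorized correlations.
#' @return SI in `[0, 1]`.
#' @export
stationarity_index <- function(traj) {
  X <- as_trajectory(traj)
  if (nrow(X) < 2) stop("need at least 2 valid time points")
  m <- colMeans(X)
  nm <- vec_norm(m)
  if (nm == 0) stop("zero mean-correlation norm: SI undefined")
  dev <- mean(apply(X, 1, function(r) vec_norm(r - m)))
  min(max(1 - dev / nm, 0), 1)
}

#' Category diversity index across an ensemble of sounds
#'
#' For the time-averaged correlation vectors `c_n` of the sounds in one
#' category, `CDI = E_n[ ||c_n - E[c_n]|| ] / ||E[c_n]||`: the ensemble-
#' averaged deviation norm normalized by the norm of the ensemble mean.
#' 0 means all members share the same time-averaged correlation structure;
#' large values indicate a heterogeneous category.
#'
#' @param category_means a member x dimension matrix, or list of equal-length
#'   vectors (one time-averaged correlation vector per sound).
#' @return CDI >= 0.
#' @export
category_diversity_index <- function(category_means) {
  if (is.list(category_means))
    category_means <- do.call(rbind, lapply(category_means, as.numeric))
  X <- as.matrix(category_means)
  if (nrow(X) < 2) stop("need at least 2 ensemble members")
  m <- colMeans(X)
  nm <- vec_norm(m)
  if (nm == 0) stop("zero ensemble-mean norm: CDI undefined")
  mean(apply(X, 1, function(r) vec_norm(r - m))) / nm
}
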