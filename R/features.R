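## Regression-feature extraction and dimensionality reduction.
##
## Each flux trajectory is summarised by the four features of an
## ordinary-least-squares line fit of flux on time: intercept, gradient,
## coefficient of determination (R^2) and mean squared error. The feature
## vectors of all simulations of one reaction are then reduced to two
## principal components, which is the space in which wild-type boundaries are
## drawn.

#' Fit the four linear-regression features of one flux series
#'
#' Ordinary least squares of flux on time. The intercept and gradient capture
#' level and drift, the mean squared residual captures smoothness versus
#' oscillation, and R^2 captures linearity. A zero-variance (constant) series
#' is a perfect constant fit and gets `r_squared = 1`, `mse = 0`.
#'
#' @param series A data frame with columns `time_s` and `flux` (at least two
#'   rows with two distinct times).
#' @return Named numeric vector `c(intercept, gradient, r_squared, mse)`.
#' @export
#' @examples
#' fit_linear_features(data.frame(time_s = 0:3, flux = c(1, 3, 5, 7)))
fit_linear_features <- function(series) {
  t <- as.numeric(series$time_s)
  y <- as.numeric(series$flux)
  if (length(t) < 2L || length(unique(t)) < 2L) {
    stop_degenerate_input("need >= 2 points with >= 2 distinct times")
  }
  n <- length(t)
  tbar <- mean(t)
  ybar <- mean(y)
  sxx <- sum((t - tbar)^2)
  sxy <- sum((t - tbar) * (y - ybar))
  gradient <- sxy / sxx
  intercept <- ybar - gradient * tbar
  resid <- y - intercept - gradient * t
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - ybar)^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  c(intercept = intercept, gradient = gradient, r_squared = r2,
    mse = ss_res / n)
}

#' Extract the feature table of a flux ensemble
#'
#' Applies [fit_linear_features()] to every (simulation, reaction) series.
#'
#' @param records List of `simulation_record` objects.
#' @return Data frame with columns `simulation_id`, `reaction_id`,
#'   `intercept`, `gradient`, `r_squared`, `mse`.
#' @export
extract_features <- function(records) {
  rows <- lapply(records, function(rec) {
    feats <- t(vapply(rec$series, fit_linear_features, numeric(4L)))
    data.frame(simulation_id = rec$simulation_id,
               reaction_id = rownames(feats), feats, row.names = NULL)
  })
  do.call(rbind, rows) %||%
    data.frame(simulation_id = character(), reaction_id = character(),
               intercept = numeric(), gradient = numeric(),
               r_squared = numeric(), mse = numeric())
}

## Shared PCA core. `scale` toggles z-standardisation before centring (used
## for the 4 regression features, whose scales differ wildly; binary profile
## matrices share a scale and are only centred). Sign convention: the
## largest-magnitude entry of each loading column is made positive, so scores
## are reproducible across platforms up to nothing.
.pca_core <- function(X, n_components, scale) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (anyNA(X)) stop_invalid_argument("feature matrix contains missing values")
  if (n < n_components) {
    stop_invalid_argument("need at least as many rows as components")
  }
  center <- colMeans(X)
  scl <- rep(1, ncol(X))
  if (scale) {
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  if (all(abs(Xs) < 1e-12)) {
    warning("zero total variance: returning all-zero scores")
    return(structure(
      list(scores = matrix(0, n, n_components,
                           dimnames = list(rownames(X),
                                           paste0("PC", seq_len(n_components)))),
           explained_variance_fraction = 0,
           component_variance = rep(0, n_components),
           loadings = matrix(0, ncol(X), n_components,
                             dimnames = list(colnames(X),
                                             paste0("PC",
                                                    seq_len(n_components)))),
           center = center, scale = scl),
      class = "reduced_scores"
    ))
  }
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  ## fix signs
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  if (k < n_components) {
    pad <- matrix(0, ncol(X), n_components - k)
    load <- cbind(load, pad)
  }
  colnames(load) <- paste0("PC", seq_len(n_components))
  scores <- Xs %*% load
  ev <- pc$sdev^2
  frac <- sum(ev[seq_len(min(n_components, length(ev)))]) / sum(ev)
  structure(
    list(scores = scores, explained_variance_fraction = frac,
         component_variance = ev / sum(ev), loadings = load,
         center = center, scale = scl),
    class = "reduced_scores"
  )
}

#' Reduce regression-feature vectors to principal components
#'
#' Z-standardises the four regression features (their native scales differ by
#' orders of magnitude, so unscaled PCA would be dominated by the mean
#' squared error), centres, and projects onto the leading principal
#' components. One PCA problem is one reaction's feature vectors pooled
#' across wild-type and knockout simulations.
#'
#' @param feature_matrix Numeric matrix, simulations x features (typically
#'   n x 4).
#' @param n_components Number of retained components (default 2).
#' @param standardise Z-standardise columns before PCA (default `TRUE`).
#' @return An object of class `reduced_scores`: `scores` (n x k),
#'   `explained_variance_fraction`, per-component variance fractions,
#'   orthonormal `loadings`, and the centring/scaling parameters needed to
#'   [project_scores()] new points.
#' @export
reduce_features <- function(feature_matrix, n_components = 2L,
                            standardise = TRUE) {
  .pca_core(feature_matrix, n_components, scale = standardise)
}

#' Project new feature vectors into an existing principal-component space
#'
#' @param reduction A `reduced_scores` object.
#' @param X New rows on the original feature scale.
#' @return Score matrix in the reduction's component space.
#' @export
project_scores <- function(reduction, X) {
  X <- matrix(as.numeric(as.matrix(X)), ncol = length(reduction$center))
  Xs <- sweep(sweep(X, 2L, reduction$center), 2L, reduction$scale, "/")
  Xs %*% reduction$loadings
}

#' @export
print.reduced_scores <- function(x, ...) {
  cat(sprintf(
    "Principal-component reduction: %d points, %d components, %.1f%% variance retained\n",
    nrow(x$scores), ncol(x$scores), 100 * x$explained_variance_fraction))
  invisible(x)
}
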