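## Per-reaction normal/abnormal classification on weak labels: fixed-length
## trajectory encoding, a 4-hidden-layer MLP per reaction, hyperparameter
## grid search, stratified k-fold cross-validation, the 70% accuracy filter
## and the binary flux profiles.

#' Specify one per-reaction classifier configuration
#'
#' The canonical architecture is a multilayer perceptron with four equally
#' wide hidden layers, softmax output and Adam optimiser. The canonical
#' hyperparameter grid (see [classifier_grid()]) crosses epochs {5, 10, 15},
#' batch sizes {50, 100, 150} and widths {750, 1500, 2250}; any positive
#' width is accepted here so that desk-scale studies can train narrower
#' networks.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param width Nodes per hidden layer.
#' @param hidden_layers Number of hidden layers (default and canonical: 4).
#' @param seed Integer seed driving initialisation, shuffling and splits.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(epochs = 10L, batch_size = 100L, width = 750L,
                            hidden_layers = 4L, seed = 1L) {
  vals <- c(epochs = epochs, batch_size = batch_size, width = width,
            hidden_layers = hidden_layers)
  if (any(vals < 1) || any(vals != floor(vals))) {
    stop_invalid_argument("classifier spec fields must be positive integers")
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         width = as.integer(width), hidden_layers = as.integer(hidden_layers),
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' The canonical 27-point hyperparameter grid
#'
#' @param epochs,batch_sizes,widths Grid axes; defaults are the canonical
#'   values.
#' @param seed Seed shared by all grid points.
#' @return List of [classifier_spec()] objects (27 by default).
#' @export
classifier_grid <- function(epochs = c(5L, 10L, 15L),
                            batch_sizes = c(50L, 100L, 150L),
                            widths = c(750L, 1500L, 2250L),
                            seed = 1L) {
  grid <- expand.grid(epochs = epochs, batch_size = batch_sizes,
                      width = widths)
  lapply(seq_len(nrow(grid)), function(i) {
    classifier_spec(grid$epochs[i], grid$batch_size[i], grid$width[i],
                    seed = seed)
  })
}

#' Encode a flux series as a fixed-length classifier input
#'
#' Linearly resamples the series onto `target_length` uniformly spaced time
#' points spanning its observed range, then min-max scales the resampled
#' values to [0, 1] per series. Constant series map to the all-zero vector.
#'
#' @param series Data frame with `time_s` and `flux` columns (non-empty).
#' @param target_length Length of the encoded vector.
#' @return Numeric vector of length `target_length` in [0, 1].
#' @export
prepare_classifier_input <- function(series, target_length = 500L) {
  t <- as.numeric(series$time_s)
  y <- as.numeric(series$flux)
  if (length(t) == 0L) stop_degenerate_input("empty series")
  if (length(t) == 1L || diff(range(t)) == 0) {
    v <- rep(y[1L], target_length)
  } else {
    xout <- seq(min(t), max(t), length.out = target_length)
    v <- stats::approx(t, y, xout = xout, ties = "ordered")$y
  }
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0, target_length))
  (v - rng[1L]) / diff(rng)
}

## Stratified index split: per class, a seeded sample of `frac` goes to the
## second part (holdout). Guarantees >= 1 holdout example per class when the
## class has >= 2 members.
.stratified_holdout <- function(labels, frac, seed) {
  set.seed(seed)
  holdout <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, round(frac * length(idx)))
    if (length(idx) > 1L) holdout <- c(holdout, sample(idx, k))
  }
  sort(holdout)
}

.check_two_classes <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L) {
    stop_degenerate_labels("weak labels contain a single class")
  }
  tab
}

#' Train one reaction's normality classifier
#'
#' Trains the MLP of `spec` on an 80/20 stratified train/holdout split of the
#' encoded series and their weak labels, and reports holdout accuracy.
#' Single-class label sets raise a `wcflux_degenerate_labels` error; such
#' reactions are excluded from profiling, like sub-70% reactions.
#'
#' @param inputs Numeric matrix, simulations x encoded length.
#' @param weak_labels Character vector of `"normal"`/`"abnormal"` (or a
#'   [combine_labels()] data frame).
#' @param spec A [classifier_spec()].
#' @param holdout_fraction Fraction held out for accuracy estimation
#'   (default 0.2).
#' @return An object of class `reaction_classifier` with the fitted weights,
#'   the spec and `holdout_accuracy`.
#' @export
train_reaction_classifier <- function(inputs, weak_labels,
                                      spec = classifier_spec(),
                                      holdout_fraction = 0.2) {
  X <- as.matrix(inputs)
  labels <- if (is.data.frame(weak_labels)) weak_labels$label else weak_labels
  if (length(labels) != nrow(X)) {
    stop_invalid_argument("one label per input row required")
  }
  .check_two_classes(labels)
  y01 <- as.integer(labels == LABEL_ABNORMAL)
  hold <- .stratified_holdout(labels, holdout_fraction, spec$seed)
  train <- setdiff(seq_len(nrow(X)), hold)
  if (min(table(labels[train])) < 2L) {
    stop_degenerate_labels("need >= 2 training examples of each class")
  }
  par <- .mlp_train(X[train, , drop = FALSE], y01[train], spec$width,
                    spec$hidden_layers, spec$epochs, spec$batch_size,
                    spec$seed)
  pred <- .mlp_predict01(par, X[hold, , drop = FALSE])
  structure(
    list(model = par, spec = spec,
         holdout_accuracy = mean(pred == y01[hold]),
         n_train = length(train), n_holdout = length(hold)),
    class = "reaction_classifier"
  )
}

#' Predict normality labels with a trained reaction classifier
#'
#' @param object A `reaction_classifier`.
#' @param newdata Encoded input matrix (or single vector).
#' @param ... Unused.
#' @return Character vector of `"normal"`/`"abnormal"`.
#' @export
predict.reaction_classifier <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
       else as.matrix(newdata)
  ifelse(.mlp_predict01(object$model, X) == 1L, LABEL_ABNORMAL, LABEL_NORMAL)
}

#' @export
print.reaction_classifier <- function(x, ...) {
  cat(sprintf(
    "MLP classifier: %d hidden layers x %d nodes, %d epochs, batch %d; holdout accuracy %.3f\n",
    x$spec$hidden_layers, x$spec$width, x$spec$epochs, x$spec$batch_size,
    x$holdout_accuracy))
  invisible(x)
}

#' Grid search over classifier hyperparameters
#'
#' Trains every grid point and returns the classifier with the highest
#' holdout accuracy. Ties are broken deterministically toward fewer epochs,
#' then smaller width, then larger batch size.
#'
#' @inheritParams train_reaction_classifier
#' @param grid List of [classifier_spec()] objects.
#' @return The winning `reaction_classifier` (with the full accuracy table in
#'   `$grid_accuracies`).
#' @export
grid_search <- function(inputs, weak_labels, grid = classifier_grid()) {
  if (!length(grid)) stop_invalid_argument("empty hyperparameter grid")
  fits <- lapply(grid, function(spec) {
    train_reaction_classifier(inputs, weak_labels, spec)
  })
  acc <- vapply(fits, function(f) f$holdout_accuracy, numeric(1L))
  ep <- vapply(grid, function(s) s$epochs, integer(1L))
  wd <- vapply(grid, function(s) s$width, integer(1L))
  bt <- vapply(grid, function(s) s$batch_size, integer(1L))
  best <- order(-acc, ep, wd, -bt)[1L]
  fit <- fits[[best]]
  fit$grid_accuracies <- data.frame(epochs = ep, batch_size = bt, width = wd,
                                    holdout_accuracy = acc)
  fit
}

#' Stratified k-fold assignment
#'
#' Shuffles each class and deals its members round-robin over the folds,
#' continuing the deal across classes so that both the per-class counts and
#' the total fold sizes differ by at most one.
#'
#' @param labels Class label per example.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold id (1..k) per example.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2L || k > n) {
    stop_invalid_argument("k must be between 2 and the number of examples")
  }
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1L) idx <- sample(idx)
    fold[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Stratified k-fold cross-validation of one classifier spec
#'
#' The overfitting check: fold accuracies that agree with the holdout
#' accuracy indicate the network has not overfitted its training split.
#'
#' @inheritParams train_reaction_classifier
#' @param k Number of folds (default 10; must be between 2 and the number of
#'   examples).
#' @return Numeric vector of `k` fold accuracies.
#' @export
cross_validate <- function(inputs, weak_labels, spec = classifier_spec(),
                           k = 10L) {
  X <- as.matrix(inputs)
  labels <- if (is.data.frame(weak_labels)) weak_labels$label else weak_labels
  n <- nrow(X)
  if (k < 2L || k > n) {
    stop_invalid_argument("k must be between 2 and the number of examples")
  }
  .check_two_classes(labels)
  y01 <- as.integer(labels == LABEL_ABNORMAL)
  fold <- stratified_folds(labels, k, spec$seed)
  vapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    par <- .mlp_train(X[train, , drop = FALSE], y01[train], spec$width,
                      spec$hidden_layers, spec$epochs, spec$batch_size,
                      spec$seed + f)
    mean(.mlp_predict01(par, X[test, , drop = FALSE]) == y01[test])
  }, numeric(1L))
}

#' Filter out weak classifiers
#'
#' Keeps classifiers whose holdout accuracy is at least `min_accuracy`
#' (default 0.70; an accuracy of exactly 0.70 is retained). The retained set
#' is ordered by reaction id.
#'
#' @param records Named list of `reaction_classifier` objects (names =
#'   reaction ids) or a list of such lists with `holdout_accuracy` fields.
#' @param min_accuracy Retention threshold in [0, 1].
#' @return The retained sub-list, sorted by reaction id.
#' @export
filter_classifiers <- function(records, min_accuracy = 0.70) {
  if (!length(records)) return(records[0])
  acc <- vapply(records, function(r) r$holdout_accuracy, numeric(1L))
  kept <- records[acc >= min_accuracy]
  kept[order(names(kept))]
}

#' Build the binary flux profile of one simulation
#'
#' One bit per retained reaction: 0 when that reaction's classifier predicts
#' normal behaviour for this simulation's trajectory, 1 when abnormal.
#'
#' @param simulation A `simulation_record`.
#' @param classifiers Named list of retained `reaction_classifier` objects.
#' @param target_length Encoding length used at training time.
#' @return Named integer 0/1 vector of class `flux_profile` with a
#'   `simulation_id` attribute.
#' @export
make_flux_profile <- function(simulation, classifiers, target_length = 500L) {
  rids <- names(classifiers)
  missing <- setdiff(rids, names(simulation$series))
  if (length(missing)) {
    stop_missing_series(sprintf(
      "simulation %s lacks series for: %s", simulation$simulation_id,
      paste(missing, collapse = ", ")))
  }
  bits <- vapply(rids, function(rid) {
    x <- prepare_classifier_input(simulation$series[[rid]], target_length)
    as.integer(predict(classifiers[[rid]], x) == LABEL_ABNORMAL)
  }, integer(1L))
  structure(bits, simulation_id = simulation$simulation_id,
            class = "flux_profile")
}

#' Stack flux profiles into a simulations x reactions matrix
#'
#' @param records List of `simulation_record` objects.
#' @param classifiers Named list of retained classifiers.
#' @param target_length Encoding length used at training time.
#' @return Integer 0/1 matrix with simulation ids as row names.
#' @export
flux_profile_matrix <- function(records, classifiers, target_length = 500L) {
  rows <- lapply(records, function(rec) {
    p <- make_flux_profile(rec, classifiers, target_length)
    stats::setNames(as.integer(p), names(p))
  })
  P <- do.call(rbind, rows)
  rownames(P) <- vapply(records, function(r) r$simulation_id, character(1L))
  P
}
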