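test_that("trajectory encoding resamples, scales and degrades sanely", {
  ## uniform-grid series: values preserved up to the min-max map
  t <- seq(0, 90, by = 10)
  y <- c(2, 4, 8, 6, 10, 12, 9, 7, 5, 3)
  v <- prepare_classifier_input(data.frame(time_s = t, flux = y), 10L)
  expect_equal(v, (y - min(y)) / diff(range(y)), tolerance = 1e-12)

  ## constant series map to all-zeros
  vc <- prepare_classifier_input(data.frame(time_s = 1:5, flux = rep(7, 5)),
                                 8L)
  expect_equal(vc, rep(0, 8))

  ## downsampling a line matches analytic interpolation, i.e. stays a line
  tl <- seq_len(500)
  vl <- prepare_classifier_input(data.frame(time_s = tl, flux = tl), 100L)
  expect_equal(vl, seq(0, 1, length.out = 100), tolerance = 1e-12)

  expect_error(prepare_classifier_input(data.frame(time_s = numeric(),
                                                   flux = numeric()), 10L),
               class = "wcflux_degenerate_input")
})

test_that("the MLP learns a separable fixture and is seed-deterministic", {
  fx <- separable_fixture(100L, 20L, seed = 5)
  spec <- classifier_spec(epochs = 10, batch_size = 20, width = 32, seed = 2)
  fit <- train_reaction_classifier(fx$X, fx$labels, spec)
  expect_gte(fit$holdout_accuracy, 0.95)

  fit2 <- train_reaction_classifier(fx$X, fx$labels, spec)
  expect_identical(fit$holdout_accuracy, fit2$holdout_accuracy)
  expect_identical(fit$model, fit2$model)

  ## chance level on permuted labels (balanced classes)
  set.seed(9)
  perm <- sample(fx$labels)
  fitp <- train_reaction_classifier(fx$X, perm, spec)
  expect_lte(abs(fitp$holdout_accuracy - 0.5), 0.15)

  expect_error(
    train_reaction_classifier(fx$X, rep("normal", nrow(fx$X)), spec),
    class = "wcflux_degenerate_labels")
})

test_that("grid search evaluates every point and breaks ties stably", {
  fx <- separable_fixture(25L, 20L, seed = 8)
  one <- classifier_spec(epochs = 5, batch_size = 10, width = 16, seed = 4)
  best1 <- grid_search(fx$X, fx$labels, list(one))
  expect_identical(best1$spec, one)

  grid <- list(classifier_spec(5, 10, 16, seed = 4),
               classifier_spec(10, 10, 16, seed = 4),
               classifier_spec(5, 25, 8, seed = 4))
  best <- grid_search(fx$X, fx$labels, grid)
  individual <- vapply(grid, function(s) {
    train_reaction_classifier(fx$X, fx$labels, s)$holdout_accuracy
  }, numeric(1))
  expect_equal(best$holdout_accuracy, max(individual))
  expect_equal(nrow(best$grid_accuracies), length(grid))

  ## ties break toward fewer epochs, then smaller width, then larger batch
  tie <- grid_search(fx$X, fx$labels,
                     list(classifier_spec(15, 10, 16, seed = 4),
                          classifier_spec(5, 10, 16, seed = 4)))
  if (tie$grid_accuracies$holdout_accuracy[1] ==
        tie$grid_accuracies$holdout_accuracy[2]) {
    expect_equal(tie$spec$epochs, 5L)
  }
  expect_error(grid_search(fx$X, fx$labels, list()),
               class = "wcflux_invalid_argument")
})

test_that("cross-validation folds are stratified, balanced and stable", {
  fx <- separable_fixture(40L, 30L, seed = 6)
  spec <- classifier_spec(epochs = 15, batch_size = 10, width = 32, seed = 3)
  expect_error(cross_validate(fx$X, fx$labels, spec, k = 1),
               class = "wcflux_invalid_argument")
  expect_error(cross_validate(fx$X, fx$labels, spec, k = 1000),
               class = "wcflux_invalid_argument")

  acc <- cross_validate(fx$X, fx$labels, spec, k = 5)
  expect_length(acc, 5L)
  fit <- train_reaction_classifier(fx$X, fx$labels, spec)
  expect_lte(abs(mean(acc) - fit$holdout_accuracy), 0.1)
})

test_that("fold assignment partitions evenly within and across classes", {
  labels <- rep(c("normal", "abnormal"), c(33, 21))
  k <- 10L
  fold <- stratified_folds(labels, k, seed = 1)
  sizes <- tabulate(fold, k)
  expect_lte(diff(range(sizes)), 1L)
  for (cl in unique(labels)) {
    cl_sizes <- tabulate(fold[labels == cl], k)
    expect_lte(diff(range(cl_sizes)), 1L)
  }
  expect_error(stratified_folds(labels, 1L),
               class = "wcflux_invalid_argument")
})

test_that("the 70% filter keeps the boundary case and orders by reaction", {
  mk <- function(acc) structure(list(holdout_accuracy = acc),
                                class = "reaction_classifier")
  recs <- list(r3 = mk(0.95), r1 = mk(0.69), r2 = mk(0.70))
  kept <- filter_classifiers(recs)
  expect_named(kept, c("r2", "r3"))
  expect_length(filter_classifiers(list()), 0L)
  expect_named(filter_classifiers(recs, min_accuracy = 0),
               c("r1", "r2", "r3"))
})

test_that("flux profiles collect per-reaction predictions", {
  archs <- test_archetypes()
  wt <- generate_wildtype_ensemble(archs, 30, duration_s = 10000, dt_s = 100,
                                   seed = 21)
  ko <- generate_knockout_ensemble(
    archs, "metabolic",
    list(perturbation_spec("R_001", "offset_shift", 6),
         perturbation_spec("R_002", "slope_shift", 6),
         perturbation_spec("R_003", "amplitude_shift", 6)),
    30, duration_s = 10000, dt_s = 100, seed = 22)
  records <- c(wt, ko)
  feat <- extract_features(records)
  wildtype <- rep(c(TRUE, FALSE), each = 30)

  classifiers <- list()
  for (rid in c("R_001", "R_002", "R_003")) {
    sub <- feat[feat$reaction_id == rid, ]
    m <- as.matrix(sub[, c("intercept", "gradient", "r_squared", "mse")])
    wl <- weak_label_reaction(reduce_features(m)$scores, wildtype)
    X <- t(vapply(records, function(r) {
      prepare_classifier_input(r$series[[rid]], 60L)
    }, numeric(60)))
    classifiers[[rid]] <- train_reaction_classifier(
      X, wl$weak_labels$label,
      classifier_spec(epochs = 10, batch_size = 20, width = 32, seed = 6))
  }

  prof_ko <- make_flux_profile(records[[35]], classifiers, 60L)
  expect_length(prof_ko, 3L)
  expect_true(all(prof_ko %in% 0:1))
  expect_gte(sum(prof_ko), 2)  # at least 2 of 3 perturbed bits flagged

  prof_wt <- make_flux_profile(records[[1]], classifiers, 60L)
  expect_length(prof_wt, 3L)

  broken <- records[[1]]
  broken$series$R_002 <- NULL
  expect_error(make_flux_profile(broken, classifiers, 60L),
               class = "wcflux_missing_series")

  P <- flux_profile_matrix(records, classifiers, 60L)
  expect_equal(dim(P), c(60L, 3L))
  expect_identical(rownames(P)[1], records[[1]]$simulation_id)
})
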