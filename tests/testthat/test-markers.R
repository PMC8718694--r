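test_that("profile PCA separates distinct clusters and handles degeneracy", {
  P <- rbind(matrix(0L, 10, 6), matrix(1L, 10, 6))
  red <- reduce_profiles(P)
  expect_gte(red$explained_variance_fraction, 1 - 1e-10)
  ## PC1 splits the clusters; two-point covariance oracle: scores at
  ## +/- sqrt(6)/2 after centring
  expect_equal(sort(unique(round(red$scores[, 1], 10))),
               c(-sqrt(6) / 2, sqrt(6) / 2), tolerance = 1e-8)
  expect_true(max(red$scores[1:10, 1]) < min(red$scores[11:20, 1]) ||
                min(red$scores[1:10, 1]) > max(red$scores[11:20, 1]))

  red2 <- reduce_profiles(P)
  expect_identical(red$scores, red2$scores)

  expect_warning(z <- reduce_profiles(matrix(1L, 5, 4)), "zero")
  expect_true(all(z$scores == 0))
  expect_error(reduce_profiles(P[1, , drop = FALSE]),
               class = "wcflux_invalid_argument")
})

test_that("linear SVM separability distinguishes separated from random data", {
  set.seed(71)
  X <- rbind(matrix(stats::rnorm(100, mean = -3, sd = 0.3), ncol = 2),
             matrix(stats::rnorm(100, mean = 3, sd = 0.3), ncol = 2))
  y <- rep(c(0L, 1L), each = 50)
  sep <- svm_separability(X, y, reaction_id = "Rx")
  expect_equal(sep$accuracy, 1)
  expect_true(sep$passes)

  ## hyperplane re-evaluation oracle: the stored hyperplane reclassifies
  ## the training points to the reported accuracy
  pred_hp <- as.integer(drop(X %*% sep$hyperplane$w) + sep$hyperplane$b > 0)
  expect_equal(mean(pred_hp == y), sep$accuracy)

  ## chance-level labels on one Gaussian blob are not separable
  set.seed(72)
  Xb <- matrix(stats::rnorm(1000), ncol = 2)
  yb <- sample(0:1, 500, replace = TRUE)
  sepb <- svm_separability(Xb, yb)
  expect_lt(sepb$accuracy, 0.95)
  expect_false(sepb$passes)
  pred_hpb <- as.integer(drop(Xb %*% sepb$hyperplane$w) +
                           sepb$hyperplane$b > 0)
  expect_equal(mean(pred_hpb == yb), sepb$accuracy)

  expect_error(svm_separability(X, rep(0L, 100)),
               class = "wcflux_degenerate_labels")
})

test_that("phi coefficient follows its closed form and symmetries", {
  expect_equal(phi_coefficient(rbind(c(10, 0), c(0, 10))), 1)
  expect_equal(phi_coefficient(rbind(c(5, 5), c(5, 5))), 0)
  expect_equal(phi_coefficient(rbind(c(20, 5), c(10, 65))),
               1250 / sqrt(3937500), tolerance = 1e-12)
  expect_equal(phi_coefficient(rbind(c(20, 5), c(10, 65))), 0.6299,
               tolerance = 1e-4)
  expect_error(phi_coefficient(rbind(c(5, 0), c(7, 0))),
               class = "wcflux_undefined_statistic")

  ## phi equals the Pearson correlation of the expanded binary variables
  set.seed(81)
  for (i in 1:100) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    x <- rep(c(1, 1, 0, 0), tab[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))])
    y <- rep(c(1, 0, 1, 0), tab[cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))])
    expect_equal(phi_coefficient(tab), stats::cor(x, y), tolerance = 1e-10)
    ## swapping both rows and columns preserves phi; one swap flips the sign
    expect_equal(phi_coefficient(tab[2:1, 2:1]), phi_coefficient(tab),
                 tolerance = 1e-12)
    expect_equal(phi_coefficient(tab[2:1, ]), -phi_coefficient(tab),
                 tolerance = 1e-12)
  }
})

test_that("the printed phenotype table classifies all seven rows", {
  expect_identical(
    classify_phenotype(phenotype_flags(FALSE, FALSE, FALSE, FALSE, FALSE)),
    "metabolic")
  expect_identical(
    classify_phenotype(phenotype_flags(TRUE, FALSE, FALSE, FALSE, FALSE)),
    "rna")
  expect_identical(
    classify_phenotype(phenotype_flags(TRUE, TRUE, FALSE, FALSE, FALSE)),
    "protein")
  expect_identical(
    classify_phenotype(phenotype_flags(FALSE, TRUE, TRUE, TRUE, FALSE)),
    "dna")
  expect_identical(
    classify_phenotype(phenotype_flags(TRUE, TRUE, TRUE, TRUE, FALSE,
                                       division_initiated = TRUE)),
    "slow_growing")
  expect_identical(
    classify_phenotype(phenotype_flags(TRUE, TRUE, TRUE, TRUE, FALSE,
                                       division_initiated = FALSE)),
    "septum")
  expect_identical(
    classify_phenotype(phenotype_flags(TRUE, TRUE, TRUE, TRUE, TRUE)),
    "non_essential")

  ## unlisted combinations are refused, not guessed
  expect_error(
    classify_phenotype(phenotype_flags(FALSE, FALSE, TRUE, FALSE, FALSE)),
    class = "wcflux_unclassified_phenotype")
  expect_error(
    classify_phenotype(phenotype_flags(TRUE, TRUE, TRUE, FALSE, FALSE)),
    class = "wcflux_unclassified_phenotype")
  ## completed division implies initiated division
  expect_error(phenotype_flags(TRUE, TRUE, TRUE, TRUE, TRUE,
                               division_initiated = FALSE),
               class = "wcflux_invalid_argument")
})

test_that("marker report consolidates drivers, phi and separability", {
  expect_equal(nrow(marker_report(list(drivers = character()))), 0L)

  ## planted marker: reaction M abnormal exactly in class "k1"
  set.seed(91)
  classes <- rep(c("k1", "k2", "k3"), each = 30)
  P <- cbind(M = as.integer(classes == "k1"),
             O = sample(0:1, 90, replace = TRUE, prob = c(0.9, 0.1)))
  phi_m <- phi_by_class(P, classes)
  expect_identical(names(which.max(abs(phi_m["M", ]))), "k1")
  expect_gte(phi_m["M", "k1"], 0.9)

  scores <- cbind(P[, "M"] * 4 + stats::rnorm(90, sd = 0.2),
                  stats::rnorm(90, sd = 0.2))
  sep <- list(M = svm_separability(scores, P[, "M"], "M"))
  report <- marker_report(list(drivers = c("M", "O")), sep, phi_m,
                          annotations = data.frame(
                            reaction_id = c("M", "O"),
                            pathways = c("Pyrimidine metabolism", "n/a"),
                            annotated_via = c("self", "none")))
  expect_equal(nrow(report), 2L)
  mrow <- report[report$reaction_id == "M", ]
  expect_identical(mrow$best_class, "k1")
  expect_true(mrow$separable)
  expect_identical(mrow$pathways, "Pyrimidine metabolism")
  expect_true(is.na(report$separable[report$reaction_id == "O"]))
})
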