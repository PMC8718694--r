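test_that("wild-type generation handles empty and noise-free cases", {
  archs <- test_archetypes()
  expect_length(generate_wildtype_ensemble(archs, 0, seed = 1), 0L)

  const <- list(reaction_archetype("R_C", "steady", baseline = 3,
                                   noise_sd = 0))
  wt <- generate_wildtype_ensemble(const, 3, duration_s = 1000, dt_s = 100,
                                   seed = 5, jitter = 0)
  for (rec in wt) {
    expect_true(all(rec$series$R_C$flux == 3.0))
    expect_true(all(rec$truth_labels == "normal"))
  }
  expect_error(generate_wildtype_ensemble(const, 2, duration_s = -1),
               class = "wcflux_invalid_argument")
  expect_error(generate_wildtype_ensemble(const, 2, dt_s = 0),
               class = "wcflux_invalid_argument")
})

test_that("a fixed seed reproduces an ensemble bit-for-bit", {
  archs <- test_archetypes()
  e1 <- generate_wildtype_ensemble(archs, 5, duration_s = 5000, dt_s = 100,
                                   seed = 7)
  e2 <- generate_wildtype_ensemble(archs, 5, duration_s = 5000, dt_s = 100,
                                   seed = 7)
  expect_identical(e1, e2)
  k1 <- generate_knockout_ensemble(
    archs, "metabolic", list(perturbation_spec("R_001", "offset_shift", 5)),
    4, duration_s = 5000, dt_s = 100, seed = 3)
  k2 <- generate_knockout_ensemble(
    archs, "metabolic", list(perturbation_spec("R_001", "offset_shift", 5)),
    4, duration_s = 5000, dt_s = 100, seed = 3)
  expect_identical(k1, k2)
})

test_that("knockout truth labels track exactly the perturbed reactions", {
  archs <- test_archetypes()
  none <- generate_knockout_ensemble(archs, "rna", list(), 3,
                                     duration_s = 2000, dt_s = 100, seed = 2)
  for (rec in none) expect_true(all(rec$truth_labels == "normal"))

  perts <- list(perturbation_spec("R_001", "collapse_to_zero"),
                perturbation_spec("R_002", "slope_shift", 5))
  ko <- generate_knockout_ensemble(archs, "metabolic", perts, 5,
                                   duration_s = 2000, dt_s = 100, seed = 2)
  for (rec in ko) {
    abn <- names(rec$truth_labels)[rec$truth_labels == "abnormal"]
    expect_setequal(abn, c("R_001", "R_002"))
    expect_length(abn, length(perts))
    expect_true(all(rec$series$R_001$flux == 0))
  }
  expect_error(
    generate_knockout_ensemble(
      archs, "rna", list(perturbation_spec("NOPE", "offset_shift", 1)), 2,
      duration_s = 2000, dt_s = 100, seed = 1),
    class = "wcflux_key_not_found")
})

test_that("knockout phenotype flags map back to the requested class", {
  archs <- test_archetypes()
  for (cls in c("metabolic", "rna", "protein", "slow_growing", "dna",
                "septum", "non_essential")) {
    ko <- generate_knockout_ensemble(archs, cls, list(), 1,
                                     duration_s = 1000, dt_s = 100, seed = 1)
    expect_identical(classify_phenotype(ko[[1]]$phenotype_flags), cls)
  }
})

test_that("stoichiometric generator respects structure requests", {
  expect_equal(ncol(generate_stoichiometric_matrix(5, 0, 0, seed = 1)), 0L)

  S <- generate_stoichiometric_matrix(10, 6, 4, connectivity = 3, seed = 9)
  tx <- grep("^TX_", colnames(S), value = TRUE)
  expect_length(tx, 4L)
  expect_equal(ncol(S), 10L)
  expect_equal(nrow(S), 14L)  # internal + one boundary row per transport
  for (j in tx) {
    touched <- rownames(S)[S[, j] != 0]
    expect_length(grep("^MET_", touched), 1L)
    expect_length(grep("^BND_", touched), 1L)
  }
  expect_false(any(colSums(S != 0) == 0))
  expect_error(generate_stoichiometric_matrix(3, 2, 0, connectivity = 0.5),
               class = "wcflux_invalid_argument")
})

test_that("a planted three-reaction chain yields one driver node", {
  ## R1-R2 share metabolite B, R2-R3 share C; path graph on three nodes
  S <- rbind(A = c(-1, 0, 0), B = c(1, -1, 0), C = c(0, 1, -1),
             D = c(0, 0, 1))
  colnames(S) <- c("R1", "R2", "R3")
  A <- adjacency_from_stoichiometry(S)
  expect_equal(sum(A) / 2, 2)
  ds <- find_driver_nodes(A, "maximum")
  expect_length(ds$drivers, nrow(A) - 2 * brute_max_matching(A))
  expect_length(ds$drivers, 1L)
})

test_that("planted marker transport is isolated hence always a driver", {
  S <- generate_stoichiometric_matrix(8, 5, 2, seed = 4)
  S2 <- plant_marker_transport(S, "TX_MARK")
  A <- adjacency_from_stoichiometry(S2)
  expect_true(all(A["TX_MARK", ] == 0))
  expect_true("TX_MARK" %in% find_driver_nodes(A)$drivers)
  expect_error(plant_marker_transport(S2, "TX_MARK"),
               class = "wcflux_invalid_argument")
})
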