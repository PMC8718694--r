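test_that("adjacency construction matches the shared-metabolite relation", {
  ## single reaction -> 1x1 zero matrix
  S1 <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  expect_equal(adjacency_from_stoichiometry(S1),
               matrix(0L, 1, 1, dimnames = list("R1", "R1")))

  ## triangle: R1 A->B, R2 B->C, R3 C->A
  S3 <- rbind(A = c(-1, 0, 1), B = c(1, -1, 0), C = c(0, 1, -1))
  colnames(S3) <- c("R1", "R2", "R3")
  A3 <- adjacency_from_stoichiometry(S3)
  expect_true(all(A3[upper.tri(A3)] == 1L))
  expect_true(all(diag(A3) == 0L))

  expect_error(adjacency_from_stoichiometry(matrix(0, 0, 0)),
               class = "wcflux_invalid_argument")

  ## random matrices vs a pairwise set-intersection oracle
  set.seed(51)
  for (i in 1:30) {
    nm <- sample(2:30, 1)
    nr <- sample(2:40, 1)
    S <- matrix(sample(c(0L, 0L, 0L, -1L, 1L, 2L), nm * nr, replace = TRUE),
                nm, nr, dimnames = list(paste0("M", 1:nm), paste0("R", 1:nr)))
    A <- adjacency_from_stoichiometry(S)
    expect_true(isSymmetric(unname(A)))
    expect_true(all(diag(A) == 0L))
    for (p in seq_len(nr)) {
      for (q in seq_len(nr)) {
        if (p == q) next
        share <- length(intersect(which(S[, p] != 0), which(S[, q] != 0))) > 0
        expect_identical(A[p, q] == 1L, share)
      }
    }
  }
})

test_that("driver counts equal the exhaustive-matching oracle", {
  ## single edge: perfect matching, no drivers
  A2 <- matrix(c(0L, 1L, 1L, 0L), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_length(find_driver_nodes(A2)$drivers, 0L)

  ## 3-path: exactly one driver
  A3 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A3["a", "b"] <- A3["b", "a"] <- 1L
  A3["b", "c"] <- A3["c", "b"] <- 1L
  expect_length(find_driver_nodes(A3)$drivers, 1L)

  set.seed(61)
  for (i in 1:60) {
    A <- random_adjacency(sample(2:8, 1))
    ds <- find_driver_nodes(A, "maximum")
    expect_length(ds$drivers, nrow(A) - 2L * brute_max_matching(A))
    ## matching edges pairwise disjoint, drivers unmatched
    expect_false(anyDuplicated(c(ds$matching)) > 0)
    expect_length(intersect(ds$drivers, c(ds$matching)), 0L)
    ## greedy never yields fewer drivers
    dg <- find_driver_nodes(A, "greedy_sorted")
    expect_gte(length(dg$drivers), length(ds$drivers))
    expect_false(anyDuplicated(c(dg$matching)) > 0)
  }

  ## isolated nodes are always drivers
  Aiso <- matrix(0L, 3, 3, dimnames = list(c("x", "y", "z"),
                                           c("x", "y", "z")))
  Aiso["x", "y"] <- Aiso["y", "x"] <- 1L
  expect_identical(find_driver_nodes(Aiso)$drivers, "z")
})

test_that("transport fraction of drivers is reported", {
  S <- plant_marker_transport(generate_stoichiometric_matrix(8, 6, 3,
                                                             seed = 2))
  ds <- find_driver_nodes(adjacency_from_stoichiometry(S))
  fr <- driver_transport_fraction(ds)
  expect_true(fr >= 0 && fr <= 1)
  expect_equal(fr, mean(startsWith(ds$drivers, "TX_")))
})

test_that("abnormality frequencies are per-group bit means", {
  P <- rbind(c(1, 0), c(0, 0), c(1, 1), c(1, 0))
  colnames(P) <- c("Ra", "Rb")
  f <- abnormality_frequencies(P)
  expect_equal(unname(f["all", ]), c(0.75, 0.25))

  g <- abnormality_frequencies(P, c("u", "u", "v", "v"))
  expect_equal(unname(g["u", ]), c(0.5, 0))
  expect_equal(unname(g["v", ]), c(1, 0.5))
  expect_true(all(g >= 0 & g <= 1))

  expect_error(abnormality_frequencies(P[0, , drop = FALSE]),
               class = "wcflux_invalid_argument")
})

test_that("the exponential noise threshold follows its closed form", {
  nt <- noise_threshold(rep(0.1, 7), coverage = 0.95)
  expect_equal(nt$rate, 10, tolerance = 1e-12)
  expect_equal(nt$threshold, -log(0.05) / 10, tolerance = 1e-12)
  expect_equal(nt$threshold, 0.29957, tolerance = 1e-4)

  ## coverage -> 0 gives threshold -> 0; monotone in coverage and mean
  expect_equal(noise_threshold(rep(0.1, 3), coverage = 0)$threshold, 0)
  t1 <- noise_threshold(rep(0.1, 3), coverage = 0.9)$threshold
  t2 <- noise_threshold(rep(0.1, 3), coverage = 0.95)$threshold
  t3 <- noise_threshold(rep(0.2, 3), coverage = 0.95)$threshold
  expect_lt(t1, t2)
  expect_lt(t2, t3)

  expect_warning(nt0 <- noise_threshold(c(0, 0, 0)), "degenerate")
  expect_equal(nt0$threshold, 0)
})

test_that("class sub-networks induce exactly the selected nodes and edges", {
  A <- random_adjacency(6, p = 0.5)
  freqs <- stats::setNames(c(0.9, 0.1, 0.5, 0.05, 0.8, 0.02), rownames(A))

  empty <- class_subnetwork(A, freqs, 1.0)
  expect_equal(igraph::vcount(empty), 0L)

  one <- class_subnetwork(A, stats::setNames(c(0.9, rep(0.1, 5)),
                                             rownames(A)), 0.3)
  expect_equal(igraph::vcount(one), 1L)

  sub <- class_subnetwork(A, freqs, 0.3)
  sel <- names(freqs)[freqs > 0.3]
  expect_setequal(igraph::V(sub)$name, sel)
  el <- igraph::as_edgelist(sub)
  for (i in seq_along(sel)) {
    for (j in seq_along(sel)) {
      if (i < j) {
        has_edge <- any((el[, 1] == sel[i] & el[, 2] == sel[j]) |
                          (el[, 1] == sel[j] & el[, 2] == sel[i]))
        expect_identical(has_edge, A[sel[i], sel[j]] == 1L)
      }
    }
  }
  expect_equal(igraph::V(sub)$frequency, unname(freqs[sel]))
})

test_that("pathway annotation joins, inherits from neighbours, or is n/a", {
  A <- matrix(0L, 3, 3, dimnames = list(c("R1", "R2", "TX_9"),
                                        c("R1", "R2", "TX_9")))
  A["R1", "R2"] <- A["R2", "R1"] <- 1L
  ds <- list(drivers = c("R1", "R2", "TX_9"))

  empty_tab <- data.frame(reaction_id = character(), pathway = character())
  out0 <- annotate_pathways(ds, empty_tab, A)
  expect_true(all(out0$pathways == "n/a"))

  tab <- data.frame(reaction_id = c("R2", "R2"),
                    pathway = c("Pyrimidine metabolism", "Carbon metabolism"))
  out <- annotate_pathways(ds, tab, A)
  expect_match(out$pathways[out$reaction_id == "R2"], "Pyrimidine metabolism")
  ## R1 has no annotation; its only neighbour R2 donates its pathways
  expect_identical(out$annotated_via[out$reaction_id == "R1"], "neighbour")
  expect_match(out$pathways[out$reaction_id == "R1"], "Carbon metabolism")
  ## isolated unannotated driver stays n/a
  expect_identical(out$pathways[out$reaction_id == "TX_9"], "n/a")

  expect_error(annotate_pathways(ds, data.frame(x = 1)),
               class = "wcflux_parse_error")
})
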