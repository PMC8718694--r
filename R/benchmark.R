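## Desk-scale synthetic benchmark: a fixed study design with known ground
## truth on which the whole pipeline can be scored end to end. The design
## emulates the shape of a whole-cell-model knockout screen: a wild-type
## ensemble defines normal behaviour, five knockout classes perturb
## class-specific reaction subsets at a drastic effect size, and one planted
## transport reaction is perturbed in exactly one class so that it should be
## recovered as a class marker among the driver nodes.

#' Build the synthetic benchmark study
#'
#' Generates the benchmark inputs: a random stoichiometric network of 19
#' reactions plus one planted isolated transport marker (20 reactions
#' total), mixed-kind archetypes over those reactions, a wild-type ensemble,
#' and five knockout classes (metabolic, rna, protein, dna, non_essential)
#' whose perturbations (effect size 6, i.e. drastic) target disjoint
#' reaction subsets. The planted marker `TX_MARK` collapses to zero flux in
#' the metabolic class only.
#'
#' @param seed Integer seed; every ensemble seed derives from it.
#' @param n_wildtype Number of wild-type simulations (default 60).
#' @param n_knockout_per_class Knockout simulations per class (default 40,
#'   i.e. 200 knockouts in total).
#' @param duration_s,dt_s Time grid (default 50,000 s at 100 s: 500 points).
#' @return A list: `records`, `stoichiometry`, `archetypes`, `wildtype`
#'   (logical per record), `classes` (per record, `NA` for wild type),
#'   `truth` (simulations x reactions character matrix), `marker`,
#'   `marker_class`, `perturbed` (named list class -> reaction ids).
#' @export
synthetic_benchmark <- function(seed = 1L, n_wildtype = 60L,
                                n_knockout_per_class = 40L,
                                duration_s = 50000, dt_s = 100) {
  S <- plant_marker_transport(
    generate_stoichiometric_matrix(15, 15, 4, connectivity = 3,
                                   seed = seed),
    "TX_MARK")
  rids <- colnames(S)
  kinds <- c("steady", "ramp", "oscillation", "step", "burst")
  archetypes <- lapply(seq_along(rids), function(i) {
    if (rids[i] == "TX_MARK") {
      return(reaction_archetype("TX_MARK", "steady", baseline = 3,
                                noise_sd = 0.3))
    }
    switch(kinds[(i - 1L) %% 5L + 1L],
      steady = reaction_archetype(rids[i], "steady", baseline = 5,
                                  noise_sd = 0.3),
      ramp = reaction_archetype(rids[i], "ramp", baseline = 1, slope = 2e-4,
                                noise_sd = 0.3),
      oscillation = reaction_archetype(rids[i], "oscillation", baseline = 0,
                                       amplitude = 2, period = 5000,
                                       noise_sd = 0.3),
      step = reaction_archetype(rids[i], "step", baseline = 2,
                                amplitude = 1.5, noise_sd = 0.3),
      burst = reaction_archetype(rids[i], "burst", baseline = 1,
                                 amplitude = 3, period = 2000,
                                 noise_sd = 0.3)
    )
  })
  ## Perturbation modes are matched to the archetype kind so every
  ## disruption changes the trajectory's *shape*: slope shifts derange the
  ## drift of steady/ramp reactions (gradient and R^2 move together),
  ## collapses silence oscillatory/step/burst reactions (MSE and R^2 move
  ## together). A pure offset shift moves only one of the four standardised
  ## features and can be dropped by 2-component PCA; see the vignette.
  shift <- function(rid) perturbation_spec(rid, "slope_shift",
                                           effect_size = 6)
  collapse <- function(rid) perturbation_spec(rid, "collapse_to_zero")
  perturbations <- list(
    metabolic = list(collapse("TX_MARK"),
                     shift("R_001"), shift("R_002"),
                     collapse("R_003"), collapse("R_004")),
    rna = list(collapse("R_005"), shift("R_006")),
    protein = list(shift("R_007"), collapse("R_008"), collapse("R_009")),
    dna = list(collapse("R_010")),
    non_essential = list()
  )
  records <- generate_wildtype_ensemble(archetypes, n_wildtype, duration_s,
                                        dt_s, seed = seed + 1L)
  for (i in seq_along(perturbations)) {
    cls <- names(perturbations)[i]
    records <- c(records, generate_knockout_ensemble(
      archetypes, cls, perturbations[[i]], n_knockout_per_class, duration_s,
      dt_s, seed = seed + 1L + i))
  }
  wildtype <- vapply(records, function(r) r$genotype == "wild_type",
                     logical(1L))
  classes <- vapply(records, function(r) r$phenotype_class %||%
                      NA_character_, character(1L))
  truth <- t(vapply(records, function(r) r$truth_labels[rids],
                    character(length(rids))))
  colnames(truth) <- rids
  rownames(truth) <- vapply(records, function(r) r$simulation_id,
                            character(1L))
  list(records = records, stoichiometry = S, archetypes = archetypes,
       wildtype = wildtype, classes = classes, truth = truth,
       marker = "TX_MARK", marker_class = "metabolic",
       perturbed = lapply(perturbations, function(ps) {
         vapply(ps, function(p) p$reaction_id, character(1L))
       }))
}

#' Run and score the pipeline on the synthetic benchmark
#'
#' Executes every stage on a [synthetic_benchmark()] study and scores it
#' against the study's ground truth: per-reaction weak-label accuracy, mean
#' retained-classifier holdout accuracy, profile PCA variance, the wild-type
#' noise threshold, driver nodes and their transport fraction, and the
#' planted marker's phi coefficient and linear separability for its class.
#' Phenotype-dependent scores (phi, separability, profile PCA) use the
#' knockout simulations, mirroring a training-versus-analysis split; the
#' noise threshold comes from the wild-type profiles.
#'
#' @param study A [synthetic_benchmark()] list.
#' @param classifier A [classifier_spec()]; the default desk-scale network
#'   (width 128, 10 epochs, batch 50) trains in seconds per reaction.
#' @param input_length Trajectory encoding length (default 100).
#' @return A list of scores; see Details in the vignette.
#' @export
run_benchmark <- function(study,
                          classifier = classifier_spec(epochs = 10L,
                                                       batch_size = 50L,
                                                       width = 128L),
                          input_length = 100L) {
  records <- study$records
  rids <- colnames(study$truth)
  n <- length(records)
  feat <- extract_features(records)
  sim_ids <- rownames(study$truth)

  weak <- matrix(NA_character_, n, length(rids),
                 dimnames = list(sim_ids, rids))
  classifiers <- list()
  for (rid in rids) {
    sub <- feat[feat$reaction_id == rid, ]
    m <- as.matrix(sub[, c("intercept", "gradient", "r_squared", "mse")])
    rownames(m) <- sub$simulation_id
    m <- m[sim_ids, , drop = FALSE]
    red <- reduce_features(m)
    wl <- weak_label_reaction(red$scores, study$wildtype)
    weak[, rid] <- wl$weak_labels$label
    X <- t(vapply(records, function(r) {
      prepare_classifier_input(r$series[[rid]], input_length)
    }, numeric(input_length)))
    spec <- classifier
    fit <- tryCatch(train_reaction_classifier(X, weak[, rid], spec),
                    wcflux_degenerate_labels = function(e) NULL)
    if (!is.null(fit)) classifiers[[rid]] <- fit
  }
  weak_label_accuracy <- vapply(rids, function(rid) {
    mean(weak[, rid] == study$truth[, rid])
  }, numeric(1L))

  retained <- filter_classifiers(classifiers, 0.70)
  holdout <- vapply(retained, function(f) f$holdout_accuracy, numeric(1L))
  profiles <- flux_profile_matrix(records, retained, input_length)
  ## classifier accuracy against ground truth, not just weak labels
  truth_bits <- (study$truth[, names(retained), drop = FALSE] ==
                   "abnormal") + 0L
  truth_accuracy <- colMeans(profiles == truth_bits)

  ko <- !study$wildtype
  prof_red <- reduce_profiles(profiles[ko, , drop = FALSE])
  wt_freq <- abnormality_frequencies(
    profiles[study$wildtype, , drop = FALSE])["all", ]
  thr <- noise_threshold(wt_freq, coverage = 0.95)

  A <- adjacency_from_stoichiometry(study$stoichiometry)
  drivers <- find_driver_nodes(A, "maximum")

  phi_m <- phi_by_class(profiles[ko, , drop = FALSE], study$classes[ko])
  marker_phi <- if (study$marker %in% rownames(phi_m)) {
    phi_m[study$marker, study$marker_class]
  } else NA_real_
  marker_sep <- if (study$marker %in% colnames(profiles)) {
    svm_separability(prof_red$scores, profiles[ko, study$marker],
                     study$marker)
  } else NULL

  detection_rate <- vapply(rids, function(rid) {
    abn <- study$truth[, rid] == "abnormal"
    if (!any(abn)) return(NA_real_)
    mean(weak[abn, rid] == "abnormal")
  }, numeric(1L))

  list(
    weak_labels = weak,
    weak_label_accuracy = weak_label_accuracy,
    weak_label_detection = detection_rate,
    perturbed_reactions = unique(unlist(study$perturbed)),
    n_classifiers_trained = length(classifiers),
    n_retained = length(retained),
    holdout_accuracy = holdout,
    mean_holdout_accuracy = mean(holdout),
    truth_accuracy = truth_accuracy,
    profiles = profiles,
    profile_variance_fraction = prof_red$explained_variance_fraction,
    profile_scores = prof_red$scores,
    noise_threshold = thr,
    drivers = drivers,
    driver_transport_fraction = driver_transport_fraction(drivers),
    phi_by_class = phi_m,
    marker_phi = marker_phi,
    marker_separability = marker_sep
  )
}
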