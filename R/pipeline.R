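## End-to-end pipeline driver: features -> boundaries -> weak labels ->
## classifiers -> profiles -> profile PCA -> network/drivers -> markers,
## with every stage's table written to the output directory and a JSON
## manifest recording seeds, configuration and per-stage record counts.

#' Build a pipeline configuration
#'
#' Materialises every tunable of the pipeline with its default so a run is
#' fully described by one object. Paths may be `NULL` where a stage is fed
#' in-memory records instead.
#'
#' @param flux_path Long-format flux TSV (training + analysis simulations).
#' @param stoichiometry_path Stoichiometric-matrix TSV.
#' @param simulations_path Simulation metadata TSV (`simulation_id`,
#'   `genotype`, optional `phenotype_class`); wild-type rows have genotype
#'   `"wild_type"`.
#' @param phenotype_path Optional phenotype-flag TSV; when absent the marker
#'   stages are skipped.
#' @param annotation_path Optional reaction-to-pathway TSV
#'   (`reaction_id`, `pathway`).
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed; per-stage seeds derive from it.
#' @param boundary_schemes Labelling-function schemes (default all three).
#' @param classifier Classifier spec, or the string `"grid"` to grid-search
#'   the canonical 27-point grid per reaction.
#' @param input_length Fixed encoding length of each trajectory.
#' @param min_accuracy Classifier retention threshold (default 0.70).
#' @param noise_coverage Exponential noise-threshold coverage (default 0.95).
#' @param matching_strategy Driver matching strategy (default `"maximum"`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(flux_path = NULL, stoichiometry_path = NULL,
                            simulations_path = NULL, phenotype_path = NULL,
                            annotation_path = NULL, out_dir = "wcflux-out",
                            seed = 1L,
                            boundary_schemes = BOUNDARY_SCHEMES,
                            classifier = classifier_spec(),
                            input_length = 500L, min_accuracy = 0.70,
                            noise_coverage = 0.95,
                            matching_strategy = "maximum") {
  if (min_accuracy < 0 || min_accuracy > 1 ||
      noise_coverage < 0 || noise_coverage >= 1) {
    stop_invalid_argument("thresholds must lie in [0, 1]")
  }
  structure(
    list(flux_path = flux_path, stoichiometry_path = stoichiometry_path,
         simulations_path = simulations_path,
         phenotype_path = phenotype_path, annotation_path = annotation_path,
         out_dir = out_dir, seed = as.integer(seed),
         boundary_schemes = boundary_schemes, classifier = classifier,
         input_length = as.integer(input_length),
         min_accuracy = min_accuracy, noise_coverage = noise_coverage,
         matching_strategy = matching_strategy),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments; `classifier` may be `"grid"` or a mapping of spec fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$classifier) && !identical(raw$classifier, "grid")) {
    raw$classifier <- do.call(classifier_spec, raw$classifier)
  }
  do.call(pipeline_config, raw)
}

## Pivot the long feature table of one reaction into the n x 4 matrix the
## PCA consumes, rows named by simulation id.
.reaction_feature_matrix <- function(features, reaction_id) {
  sub <- features[features$reaction_id == reaction_id, , drop = FALSE]
  m <- as.matrix(sub[, c("intercept", "gradient", "r_squared", "mse")])
  rownames(m) <- sub$simulation_id
  m
}

#' Run the full analysis pipeline
#'
#' Executes the eight stages in order on a flux ensemble: (1) per-reaction
#' regression features, (2) per-reaction PCA and wild-type boundaries,
#' (3) weak labels from the combined labelling functions, (4) one MLP
#' classifier per reaction with the accuracy filter, (5) binary flux
#' profiles, (6) profile PCA, (7) reaction network, driver nodes and noise
#' threshold, (8) phenotype markers (phi and separability). Stages 7-8 are
#' skipped gracefully when their inputs (stoichiometry, phenotype classes)
#' are absent. All stage outputs are TSV/YAML/GraphML files under
#' `config$out_dir`, plus `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param records Optional in-memory list of `simulation_record`s (otherwise
#'   read from `config$flux_path`).
#' @return The run manifest (a list), invisibly.
#' @export
run_pipeline <- function(config, records = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("wcflux")),
                   seed = config$seed, stages = list(), skipped = character())
  fail <- function(stage, e) {
    wcflux_error("wcflux_stage_error",
                 sprintf("pipeline stage '%s' failed: %s", stage,
                         conditionMessage(e)))
  }

  ## load inputs -----------------------------------------------------------
  if (is.null(records)) {
    if (is.null(config$flux_path)) {
      stop_invalid_argument("either records or config$flux_path is required")
    }
    records <- read_flux_table(config$flux_path)
  }
  sim_ids <- vapply(records, function(r) r$simulation_id, character(1L))
  genotype <- vapply(records, function(r) r$genotype %||% NA_character_,
                     character(1L))
  classes <- vapply(records, function(r) {
    if (!is.null(r$phenotype_class)) r$phenotype_class
    else if (!is.null(r$phenotype_flags)) classify_phenotype(r$phenotype_flags)
    else NA_character_
  }, character(1L))
  if (!is.null(config$simulations_path)) {
    meta <- .read_tsv(config$simulations_path)
    genotype <- meta$genotype[match(sim_ids, meta$simulation_id)]
    if ("phenotype_class" %in% names(meta)) {
      cl <- meta$phenotype_class[match(sim_ids, meta$simulation_id)]
      classes <- ifelse(is.na(cl) | cl == "", classes, cl)
    }
  }
  if (!is.null(config$phenotype_path)) {
    if (!file.exists(config$phenotype_path)) {
      warning(sprintf(
        "phenotype flag file '%s' not found; marker stages will be skipped",
        config$phenotype_path))
    } else {
      flags <- read_phenotype_flags(config$phenotype_path)
      have <- sim_ids %in% names(flags)
      classes[have] <- vapply(flags[sim_ids[have]], classify_phenotype,
                              character(1L))
    }
  }
  wildtype <- !is.na(genotype) & genotype == "wild_type"
  if (sum(wildtype) < 3L) {
    stop_invalid_argument(
      "pipeline needs >= 3 wild-type simulations (genotype 'wild_type')")
  }
  reaction_ids <- sort(names(records[[1L]]$series))

  ## stage 1: features -----------------------------------------------------
  features <- tryCatch(extract_features(records), error = function(e)
    fail("features", e))
  .write_tsv(features, file.path(out, "features.tsv"))
  manifest$stages$features <- nrow(features)

  ## stages 2-3: per-reaction PCA, boundaries, weak labels ------------------
  weak <- list()
  boundaries <- list()
  reductions <- list()
  for (rid in reaction_ids) {
    m <- .reaction_feature_matrix(features, rid)
    m <- m[match(sim_ids, rownames(m)), , drop = FALSE]
    red <- reduce_features(m)
    wl <- weak_label_reaction(red$scores, wildtype,
                              schemes = config$boundary_schemes)
    reductions[[rid]] <- red
    boundaries[[rid]] <- wl$boundaries
    weak[[rid]] <- data.frame(simulation_id = sim_ids, reaction_id = rid,
                              label = wl$weak_labels$label,
                              probability = wl$weak_labels$probability)
  }
  weak_df <- do.call(rbind, weak)
  .write_tsv(weak_df, file.path(out, "weak_labels.tsv"))
  write_boundaries_yaml(boundaries, file.path(out, "boundaries.yaml"))
  manifest$stages$boundaries <- length(boundaries)
  manifest$stages$weak_labels <- nrow(weak_df)

  ## stage 4: per-reaction classifiers -------------------------------------
  encoded <- lapply(stats::setNames(reaction_ids, reaction_ids),
                    function(rid) {
    t(vapply(records, function(rec) {
      prepare_classifier_input(rec$series[[rid]], config$input_length)
    }, numeric(config$input_length)))
  })
  classifiers <- list()
  registry <- list()
  for (rid in reaction_ids) {
    labels <- weak[[rid]]$label
    fit <- tryCatch({
      if (identical(config$classifier, "grid")) {
        grid_search(encoded[[rid]], labels,
                    classifier_grid(seed = config$seed))
      } else {
        spec <- config$classifier
        spec$seed <- config$seed
        train_reaction_classifier(encoded[[rid]], labels, spec)
      }
    }, wcflux_degenerate_labels = function(e) NULL)
    if (is.null(fit)) {
      registry[[rid]] <- data.frame(
        reaction_id = rid, epochs = NA, batch_size = NA, width = NA,
        holdout_accuracy = NA, retained = FALSE, note = "single-class labels")
      next
    }
    classifiers[[rid]] <- fit
    registry[[rid]] <- data.frame(
      reaction_id = rid, epochs = fit$spec$epochs,
      batch_size = fit$spec$batch_size, width = fit$spec$width,
      holdout_accuracy = fit$holdout_accuracy,
      retained = fit$holdout_accuracy >= config$min_accuracy, note = "")
  }
  retained <- filter_classifiers(classifiers, config$min_accuracy)
  registry_df <- do.call(rbind, registry)
  .write_tsv(registry_df, file.path(out, "classifiers.tsv"))
  manifest$stages$classifiers_trained <- length(classifiers)
  manifest$stages$classifiers_retained <- length(retained)

  ## stage 5: flux profiles ------------------------------------------------
  if (!length(retained)) {
    stop_invalid_argument("no classifiers retained; cannot build profiles")
  }
  profiles <- flux_profile_matrix(records, retained, config$input_length)
  .write_tsv(data.frame(simulation_id = rownames(profiles), profiles,
                        check.names = FALSE),
             file.path(out, "profiles.tsv"))
  manifest$stages$profiles <- nrow(profiles)

  ## stage 6: profile PCA --------------------------------------------------
  prof_red <- reduce_profiles(profiles)
  .write_tsv(data.frame(simulation_id = rownames(profiles),
                        PC1 = prof_red$scores[, 1L],
                        PC2 = prof_red$scores[, 2L],
                        phenotype_class = classes),
             file.path(out, "profile_scores.tsv"))
  manifest$stages$profile_variance_fraction <-
    prof_red$explained_variance_fraction

  ## stage 7: network ------------------------------------------------------
  drivers <- NULL
  adjacency <- NULL
  if (!is.null(config$stoichiometry_path)) {
    S <- read_stoichiometric_matrix(config$stoichiometry_path)
    adjacency <- adjacency_from_stoichiometry(S)
    export_reaction_graph(adjacency,
                          graphml_path = file.path(out, "network.graphml"),
                          edges_path = file.path(out, "network_edges.tsv"))
    drivers <- find_driver_nodes(adjacency, config$matching_strategy)
    .write_tsv(data.frame(reaction_id = drivers$drivers),
               file.path(out, "drivers.tsv"))
    wt_freq <- abnormality_frequencies(
      profiles[wildtype, , drop = FALSE])["all", ]
    thr <- noise_threshold(wt_freq, config$noise_coverage)
    group_freq <- if (any(!is.na(classes))) {
      abnormality_frequencies(profiles[!is.na(classes), , drop = FALSE],
                              classes[!is.na(classes)])
    } else NULL
    freq_rows <- list(data.frame(group = "wild_type",
                                 reaction_id = names(wt_freq),
                                 frequency = unname(wt_freq),
                                 consistently_abnormal =
                                   unname(wt_freq > thr$threshold)))
    if (!is.null(group_freq)) {
      for (gr in rownames(group_freq)) {
        v <- group_freq[gr, ]
        freq_rows[[gr]] <- data.frame(group = gr,
                                      reaction_id = names(v),
                                      frequency = unname(v),
                                      consistently_abnormal =
                                        unname(v > thr$threshold))
        subg <- class_subnetwork(adjacency,
                                 v[intersect(names(v), rownames(adjacency))],
                                 thr)
        igraph::write_graph(subg,
                            file.path(out, sprintf("subnetwork_%s.graphml",
                                                   gr)),
                            format = "graphml")
      }
    }
    .write_tsv(do.call(rbind, freq_rows),
               file.path(out, "abnormality_frequencies.tsv"))
    manifest$stages$noise_threshold <- thr$threshold
    manifest$stages$drivers <- length(drivers$drivers)
  } else {
    manifest$skipped <- c(manifest$skipped, "network")
  }

  ## stage 8: markers ------------------------------------------------------
  have_classes <- any(!is.na(classes))
  if (!is.null(drivers) && have_classes) {
    phi_m <- phi_by_class(profiles[!is.na(classes), , drop = FALSE],
                          classes[!is.na(classes)])
    sep <- list()
    for (rid in intersect(drivers$drivers, colnames(profiles))) {
      sep[[rid]] <- tryCatch(
        svm_separability(prof_red$scores, profiles[, rid], rid),
        wcflux_degenerate_labels = function(e) NULL)
    }
    annotations <- if (!is.null(config$annotation_path)) {
      annotate_pathways(drivers, .read_tsv(config$annotation_path),
                        adjacency)
    } else NULL
    report <- marker_report(drivers, sep, phi_m, annotations)
    .write_tsv(report, file.path(out, "markers.tsv"))
    manifest$stages$markers <- nrow(report)
  } else {
    manifest$skipped <- c(manifest$skipped, "markers")
  }

  ## manifest --------------------------------------------------------------
  manifest$config <- list(
    boundary_schemes = config$boundary_schemes,
    classifier = if (identical(config$classifier, "grid")) "grid"
                 else unclass(config$classifier),
    input_length = config$input_length,
    min_accuracy = config$min_accuracy,
    noise_coverage = config$noise_coverage,
    matching_strategy = config$matching_strategy
  )
  cfg_str <- paste(deparse(manifest$config), collapse = "")
  manifest$config_hash <- sprintf("%08x",
                                  sum(utf8ToInt(cfg_str) *
                                        seq_along(utf8ToInt(cfg_str))) %%
                                    .Machine$integer.max)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
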