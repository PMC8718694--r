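## Readers and writers for the package's plain-text interchange formats.
## Long-format TSV is the canonical source of truth for flux series; the
## stoichiometric matrix, truth labels, phenotype flags and all stage outputs
## are TSV as well, and boundaries/configs serialise to YAML.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop_parse_error(sprintf("file not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a flux ensemble as long-format TSV
#'
#' Columns: `simulation_id`, `reaction_id`, `time_s`, `flux`. Sidecar tables
#' (simulation metadata, truth labels, phenotype flags) are written by
#' [write_ensemble_sidecars()].
#'
#' @param records List of `simulation_record` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_flux_table <- function(records, path) {
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(names(rec$series), function(rid) {
      s <- rec$series[[rid]]
      data.frame(simulation_id = rec$simulation_id, reaction_id = rid,
                 time_s = s$time_s, flux = s$flux)
    }))
  })
  df <- do.call(rbind, rows) %||%
    data.frame(simulation_id = character(), reaction_id = character(),
               time_s = numeric(), flux = numeric())
  .write_tsv(df, path)
}

#' Read a long-format flux TSV into simulation records
#'
#' Expects columns `simulation_id`, `reaction_id`, `time_s`, `flux`. Series
#' are grouped by simulation and reaction with times sorted ascending.
#' Missing columns, non-numeric fields and duplicate
#' (simulation, reaction, time) rows raise parse errors naming the offending
#' rows.
#'
#' @param path TSV file path.
#' @return List of `simulation_record` objects (genotype `NA`, no truth
#'   labels).
#' @export
read_flux_table <- function(path) {
  df <- .read_tsv(path)
  needed <- c("simulation_id", "reaction_id", "time_s", "flux")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_parse_error(sprintf("flux table lacks columns: %s",
                             paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(list())
  num_t <- suppressWarnings(as.numeric(df$time_s))
  num_f <- suppressWarnings(as.numeric(df$flux))
  bad <- which(is.na(num_t) | is.na(num_f))
  if (length(bad)) {
    stop_parse_error(sprintf("non-numeric time_s/flux at data row(s) %s",
                             paste(utils::head(bad, 5L), collapse = ", ")))
  }
  key <- paste(df$simulation_id, df$reaction_id, num_t, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_parse_error(sprintf(
      "duplicate (simulation, reaction, time) at data row(s) %s",
      paste(utils::head(dup, 5L), collapse = ", ")))
  }
  df$time_s <- num_t
  df$flux <- num_f
  sims <- split(df, df$simulation_id)
  lapply(sims, function(sd) {
    series <- lapply(split(sd, sd$reaction_id), function(rd) {
      rd <- rd[order(rd$time_s), c("time_s", "flux")]
      rownames(rd) <- NULL
      rd
    })
    structure(
      list(simulation_id = sd$simulation_id[1L], genotype = NA_character_,
           series = series, truth_labels = NULL, phenotype_flags = NULL,
           phenotype_class = NULL),
      class = "simulation_record"
    )
  })
}

#' Write ensemble sidecar tables
#'
#' Writes up to three TSVs next to a flux table: simulation metadata
#' (`simulation_id`, `genotype`, `phenotype_class`), truth labels
#' (`simulation_id`, `reaction_id`, `label`) and phenotype flags
#' (`simulation_id` plus the six flag columns). Tables without content are
#' skipped.
#'
#' @param records List of `simulation_record` objects.
#' @param dir Output directory.
#' @param prefix File-name prefix (default `""`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_ensemble_sidecars <- function(records, dir, prefix = "") {
  meta <- do.call(rbind, lapply(records, function(r) {
    data.frame(simulation_id = r$simulation_id, genotype = r$genotype,
               phenotype_class = r$phenotype_class %||% NA_character_)
  }))
  paths <- c(simulations = file.path(dir, paste0(prefix, "simulations.tsv")))
  .write_tsv(meta, paths[["simulations"]])
  labs <- do.call(rbind, lapply(records, function(r) {
    if (is.null(r$truth_labels)) return(NULL)
    data.frame(simulation_id = r$simulation_id,
               reaction_id = names(r$truth_labels),
               label = unname(r$truth_labels))
  }))
  if (!is.null(labs)) {
    paths[["truth_labels"]] <- file.path(dir,
                                         paste0(prefix, "truth_labels.tsv"))
    .write_tsv(labs, paths[["truth_labels"]])
  }
  flags <- do.call(rbind, lapply(records, function(r) {
    if (is.null(r$phenotype_flags)) return(NULL)
    cbind(data.frame(simulation_id = r$simulation_id),
          as.data.frame(t(unclass(r$phenotype_flags))))
  }))
  if (!is.null(flags)) {
    paths[["phenotype_flags"]] <- file.path(
      dir, paste0(prefix, "phenotype_flags.tsv"))
    .write_tsv(flags, paths[["phenotype_flags"]])
  }
  invisible(paths)
}

#' Read phenotype flags from TSV
#'
#' @param path TSV with columns `simulation_id`, `dna`, `rna`, `protein`,
#'   `growth`, `division` and optionally `division_initiated`.
#' @return Named list of [phenotype_flags()] keyed by simulation id.
#' @export
read_phenotype_flags <- function(path) {
  df <- .read_tsv(path)
  needed <- c("simulation_id", "dna", "rna", "protein", "growth", "division")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_parse_error(sprintf("phenotype flags lack columns: %s",
                             paste(missing, collapse = ", ")))
  }
  if (!"division_initiated" %in% names(df)) {
    df$division_initiated <- df$division
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    phenotype_flags(as.logical(df$dna[i]), as.logical(df$rna[i]),
                    as.logical(df$protein[i]), as.logical(df$growth[i]),
                    as.logical(df$division[i]),
                    as.logical(df$division_initiated[i]))
  })
  stats::setNames(out, df$simulation_id)
}

#' Write a stoichiometric matrix as TSV
#'
#' First column `metabolite_id`, remaining columns one per reaction id,
#' integer coefficients.
#'
#' @param S Stoichiometric matrix with dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_stoichiometric_matrix <- function(S, path) {
  df <- data.frame(metabolite_id = rownames(S), as.data.frame(S),
                   check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a stoichiometric matrix from TSV
#'
#' @param path TSV written by [write_stoichiometric_matrix()].
#' @return Integer matrix with metabolite row names and reaction column
#'   names.
#' @export
read_stoichiometric_matrix <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1L] != "metabolite_id") {
    stop_parse_error("first column must be 'metabolite_id'")
  }
  S <- as.matrix(df[, -1L, drop = FALSE])
  rownames(S) <- df$metabolite_id
  if (any(is.na(suppressWarnings(as.numeric(S))))) {
    stop_parse_error("non-numeric stoichiometric coefficients")
  }
  storage.mode(S) <- "integer"
  S
}

#' Serialise boundaries to YAML for audit
#'
#' @param boundaries Named list (reaction -> scheme -> `flux_boundary`).
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_boundaries_yaml <- function(boundaries, path) {
  ser <- lapply(boundaries, function(per_reaction) {
    lapply(per_reaction, function(b) {
      list(scheme = b$scheme, lower = as.numeric(b$lower),
           upper = as.numeric(b$upper))
    })
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Export a reaction graph to GraphML and an edge-list TSV
#'
#' @param adjacency Reaction adjacency matrix (dimnames = reaction ids).
#' @param graphml_path Output GraphML path (skipped if `NULL`).
#' @param edges_path Output edge-list TSV path (skipped if `NULL`).
#' @return Invisibly, the igraph graph.
#' @export
export_reaction_graph <- function(adjacency, graphml_path = NULL,
                                  edges_path = NULL) {
  gr <- igraph::graph_from_adjacency_matrix(as.matrix(adjacency),
                                            mode = "undirected")
  if (!is.null(graphml_path)) {
    igraph::write_graph(gr, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(gr)
    .write_tsv(data.frame(from = el[, 1L], to = el[, 2L]), edges_path)
  }
  invisible(gr)
}
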