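## Synthetic flux-ensemble generator.
##
## Emulates the behavioural variety of metabolic fluxes in a stochastic
## whole-cell model: steady, ramping, oscillatory, stepping and bursting
## trajectories, with per-simulation parameter jitter standing in for the
## model's stochastic initial conditions. Knockout ensembles perturb a known
## subset of reactions so that downstream stages can be scored against ground
## truth.

#' Describe the wild-type behaviour of one reaction flux
#'
#' An archetype fixes the generative law of a reaction's flux trajectory:
#' the behavioural kind plus its parameters, all in flux units (slope in flux
#' units per second, period in seconds).
#'
#' @param reaction_id Reaction identifier (opaque string; transport reactions
#'   use the `"TX_"` prefix by convention).
#' @param kind One of `"steady"`, `"ramp"`, `"oscillation"`, `"step"`,
#'   `"burst"`.
#' @param baseline Baseline flux level.
#' @param slope Linear drift, flux units per second (used by `"ramp"`).
#' @param amplitude Oscillation/step/pulse height (ignored by `"steady"` and
#'   `"ramp"`).
#' @param period Oscillation period in seconds; must be positive for
#'   `kind = "oscillation"`. Also used as the pulse width for `"burst"`.
#' @param noise_sd Standard deviation of additive white noise; non-negative.
#' @return An object of class `reaction_archetype`.
#' @export
reaction_archetype <- function(reaction_id,
                               kind = c("steady", "ramp", "oscillation",
                                        "step", "burst"),
                               baseline = 0, slope = 0, amplitude = 0,
                               period = NA_real_, noise_sd = 0) {
  kind <- match.arg(kind)
  if (!is.character(reaction_id) || length(reaction_id) != 1L ||
      !nzchar(reaction_id)) {
    stop_invalid_argument("reaction_id must be a non-empty string")
  }
  if (noise_sd < 0) stop_invalid_argument("noise_sd must be >= 0")
  if (kind == "oscillation" && (is.na(period) || period <= 0)) {
    stop_invalid_argument("oscillation archetypes need period > 0")
  }
  structure(
    list(reaction_id = reaction_id, kind = kind, baseline = baseline,
         slope = slope, amplitude = amplitude, period = period,
         noise_sd = noise_sd),
    class = "reaction_archetype"
  )
}

#' Describe how a knockout perturbs one reaction
#'
#' `effect_size` is dimensionless: the shift is `effect_size` times the scale
#' of the targeted wild-type parameter, so `effect_size = 1` is a shift
#' comparable to the parameter itself and `effect_size >= 5` is a drastic
#' disruption. `collapse_to_zero` forces the whole trajectory to zero and
#' ignores `effect_size`.
#'
#' @param reaction_id Reaction to perturb.
#' @param mode One of `"slope_shift"`, `"amplitude_shift"`, `"offset_shift"`,
#'   `"collapse_to_zero"`.
#' @param effect_size Non-negative multiplier of the wild-type parameter
#'   scale.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(reaction_id,
                              mode = c("slope_shift", "amplitude_shift",
                                       "offset_shift", "collapse_to_zero"),
                              effect_size = 1) {
  mode <- match.arg(mode)
  if (effect_size < 0) stop_invalid_argument("effect_size must be >= 0")
  structure(
    list(reaction_id = reaction_id, mode = mode, effect_size = effect_size),
    class = "perturbation_spec"
  )
}

## Time grid: uniform, dt_s .. duration_s. 50,000 s at dt 100 s gives the
## 500-point desk-scale default used throughout the tests.
.time_grid <- function(duration_s, dt_s) {
  if (duration_s <= 0 || dt_s <= 0) {
    stop_invalid_argument("duration_s and dt_s must be positive")
  }
  dt_s * seq_len(max(1L, floor(duration_s / dt_s)))
}

## Simulate one reaction's trajectory from (possibly jittered/perturbed)
## parameters. Bursts are Poisson-timed rectangular pulses.
.simulate_series <- function(par, time_s) {
  n <- length(time_s)
  base <- par$baseline + par$slope * time_s
  y <- switch(par$kind,
    steady = base,
    ramp = base,
    oscillation = base +
      par$amplitude * sin(2 * pi * time_s / par$period + par$phase),
    step = base + ifelse(time_s > par$step_time, par$amplitude, 0),
    burst = {
      y0 <- base
      if (par$n_pulses > 0L) {
        width <- if (is.finite(par$period) && par$period > 0) par$period
                 else diff(range(time_s)) / 25
        for (s in par$pulse_starts) {
          y0 <- y0 + par$amplitude * (time_s >= s & time_s < s + width)
        }
      }
      y0
    }
  )
  if (par$noise_sd > 0) y <- y + stats::rnorm(n, sd = par$noise_sd)
  if (isTRUE(par$collapse)) y <- rep(0, n)
  data.frame(time_s = time_s, flux = y)
}

## Draw per-simulation parameters for one archetype: multiplicative jitter on
## baseline/slope/amplitude plus the stochastic elements of each kind. RNG
## draws happen in a fixed order so ensembles are seed-reproducible.
.draw_sim_parameters <- function(arch, duration_s, jitter) {
  jit <- function(x) x * (1 + stats::runif(1L, -jitter, jitter))
  par <- list(
    kind = arch$kind,
    baseline = jit(arch$baseline),
    slope = jit(arch$slope),
    amplitude = jit(arch$amplitude),
    period = arch$period,
    noise_sd = arch$noise_sd,
    phase = stats::runif(1L, 0, 2 * pi),
    step_time = duration_s * stats::runif(1L, 0.4, 0.6),
    collapse = FALSE
  )
  par$n_pulses <- stats::rpois(1L, 3)
  par$pulse_starts <- sort(stats::runif(par$n_pulses, 0, duration_s))
  par
}

## Scale of each perturbable parameter, used to convert the dimensionless
## effect size into flux units. Floored so a perturbation never vanishes on
## an all-zero archetype.
.perturbation_scales <- function(arch, duration_s) {
  tiny <- 1e-6
  list(
    slope = max(abs(arch$slope),
                (abs(arch$baseline) + abs(arch$amplitude) + arch$noise_sd) /
                  duration_s, tiny / duration_s),
    offset = max(abs(arch$baseline), abs(arch$amplitude), arch$noise_sd, tiny),
    amplitude = max(abs(arch$amplitude), arch$noise_sd,
                    0.25 * abs(arch$baseline), tiny)
  )
}

.apply_perturbation <- function(par, pert, scales) {
  switch(pert$mode,
    slope_shift = { par$slope <- par$slope + pert$effect_size * scales$slope },
    offset_shift = {
      par$baseline <- par$baseline + pert$effect_size * scales$offset
    },
    amplitude_shift = {
      par$amplitude <- par$amplitude + pert$effect_size * scales$amplitude
    },
    collapse_to_zero = { par$collapse <- TRUE }
  )
  par
}

.check_archetypes <- function(archetypes) {
  if (!length(archetypes)) {
    stop_invalid_argument("need at least one reaction archetype")
  }
  ids <- vapply(archetypes, function(a) a$reaction_id, character(1L))
  if (anyDuplicated(ids)) {
    stop_invalid_argument("duplicate reaction ids in archetypes")
  }
  stats::setNames(archetypes, ids)
}

.make_record <- function(simulation_id, genotype, archetypes, time_s,
                         duration_s, jitter, perturbations = list(),
                         phenotype = NULL) {
  pert_by_reaction <- split(
    perturbations,
    vapply(perturbations, function(p) p$reaction_id, character(1L))
  )
  series <- vector("list", length(archetypes))
  names(series) <- names(archetypes)
  labels <- stats::setNames(rep(LABEL_NORMAL, length(archetypes)),
                            names(archetypes))
  for (rid in names(archetypes)) {
    par <- .draw_sim_parameters(archetypes[[rid]], duration_s, jitter)
    for (p in pert_by_reaction[[rid]]) {
      par <- .apply_perturbation(
        par, p, .perturbation_scales(archetypes[[rid]], duration_s))
      labels[[rid]] <- LABEL_ABNORMAL
    }
    series[[rid]] <- .simulate_series(par, time_s)
  }
  structure(
    list(simulation_id = simulation_id, genotype = genotype, series = series,
         truth_labels = labels,
         phenotype_flags = if (is.null(phenotype)) NULL
                           else flags_for_class(phenotype),
         phenotype_class = phenotype),
    class = "simulation_record"
  )
}

#' Generate a wild-type flux ensemble
#'
#' Simulates `n_sims` wild-type cells: every reaction follows its archetype
#' with per-simulation parameter jitter (emulating the whole-cell model's
#' stochasticity), and every truth label is `"normal"`. A fixed seed gives a
#' bit-identical ensemble.
#'
#' @param archetypes List of [reaction_archetype()] objects with unique ids.
#' @param n_sims Number of simulations (may be zero).
#' @param duration_s Total simulated time in seconds (default 50,000).
#' @param dt_s Time step in seconds (default 100, i.e. 500 points).
#' @param seed Integer RNG seed.
#' @param jitter Relative per-simulation jitter applied to baseline, slope and
#'   amplitude (default 0.1 = +/-10%).
#' @return List of `simulation_record` objects.
#' @export
generate_wildtype_ensemble <- function(archetypes, n_sims,
                                       duration_s = 50000, dt_s = 100,
                                       seed = 1L, jitter = 0.1) {
  archetypes <- .check_archetypes(archetypes)
  if (n_sims < 0) stop_invalid_argument("n_sims must be >= 0")
  time_s <- .time_grid(duration_s, dt_s)
  if (n_sims == 0L) return(list())
  set.seed(seed)
  lapply(seq_len(n_sims), function(i) {
    .make_record(sprintf("WT_%04d", i), "wild_type", archetypes, time_s,
                 duration_s, jitter)
  })
}

#' Generate a gene-knockout flux ensemble
#'
#' Simulates `n_sims` knockout cells of one phenotypic class: the listed
#' perturbations are applied on top of the jittered wild-type parameters, the
#' perturbed reactions carry `"abnormal"` truth labels, and every record's
#' phenotype flags are the flag combination of `phenotype_class`.
#'
#' @inheritParams generate_wildtype_ensemble
#' @param phenotype_class Phenotypic class of the knockout (see
#'   [classify_phenotype()]).
#' @param perturbations List of [perturbation_spec()] objects; every target
#'   must be present in `archetypes`.
#' @param genotype Knocked-out gene identifier (free string).
#' @return List of `simulation_record` objects.
#' @export
generate_knockout_ensemble <- function(archetypes, phenotype_class,
                                       perturbations, n_sims,
                                       duration_s = 50000, dt_s = 100,
                                       seed = 1L, jitter = 0.1,
                                       genotype = paste0("KO_",
                                                         phenotype_class)) {
  archetypes <- .check_archetypes(archetypes)
  phenotype_class <- match.arg(phenotype_class, PHENOTYPE_CLASSES)
  if (n_sims < 0) stop_invalid_argument("n_sims must be >= 0")
  targets <- vapply(perturbations, function(p) p$reaction_id, character(1L))
  missing <- setdiff(targets, names(archetypes))
  if (length(missing)) {
    stop_key_not_found(sprintf(
      "perturbation targets not in archetypes: %s",
      paste(missing, collapse = ", ")))
  }
  time_s <- .time_grid(duration_s, dt_s)
  if (n_sims == 0L) return(list())
  set.seed(seed)
  lapply(seq_len(n_sims), function(i) {
    .make_record(sprintf("%s_%04d", genotype, i), genotype, archetypes,
                 time_s, duration_s, jitter, perturbations, phenotype_class)
  })
}

#' Generate a random stoichiometric matrix
#'
#' Builds a metabolites-by-reactions matrix of signed integer coefficients.
#' Internal reactions (`"R_"` prefix) touch about `connectivity` internal
#' metabolites; transport reactions (`"TX_"` prefix) exchange exactly one
#' internal metabolite with a dedicated boundary metabolite (`"BND_"` row).
#' Boundary metabolites are included as matrix rows, so the matrix has
#' `n_metabolites + n_transport_reactions` rows.
#'
#' @param n_metabolites Number of internal metabolites.
#' @param n_internal_reactions Number of internal reactions.
#' @param n_transport_reactions Number of transport reactions.
#' @param connectivity Mean number of metabolites touched per internal
#'   reaction; must be >= 1.
#' @param seed Integer RNG seed.
#' @return Integer matrix with metabolite row names and reaction column
#'   names.
#' @export
generate_stoichiometric_matrix <- function(n_metabolites,
                                           n_internal_reactions,
                                           n_transport_reactions,
                                           connectivity = 3, seed = 1L) {
  if (n_metabolites < 0 || n_internal_reactions < 0 ||
      n_transport_reactions < 0) {
    stop_invalid_argument("counts must be >= 0")
  }
  if (connectivity < 1) stop_invalid_argument("connectivity must be >= 1")
  if ((n_internal_reactions > 0 || n_transport_reactions > 0) &&
      n_metabolites < 1) {
    stop_invalid_argument("reactions need at least one internal metabolite")
  }
  set.seed(seed)
  met_ids <- sprintf("MET_%03d", seq_len(n_metabolites))
  bnd_ids <- sprintf("BND_%03d", seq_len(n_transport_reactions))
  rxn_ids <- c(sprintf("R_%03d", seq_len(n_internal_reactions)),
               sprintf("TX_%03d", seq_len(n_transport_reactions)))
  S <- matrix(0L, nrow = n_metabolites + n_transport_reactions,
              ncol = length(rxn_ids),
              dimnames = list(c(met_ids, bnd_ids), rxn_ids))
  for (j in seq_len(n_internal_reactions)) {
    k <- min(n_metabolites, max(1L, 1L + stats::rpois(1L, connectivity - 1)))
    rows <- sample.int(n_metabolites, k)
    S[rows, j] <- sample(c(-2L, -1L, 1L, 2L), k, replace = TRUE)
  }
  for (t in seq_len(n_transport_reactions)) {
    j <- n_internal_reactions + t
    S[sample.int(n_metabolites, 1L), j] <- 1L
    S[n_metabolites + t, j] <- -1L
  }
  S
}

#' Plant an isolated transport marker reaction into a stoichiometric matrix
#'
#' Adds one transport reaction whose internal metabolite is touched by no
#' other reaction, so the reaction shares no metabolite with the rest of the
#' network and is isolated in the derived reaction graph. Isolated nodes are
#' always driver nodes, which makes this the canonical fixture for planting a
#' guaranteed driver/marker reaction in synthetic studies.
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @param reaction_id Identifier of the planted transport reaction; should
#'   carry the `"TX_"` prefix so transport statistics count it.
#' @return The extended stoichiometric matrix.
#' @export
plant_marker_transport <- function(S, reaction_id = "TX_MARK") {
  if (reaction_id %in% colnames(S)) {
    stop_invalid_argument(sprintf("reaction %s already present", reaction_id))
  }
  met <- paste0("MET_", reaction_id)
  bnd <- paste0("BND_", reaction_id)
  S2 <- rbind(S, matrix(0L, 2L, ncol(S), dimnames = list(c(met, bnd), NULL)))
  col <- matrix(0L, nrow(S2), 1L,
                dimnames = list(rownames(S2), reaction_id))
  col[met, 1L] <- 1L
  col[bnd, 1L] <- -1L
  cbind(S2, col)
}
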