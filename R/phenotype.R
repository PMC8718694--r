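## Phenotypic classes of a knockout simulation, following the whole-cell
## model convention: a simulation is classed by which essential productions
## (DNA, RNA, protein), growth and division it still achieves. The printed
## flag rows for "slow_growing" and "septum" are identical; they are
## distinguished by whether division was *initiated* before the end of the
## simulation (slow growing cells begin but do not complete division).

PHENOTYPE_CLASSES <- c(
  "metabolic", "rna", "protein", "slow_growing", "dna", "septum",
  "non_essential"
)

## class -> (dna, rna, protein, growth, division, division_initiated)
.phenotype_table <- function() {
  rbind(
    metabolic     = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    rna           = c(TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE),
    protein       = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
    slow_growing  = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, TRUE),
    dna           = c(FALSE, TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    septum        = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    non_essential = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE)
  )
}

#' Construct a set of phenotype production flags
#'
#' Boolean production/behaviour flags for one simulation: whether DNA, RNA and
#' protein were actively produced, whether the cell grew, and whether it
#' divided. `division_initiated` is an auxiliary flag separating slow-growing
#' cells (division begins at the end of the simulation but does not complete)
#' from septum-disrupted cells (division never begins); completed division
#' implies initiated division.
#'
#' @param dna,rna,protein,growth,division Logical scalars.
#' @param division_initiated Logical scalar; must be `TRUE` when `division`
#'   is `TRUE`.
#' @return An object of class `phenotype_flags` (a named logical vector).
#' @export
phenotype_flags <- function(dna, rna, protein, growth, division,
                            division_initiated = division) {
  flags <- c(
    dna = dna, rna = rna, protein = protein, growth = growth,
    division = division, division_initiated = division_initiated
  )
  if (!is.logical(flags) || anyNA(flags) || length(flags) != 6L) {
    stop_invalid_argument("phenotype flags must be six non-missing logicals")
  }
  if (flags[["division"]] && !flags[["division_initiated"]]) {
    stop_invalid_argument("completed division implies initiated division")
  }
  structure(flags, class = "phenotype_flags")
}

#' Flags implied by a phenotypic class
#'
#' Inverse of [classify_phenotype()]: the production-flag combination that a
#' given phenotypic class carries. Used by the synthetic-data generator to
#' emit flags consistent with a requested class.
#'
#' @param class One of `"metabolic"`, `"rna"`, `"protein"`, `"slow_growing"`,
#'   `"dna"`, `"septum"`, `"non_essential"`.
#' @return A [phenotype_flags()] object.
#' @export
flags_for_class <- function(class) {
  class <- match.arg(class, PHENOTYPE_CLASSES)
  row <- .phenotype_table()[class, ]
  phenotype_flags(row[1L], row[2L], row[3L], row[4L], row[5L], row[6L])
}

#' Classify a simulation's phenotype from its production flags
#'
#' Maps the five production/behaviour flags (plus the auxiliary
#' `division_initiated` flag) to the phenotypic class they imply:
#' no production at all is a metabolic disruption; progressively restored
#' production moves through RNA, protein, DNA, slow-growing and septum
#' disruptions; full production with completed division is non-essential.
#' Flag combinations outside the handled table raise an error of class
#' `wcflux_unclassified_phenotype` rather than guessing.
#'
#' @param flags A [phenotype_flags()] object.
#' @return A single string, one of the phenotypic classes.
#' @export
#' @examples
#' classify_phenotype(phenotype_flags(TRUE, TRUE, TRUE, TRUE, TRUE))
classify_phenotype <- function(flags) {
  if (!inherits(flags, "phenotype_flags")) {
    flags <- do.call(phenotype_flags, as.list(flags))
  }
  tab <- .phenotype_table()
  key <- unclass(flags)[c("dna", "rna", "protein", "growth", "division")]
  hits <- which(apply(tab[, 1:5, drop = FALSE], 1L,
                      function(row) all(row == key)))
  if (length(hits) == 0L) {
    stop_unclassified_phenotype(sprintf(
      "flag combination (%s) is not a handled phenotypic class",
      paste(ifelse(key, "yes", "no"), collapse = ", ")
    ))
  }
  classes <- rownames(tab)[hits]
  if (length(classes) == 1L) {
    return(classes)
  }
  ## slow_growing and septum share printed flags; the auxiliary flag decides
  if (flags[["division_initiated"]]) "slow_growing" else "septum"
}
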