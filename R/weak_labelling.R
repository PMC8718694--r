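## Weak labelling: wild-type boundaries in the 2-D feature space act as
## labelling functions, and a simplified generative label model combines
## their votes into probabilistic normal/abnormal labels.

BOUNDARY_SCHEMES <- c("extrema", "ci99", "ci95")

#' Build a wild-type boundary in principal-component space
#'
#' Axis-aligned rectangular boundary around the wild-type scores of one
#' reaction. `"extrema"` is the bounding box of all points; `"ci99"` and
#' `"ci95"` are per-axis empirical percentile boxes (`[0.5, 99.5]` and
#' `[2.5, 97.5]` percentiles respectively, type-7 quantiles). Percentile
#' boxes are per-axis by construction, not bivariate regions.
#'
#' @param wildtype_scores Numeric matrix (n x 2) of wild-type PC scores,
#'   n >= 3.
#' @param scheme One of `"extrema"`, `"ci99"`, `"ci95"`.
#' @return An object of class `flux_boundary` with per-axis `lower` and
#'   `upper` limits.
#' @export
build_boundary <- function(wildtype_scores, scheme = BOUNDARY_SCHEMES) {
  scheme <- match.arg(scheme)
  X <- as.matrix(wildtype_scores)
  if (nrow(X) < 3L) {
    stop_insufficient_reference("need >= 3 wild-type points for a boundary")
  }
  probs <- switch(scheme,
    extrema = c(0, 1),
    ci99 = c(0.005, 0.995),
    ci95 = c(0.025, 0.975)
  )
  lim <- apply(X, 2L, function(v) {
    if (scheme == "extrema") range(v)
    else stats::quantile(v, probs, names = FALSE, type = 7)
  })
  structure(
    list(scheme = scheme, lower = lim[1L, ], upper = lim[2L, ]),
    class = "flux_boundary"
  )
}

#' Apply one boundary labelling function to scores
#'
#' A point is `"normal"` iff it lies inside or on the closed box on every
#' axis; anything outside the boundary is `"abnormal"`. Edge points count as
#' normal (ties broken toward normal).
#'
#' @param boundary A [build_boundary()] object.
#' @param score Numeric 2-vector or n x 2 matrix of PC coordinates.
#' @return Character vector of `"normal"` / `"abnormal"`, one per row.
#' @export
apply_labelling_function <- function(boundary, score) {
  X <- if (is.null(dim(score))) matrix(score, nrow = 1L) else as.matrix(score)
  inside <- rep(TRUE, nrow(X))
  for (j in seq_along(boundary$lower)) {
    inside <- inside & X[, j] >= boundary$lower[j] &
      X[, j] <= boundary$upper[j]
  }
  ifelse(inside, LABEL_NORMAL, LABEL_ABNORMAL)
}

#' Build the label matrix of the three boundary labelling functions
#'
#' @param boundaries Named list of [build_boundary()] objects (one per
#'   scheme).
#' @param scores n x 2 score matrix of the simulations to label.
#' @return Character matrix, simulations x labelling functions.
#' @export
label_matrix <- function(boundaries, scores) {
  L <- vapply(boundaries, apply_labelling_function,
              character(nrow(as.matrix(scores))), score = scores)
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L,
                                   dimnames = list(NULL, names(boundaries)))
  rownames(L) <- rownames(scores)
  L
}

#' Combine labelling-function votes into probabilistic weak labels
#'
#' A simplified generative label model: each labelling function's accuracy is
#' estimated by its mean pairwise agreement rate with the other functions,
#' the functions vote with those accuracies as weights, and the emitted
#' label is the one with the larger weighted vote mass (ties broken by
#' unit-weight majority, then toward normal). The label's probability is its
#' normalised weighted vote mass, so unanimity gives probability 1 and the
#' probability always lies in [0.5, 1].
#'
#' @param L Character matrix of `"normal"`/`"abnormal"`, simulations x
#'   labelling functions (no abstentions).
#' @return Data frame with columns `label` and `probability`.
#' @export
combine_labels <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) < 1L) stop_invalid_argument("label matrix needs >= 1 row")
  if (anyNA(L) || !all(L %in% c(LABEL_NORMAL, LABEL_ABNORMAL))) {
    stop_invalid_argument("labels must be 'normal' or 'abnormal'")
  }
  m <- ncol(L)
  if (m == 1L) {
    return(data.frame(label = unname(L[, 1L]), probability = 1))
  }
  ## pairwise agreement -> per-function accuracy proxy
  agree <- matrix(1, m, m)
  for (j in seq_len(m - 1L)) {
    for (k in (j + 1L):m) {
      a <- mean(L[, j] == L[, k])
      agree[j, k] <- a
      agree[k, j] <- a
    }
  }
  w <- vapply(seq_len(m), function(j) mean(agree[j, -j]), numeric(1L))
  if (all(w == 0)) w <- rep(1, m)
  abn <- (L == LABEL_ABNORMAL) + 0
  mass_abn <- drop(abn %*% w)
  mass_nrm <- sum(w) - mass_abn
  label <- ifelse(mass_abn > mass_nrm, LABEL_ABNORMAL, LABEL_NORMAL)
  tie <- mass_abn == mass_nrm
  if (any(tie)) {
    votes_abn <- rowSums(abn[tie, , drop = FALSE])
    label[tie] <- ifelse(votes_abn > m / 2, LABEL_ABNORMAL, LABEL_NORMAL)
  }
  prob <- pmax(mass_abn, mass_nrm) / sum(w)
  prob[tie] <- 0.5
  data.frame(label = label, probability = prob)
}

#' Weakly label one reaction across an ensemble
#'
#' Convenience wrapper running the whole labelling stage for one reaction:
#' PCA of the pooled feature vectors, boundaries from the wild-type subset,
#' the three labelling functions, and the label-model combination.
#'
#' @param scores n x 2 PC score matrix of all simulations of one reaction.
#' @param wildtype Logical vector marking which rows are wild-type.
#' @param schemes Boundary schemes to use (default all three).
#' @return List with `boundaries`, `label_matrix` and `weak_labels` (the
#'   [combine_labels()] data frame, with simulation rownames preserved).
#' @export
weak_label_reaction <- function(scores, wildtype,
                                schemes = BOUNDARY_SCHEMES) {
  scores <- as.matrix(scores)
  if (length(wildtype) != nrow(scores)) {
    stop_invalid_argument("wildtype flag length must match score rows")
  }
  boundaries <- lapply(stats::setNames(schemes, schemes), function(s) {
    build_boundary(scores[wildtype, , drop = FALSE], s)
  })
  L <- label_matrix(boundaries, scores)
  wl <- combine_labels(L)
  rownames(wl) <- rownames(scores)
  list(boundaries = boundaries, label_matrix = L, weak_labels = wl)
}

#' @export
print.flux_boundary <- function(x, ...) {
  cat(sprintf("Boundary [%s]: x in [%.4g, %.4g], y in [%.4g, %.4g]\n",
              x$scheme, x$lower[1L], x$upper[1L], x$lower[2L], x$upper[2L]))
  invisible(x)
}
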