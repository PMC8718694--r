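## Phenotype-marker analysis: flux-profile PCA, linear-SVM separability of a
## reaction's normality in the 2-D profile space, phi coefficients between
## reaction behaviour and phenotypic classes, and the consolidated marker
## table for driver reactions.

#' Reduce flux profiles to principal components
#'
#' Centred PCA of the raw 0/1 profile matrix. Bits share a scale, so no
#' standardisation is applied. An all-identical profile matrix has zero
#' variance; it yields all-zero scores with a warning.
#'
#' @param profile_matrix Integer 0/1 matrix, simulations x reactions
#'   (>= 2 simulations).
#' @param n_components Number of retained components (default 2).
#' @return A `reduced_scores` object (see [reduce_features()]).
#' @export
reduce_profiles <- function(profile_matrix, n_components = 2L) {
  P <- as.matrix(profile_matrix)
  if (nrow(P) < 2L) {
    stop_invalid_argument("profile PCA needs >= 2 simulations")
  }
  .pca_core(P, n_components, scale = FALSE)
}

#' Linear-SVM separability of one reaction's normality
#'
#' Fits a linear-kernel maximum-margin classifier (cost = 1) on the 2-D
#' profile scores against the reaction's normal/abnormal bits and evaluates
#' accuracy on the fitted points themselves (the question is whether the
#' plotted data are linearly separable, not held-out generalisation). The
#' reaction passes when that accuracy exceeds 0.95.
#'
#' @param scores Numeric matrix, simulations x 2, of profile PC scores.
#' @param reaction_normality Integer/logical vector of abnormality bits
#'   (1/TRUE = abnormal), or a character vector of `"normal"`/`"abnormal"`.
#' @param reaction_id Optional reaction identifier carried into the result.
#' @param cost Soft-margin cost parameter (default 1).
#' @return An object of class `separability_result`: `hyperplane` (weights
#'   `w` and offset `b` with decision rule `sign(x %*% w + b)`), `accuracy`,
#'   `passes`.
#' @export
svm_separability <- function(scores, reaction_normality, reaction_id = NULL,
                             cost = 1) {
  X <- as.matrix(scores)
  y <- reaction_normality
  if (is.character(y)) y <- as.integer(y == LABEL_ABNORMAL)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop_degenerate_labels("both normality classes must be present")
  }
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- as.integer(as.character(predict(fit, X)))
  accuracy <- mean(pred == y)
  ## hyperplane in the original score space, oriented so the positive side
  ## is the abnormal class: predict(x) = abnormal iff x %*% w + b > 0
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## libsvm assigns the +1 side to whichever label it saw first, so resolve
  ## the orientation against the predictions themselves
  dv <- drop(X %*% w) + b
  if (mean((dv > 0) == (pred == 1L)) < 0.5) {
    w <- -w
    b <- -b
  }
  structure(
    list(reaction_id = reaction_id, hyperplane = list(w = w, b = b),
         accuracy = accuracy, passes = accuracy > 0.95),
    class = "separability_result"
  )
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("Linear separability%s: accuracy %.3f (%s)\n",
              if (is.null(x$reaction_id)) ""
              else paste0(" of ", x$reaction_id),
              x$accuracy, if (x$passes) "passes > 0.95" else "fails"))
  invisible(x)
}

#' Phi coefficient of a 2x2 contingency table
#'
#' The Pearson correlation of two binary variables:
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))` for the table
#' `rbind(c(a, b), c(c, d))`. Any zero margin leaves the statistic
#' undefined and raises a `wcflux_undefined_statistic` error.
#'
#' @param table 2x2 numeric matrix of non-negative counts, or the count `a`
#'   when `b`, `c`, `d` are given separately.
#' @param b,c,d Remaining counts when `table` is given as `a`.
#' @return Phi in [-1, 1].
#' @export
#' @examples
#' phi_coefficient(rbind(c(10, 0), c(0, 10)))
phi_coefficient <- function(table, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.null(b)) as.matrix(table) else rbind(c(table, b), c(c, d))
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop_invalid_argument("need a 2x2 table of non-negative counts")
  }
  a <- tab[1L, 1L]; bb <- tab[1L, 2L]; cc <- tab[2L, 1L]; dd <- tab[2L, 2L]
  margins <- c(a + bb, cc + dd, a + cc, bb + dd)
  if (any(margins == 0)) {
    stop_undefined_statistic("phi undefined: a table margin is zero")
  }
  (a * dd - bb * cc) / sqrt(prod(margins))
}

## 2x2 table of (abnormal bit) x (in-class indicator): positive phi means
## abnormality of the reaction associates with membership of the class.
.abnormality_class_table <- function(bits, in_class) {
  rbind(
    c(sum(bits == 1L & in_class), sum(bits == 1L & !in_class)),
    c(sum(bits == 0L & in_class), sum(bits == 0L & !in_class))
  )
}

#' Phi coefficients between reaction abnormality and phenotypic classes
#'
#' For every reaction (column of the profile matrix) and every phenotypic
#' class, computes the phi coefficient between the reaction's abnormality bit
#' and class membership. Undefined cells (zero margins) are `NA`.
#'
#' @param profiles Integer 0/1 matrix, simulations x reactions.
#' @param classes Character/factor of phenotypic class per simulation.
#' @return Numeric matrix, reactions x classes.
#' @export
phi_by_class <- function(profiles, classes) {
  P <- as.matrix(profiles)
  classes <- as.character(classes)
  if (length(classes) != nrow(P)) {
    stop_invalid_argument("one class per profile row required")
  }
  cls <- unique(classes)
  out <- matrix(NA_real_, ncol(P), length(cls),
                dimnames = list(colnames(P), cls))
  for (k in cls) {
    inc <- classes == k
    for (r in seq_len(ncol(P))) {
      out[r, k] <- tryCatch(
        phi_coefficient(.abnormality_class_table(P[, r], inc)),
        wcflux_undefined_statistic = function(e) NA_real_)
    }
  }
  out
}

#' Consolidated marker table for driver reactions
#'
#' One row per driver reaction: its pathways, whether a linear SVM separates
#' its normality in the 2-D profile space with > 95% accuracy, and the
#' phenotypic class its abnormality correlates with most strongly (largest
#' absolute phi), with that signed phi.
#'
#' @param driver_set A [find_driver_nodes()] result.
#' @param separability Named list of [svm_separability()] results (by
#'   reaction id); drivers without an entry get `NA`.
#' @param phi_matrix Reactions x classes phi matrix from [phi_by_class()].
#' @param annotations Optional [annotate_pathways()] data frame.
#' @return Data frame with columns `reaction_id`, `pathways`, `separable`,
#'   `separability_accuracy`, `best_class`, `phi`, sorted by reaction id.
#' @export
marker_report <- function(driver_set, separability = list(),
                          phi_matrix = NULL, annotations = NULL) {
  drivers <- sort(driver_set$drivers)
  if (!length(drivers)) {
    return(data.frame(reaction_id = character(), pathways = character(),
                      separable = logical(),
                      separability_accuracy = numeric(),
                      best_class = character(), phi = numeric()))
  }
  path_lookup <- if (is.null(annotations)) NULL
                 else stats::setNames(annotations$pathways,
                                      annotations$reaction_id)
  rows <- lapply(drivers, function(rid) {
    sep <- separability[[rid]]
    best_class <- NA_character_
    phi <- NA_real_
    if (!is.null(phi_matrix) && rid %in% rownames(phi_matrix)) {
      v <- phi_matrix[rid, ]
      if (any(!is.na(v))) {
        best_class <- names(v)[which.max(abs(v))]
        phi <- unname(v[best_class])
      }
    }
    data.frame(
      reaction_id = rid,
      pathways = if (is.null(path_lookup)) NA_character_
                 else unname(path_lookup[rid] %||% NA_character_),
      separable = if (is.null(sep)) NA else sep$passes,
      separability_accuracy = if (is.null(sep)) NA_real_ else sep$accuracy,
      best_class = best_class, phi = phi
    )
  })
  do.call(rbind, rows)
}
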