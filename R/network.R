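## Reaction-network analysis: the reaction-reaction graph A = S^T S from the
## binarised stoichiometric matrix, driver nodes from a matching, the
## exponential wild-type noise threshold, per-class affected sub-networks
## and offline pathway annotation.

#' Derive the reaction adjacency matrix from a stoichiometric matrix
#'
#' Binarises the stoichiometric matrix entrywise (any non-zero coefficient
#' counts), forms the reaction-by-reaction product of the binarised matrix
#' with itself, binarises again and zeroes the diagonal. The result connects
#' two reactions exactly when they share at least one metabolite
#' (substrates are the edges of the reaction graph). Self-sharing carries no
#' information for matchings, hence the zero diagonal.
#'
#' @param S Numeric matrix, metabolites x reactions, with reaction column
#'   names.
#' @return Symmetric 0/1 integer matrix over reactions with zero diagonal.
#' @export
adjacency_from_stoichiometry <- function(S) {
  S <- as.matrix(S)
  if (length(S) == 0L || ncol(S) == 0L) {
    stop_invalid_argument("stoichiometric matrix is empty")
  }
  B <- (S != 0) * 1
  A <- (crossprod(B) > 0) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}

## ---- maximum matching (blossom / Edmonds) --------------------------------
## General-graph maximum-cardinality matching via augmenting-path search
## with blossom contraction; O(V^3). Returns an integer vector `match` with
## match[v] = partner of v, or 0 if v is unmatched.
.blossom_matching <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(integer(0))
  g <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  match <- rep(0L, n)
  p <- rep(0L, n)
  base <- seq_len(n)
  blossom <- rep(FALSE, n)

  lca <- function(a, b) {
    seen <- rep(FALSE, n)
    a0 <- a
    repeat {
      a0 <- base[a0]
      seen[a0] <- TRUE
      if (match[a0] == 0L) break
      a0 <- p[match[a0]]
    }
    b0 <- b
    repeat {
      b0 <- base[b0]
      if (seen[b0]) return(b0)
      b0 <- p[match[b0]]
    }
  }

  mark_path <- function(v, b, child) {
    while (base[v] != b) {
      blossom[base[v]] <<- TRUE
      blossom[base[match[v]]] <<- TRUE
      p[v] <<- child
      child <- match[v]
      v <- p[match[v]]
    }
  }

  find_path <- function(root) {
    used <- rep(FALSE, n)
    p[] <<- 0L
    base <<- seq_len(n)
    used[root] <- TRUE
    queue <- c(root)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (to in g[[v]]) {
        if (base[v] == base[to] || match[v] == to) next
        if (to == root || (match[to] != 0L && p[match[to]] != 0L)) {
          ## odd cycle: contract the blossom
          curbase <- lca(v, to)
          blossom <<- rep(FALSE, n)
          mark_path(v, curbase, to)
          mark_path(to, curbase, v)
          for (i in seq_len(n)) {
            if (blossom[base[i]]) {
              base[i] <<- curbase
              if (!used[i]) {
                used[i] <- TRUE
                queue <- c(queue, i)
              }
            }
          }
        } else if (p[to] == 0L) {
          p[to] <<- v
          if (match[to] == 0L) {
            ## augmenting path found: flip it
            u <- to
            while (u != 0L) {
              pv <- p[u]
              ppv <- match[pv]
              match[u] <<- pv
              match[pv] <<- u
              u <- ppv
            }
            return(TRUE)
          }
          used[match[to]] <- TRUE
          queue <- c(queue, match[to])
        }
      }
    }
    FALSE
  }

  for (v in seq_len(n)) {
    if (match[v] == 0L && length(g[[v]])) find_path(v)
  }
  match
}

## Greedy maximal matching over edges in lexicographic (reaction id, id)
## order: deterministic stand-in for iterating edge pairs greedily.
.greedy_matching <- function(adj) {
  n <- nrow(adj)
  ids <- rownames(adj) %||% as.character(seq_len(n))
  edges <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  if (nrow(edges)) {
    ord <- order(ids[edges[, 1L]], ids[edges[, 2L]])
    edges <- edges[ord, , drop = FALSE]
  }
  match <- rep(0L, n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]
    j <- edges[e, 2L]
    if (match[i] == 0L && match[j] == 0L) {
      match[i] <- j
      match[j] <- i
    }
  }
  match
}

#' Find the driver nodes of a reaction graph
#'
#' Computes a matching of the undirected reaction graph and returns the
#' unmatched nodes: the driver set that must be controlled to control the
#' network. The default `"maximum"` strategy uses a blossom
#' maximum-cardinality matching, giving the minimum possible driver count;
#' `"greedy_sorted"` is a deterministic greedy maximal matching over edges in
#' lexicographic reaction-id order, which can only leave the same number of
#' drivers or more. Isolated nodes are always drivers.
#'
#' @param adjacency Symmetric 0/1 matrix over reactions (zero diagonal),
#'   with reaction ids as dimnames.
#' @param strategy `"maximum"` (default) or `"greedy_sorted"`.
#' @return An object of class `driver_set`: `drivers` (character vector of
#'   reaction ids), `matching` (two-column id matrix of matched pairs) and
#'   the strategy used.
#' @export
find_driver_nodes <- function(adjacency,
                              strategy = c("maximum", "greedy_sorted")) {
  strategy <- match.arg(strategy)
  A <- as.matrix(adjacency)
  n <- nrow(A)
  ids <- rownames(A) %||% as.character(seq_len(n))
  match <- if (strategy == "maximum") .blossom_matching(A)
           else .greedy_matching(A)
  matched <- which(match != 0L)
  pairs <- matched[matched < match[matched]]
  matching <- cbind(from = ids[pairs], to = ids[match[pairs]])
  structure(
    list(drivers = ids[match == 0L], matching = matching,
         strategy = strategy, n_nodes = n),
    class = "driver_set"
  )
}

#' @export
print.driver_set <- function(x, ...) {
  cat(sprintf(
    "Driver set (%s matching): %d drivers of %d nodes; matching size %d\n",
    x$strategy, length(x$drivers), x$n_nodes, nrow(x$matching)))
  invisible(x)
}

#' Fraction of driver nodes that are transport reactions
#'
#' Transport reactions carry the `"TX_"` identifier prefix; in minimal cells
#' that import most metabolites, the driver set is typically dominated by
#' them.
#'
#' @param driver_set A [find_driver_nodes()] result.
#' @return Fraction in [0, 1] (NaN for an empty driver set).
#' @export
driver_transport_fraction <- function(driver_set) {
  mean(startsWith(driver_set$drivers, "TX_"))
}

#' Per-reaction abnormality frequencies by group
#'
#' Frequency = mean of the reaction's profile bit over the group's
#' simulations.
#'
#' @param profiles Integer 0/1 matrix, simulations x reactions.
#' @param grouping Factor/character of group membership per simulation, or
#'   `NULL` for a single group `"all"`.
#' @return Numeric matrix, groups x reactions, of frequencies in [0, 1].
#' @export
abnormality_frequencies <- function(profiles, grouping = NULL) {
  P <- as.matrix(profiles)
  if (nrow(P) == 0L) stop_invalid_argument("no profiles supplied")
  grouping <- if (is.null(grouping)) rep("all", nrow(P))
              else as.character(grouping)
  if (length(grouping) != nrow(P)) {
    stop_invalid_argument("one group per profile row required")
  }
  groups <- unique(grouping)
  out <- t(vapply(groups, function(gr) {
    colMeans(P[grouping == gr, , drop = FALSE])
  }, numeric(ncol(P))))
  if (ncol(P) == 1L) out <- matrix(out, ncol = 1L,
                                   dimnames = list(groups, colnames(P)))
  rownames(out) <- groups
  colnames(out) <- colnames(P)
  out
}

#' Wild-type noise threshold from an exponential fit
#'
#' Even wild-type simulations show occasional abnormal classifications
#' because the underlying model is stochastic. An exponential distribution is
#' fitted by maximum likelihood to the wild-type abnormality frequencies
#' (rate = 1/mean), and the frequency below which `coverage` of that
#' distribution lies is the noise threshold: group frequencies strictly above
#' it are "consistently abnormal". All-zero frequencies give a degenerate
#' fit; the threshold is then defined as 0 with a warning.
#'
#' @param wildtype_frequencies Per-reaction abnormality frequencies of the
#'   wild-type group.
#' @param coverage Distribution mass below the threshold (default 0.95).
#' @return An object of class `noise_threshold`: `rate`, `coverage`,
#'   `threshold`.
#' @export
noise_threshold <- function(wildtype_frequencies, coverage = 0.95) {
  f <- as.numeric(wildtype_frequencies)
  if (!length(f) || any(f < 0)) {
    stop_invalid_argument("frequencies must be non-negative")
  }
  if (coverage < 0 || coverage >= 1) {
    stop_invalid_argument("coverage must be in [0, 1)")
  }
  m <- mean(f)
  if (m == 0) {
    warning("all wild-type frequencies are zero: degenerate exponential fit, threshold set to 0")
    return(structure(list(rate = Inf, coverage = coverage, threshold = 0),
                     class = "noise_threshold"))
  }
  rate <- 1 / m
  structure(
    list(rate = rate, coverage = coverage,
         threshold = -log(1 - coverage) / rate),
    class = "noise_threshold"
  )
}

#' @export
print.noise_threshold <- function(x, ...) {
  cat(sprintf(
    "Exponential noise threshold: rate %.4g, %.0f%% coverage -> threshold %.4g\n",
    x$rate, 100 * x$coverage, x$threshold))
  invisible(x)
}

#' Induced sub-network of consistently abnormal reactions
#'
#' Selects the reactions whose group abnormality frequency strictly exceeds
#' the threshold and induces the subgraph of the reaction graph on them.
#' Each node is annotated with its frequency (for colour-gradient rendering
#' and export); `selected` marks the chosen nodes in tabular exports.
#'
#' @param adjacency Reaction adjacency matrix.
#' @param frequencies Named per-reaction frequencies for one group.
#' @param threshold A [noise_threshold()] object or a bare numeric
#'   threshold.
#' @return An igraph graph with vertex attributes `name` and `frequency`
#'   (possibly empty).
#' @export
class_subnetwork <- function(adjacency, frequencies, threshold) {
  thr <- if (inherits(threshold, "noise_threshold")) threshold$threshold
         else as.numeric(threshold)
  A <- as.matrix(adjacency)
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  f <- if (is.null(names(frequencies))) {
    stats::setNames(as.numeric(frequencies), ids)
  } else {
    frequencies[ids]
  }
  dimnames(A) <- list(ids, ids)
  sel <- which(as.numeric(f) > thr)
  sub <- A[sel, sel, drop = FALSE]
  gr <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  igraph::V(gr)$frequency <- as.numeric(f[sel])
  gr
}

#' Annotate driver reactions with pathways from an offline table
#'
#' Joins driver reaction ids against a reaction-to-pathway annotation table.
#' A driver with no annotation of its own inherits the union of its
#' first-degree neighbours' pathways; drivers with neither are marked
#' `"n/a"`.
#'
#' @param driver_set A [find_driver_nodes()] result.
#' @param annotation_table Data frame with columns `reaction_id` and
#'   `pathway` (one row per reaction-pathway pair; may be empty).
#' @param adjacency Optional reaction adjacency matrix enabling the
#'   neighbour fallback.
#' @return Data frame with columns `reaction_id`, `pathways` (collapsed with
#'   `"; "`), `annotated_via` (`"self"`, `"neighbour"` or `"none"`).
#' @export
annotate_pathways <- function(driver_set, annotation_table,
                              adjacency = NULL) {
  if (!is.data.frame(annotation_table) ||
      !all(c("reaction_id", "pathway") %in% names(annotation_table))) {
    stop_parse_error(
      "annotation table needs 'reaction_id' and 'pathway' columns")
  }
  lookup <- split(as.character(annotation_table$pathway),
                  as.character(annotation_table$reaction_id))
  rows <- lapply(driver_set$drivers, function(rid) {
    own <- unique(lookup[[rid]])
    via <- "self"
    if (!length(own) && !is.null(adjacency) && rid %in% rownames(adjacency)) {
      nb <- colnames(adjacency)[adjacency[rid, ] != 0]
      own <- unique(unlist(lookup[nb], use.names = FALSE))
      via <- "neighbour"
    }
    if (!length(own)) {
      own <- "n/a"
      via <- "none"
    }
    data.frame(reaction_id = rid, pathways = paste(own, collapse = "; "),
               annotated_via = via)
  })
  do.call(rbind, rows) %||%
    data.frame(reaction_id = character(), pathways = character(),
               annotated_via = character())
}
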