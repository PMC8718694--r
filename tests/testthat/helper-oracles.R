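# Independent oracles and shared fixtures used across the suite.

# Exhaustive maximum-matching size by recursion over the edge list.
brute_max_matching <- function(adj) {
  n <- nrow(adj)
  edges <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  best <- 0L
  rec <- function(e, used, size) {
    if (size + (nrow(edges) - e + 1L) <= best) return(invisible())
    if (e > nrow(edges)) {
      best <<- max(best, size)
      return(invisible())
    }
    rec(e + 1L, used, size)
    i <- edges[e, 1L]
    j <- edges[e, 2L]
    if (!used[i] && !used[j]) {
      used[i] <- used[j] <- TRUE
      rec(e + 1L, used, size + 1L)
    }
  }
  rec(1L, rep(FALSE, n), 0L)
  best
}

# Random symmetric 0/1 adjacency with named nodes.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
    }
  }
  dimnames(A) <- list(sprintf("N%02d", seq_len(n)), sprintf("N%02d", seq_len(n)))
  A
}

# Type-7 quantile computed from order statistics by hand.
sorted_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small mixed-kind archetype set for ensemble fixtures.
test_archetypes <- function(ids = c("R_001", "R_002", "R_003", "TX_001")) {
  kinds <- c("steady", "ramp", "oscillation", "steady")
  lapply(seq_along(ids), function(i) {
    switch(kinds[(i - 1L) %% 4L + 1L],
      steady = reaction_archetype(ids[i], "steady", baseline = 3 + i,
                                  noise_sd = 0.2),
      ramp = reaction_archetype(ids[i], "ramp", baseline = 1,
                                slope = 2e-4, noise_sd = 0.2),
      oscillation = reaction_archetype(ids[i], "oscillation", baseline = 0,
                                       amplitude = 2, period = 5000,
                                       noise_sd = 0.2)
    )
  })
}

# Linearly separable two-class fixture for classifier tests: class shifts
# the whole encoded trajectory.
separable_fixture <- function(n_per_class = 40L, len = 30L, seed = 1L) {
  set.seed(seed)
  X0 <- matrix(stats::runif(n_per_class * len, 0, 0.3), n_per_class)
  X1 <- matrix(stats::runif(n_per_class * len, 0.7, 1), n_per_class)
  list(X = rbind(X0, X1),
       labels = rep(c("normal", "abnormal"), each = n_per_class))
}
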