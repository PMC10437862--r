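# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: distances by exhaustive search over periodic
# images, modularity by exhaustive partition enumeration, shortest paths by
# Floyd-Warshall.

# Exhaustive minimum distance between nodes u, v over a 5x5 block of
# periodic translates (strictly wider than any minimum image needs).
brute_torus_distance <- function(grid, u, v) {
  x <- grid$coords$x_mm
  y <- grid$coords$y_mm
  best <- Inf
  for (ix in -2:2) {
    for (iy in -2:2) {
      d <- sqrt((x[u] - x[v] + ix * grid$width)^2 +
                (y[u] - y[v] + iy * grid$height)^2)
      best <- min(best, d)
    }
  }
  best
}

# Hand-built connectome from an edge list matrix (source, target), with
# distances defaulting to 1 and explicit delay steps.
make_connectome <- function(n, edges, delay = 0L, distance = 1) {
  edges <- matrix(as.integer(edges), ncol = 2)
  mesosync:::new_connectome(
    n,
    tibble::tibble(
      source = edges[, 1], target = edges[, 2],
      distance_mm = rep_len(distance, nrow(edges)),
      delay_steps = as.integer(rep_len(delay, nrow(edges)))
    )
  )
}

# All directed edges of a complete graph on n nodes.
complete_edges <- function(n) {
  g <- expand.grid(source = 1:n, target = 1:n)
  as.matrix(g[g$source != g$target, ])
}

# Floyd-Warshall all-pairs shortest paths on a directed unweighted graph.
brute_shortest_paths <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[edges] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Fagiolo directed clustering by explicit triple counting.
brute_directed_clustering <- function(n, edges) {
  A <- matrix(0, n, n)
  A[edges] <- 1
  cc <- rep(NA_real_, n)
  for (i in 1:n) {
    tri <- 0
    for (j in 1:n) for (k in 1:n) {
      if (j != i && k != i && j != k) {
        tri <- tri + (A[i, j] + A[j, i]) * (A[i, k] + A[k, i]) *
          (A[j, k] + A[k, j])
      }
    }
    tri <- tri / 2 # each directed triangle counted once per (j,k) ordering
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    denom <- dtot * (dtot - 1) - 2 * dbi
    if (denom > 0) cc[i] <- tri / denom
  }
  mean(cc, na.rm = TRUE)
}

# Exhaustive maximal-modularity partition (restricted growth strings).
# Only feasible for n <= 8.
brute_best_modularity <- function(W, gamma = 1) {
  n <- nrow(W)
  best <- -Inf
  best_labels <- rep(1L, n)
  rec <- function(labels, pos, maxlab) {
    if (pos > n) {
      q <- mesosync::modularity_score(W, labels, gamma)
      if (q > best) {
        best <<- q
        best_labels <<- labels
      }
      return(invisible())
    }
    for (lab in 1:(maxlab + 1)) {
      labels[pos] <- lab
      rec(labels, pos + 1, max(maxlab, lab))
    }
  }
  rec(integer(n), 1, 0)
  list(q = best, labels = best_labels)
}

# Tiny deterministic study config used by orchestration tests.
smoke_config <- function(...) {
  study_config(rows = 8, cols = 8, spacing = 0.5, n_edges = 256,
               etas = c(1, 5), lambdas = c(4, 28), n_networks = 1,
               duration = 0.4, min_module_size = 4, master_seed = 11, ...)
}
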