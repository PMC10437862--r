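#' Sample a distance-constrained random directed network
#'
#' Draws exactly `n_edges` distinct ordered node pairs (no self-loops) with
#' sampling weight proportional to `d^-eta`, where `d` is the minimum-image
#' toroidal distance between the pair. `eta = 0` reduces to a uniform random
#' directed graph; large `eta` confines edges to nearest neighbours. Power-law
#' weights are scale invariant, so the unit of distance does not affect
#' relative sampling probabilities. Sampling without replacement uses
#' exponential race keys (`rexp(1)/w`), which gives an exact edge count and
#' full reproducibility under the seed.
#'
#' @param grid A `torus_grid`.
#' @param eta Nonnegative distance-decay exponent.
#' @param n_edges Number of directed edges; must not exceed `n * (n - 1)`.
#' @param seed Integer RNG seed.
#' @return A `connectome` object: list with `n_nodes` and `edges`, a tibble
#'   with columns `source`, `target` (1-based), `distance_mm`, `delay_steps`
#'   (initially 0; see [assign_delays()]).
#' @export
sample_network <- function(grid, eta, n_edges, seed) {
  stopifnot(eta >= 0, n_edges >= 1)
  n <- n_nodes(grid)
  if (n_edges > n * (n - 1)) {
    stop(sprintf("n_edges = %d exceeds the %d possible ordered pairs", n_edges, n * (n - 1)))
  }
  D <- toroidal_distance_matrix(grid)
  off <- which(row(D) != col(D))
  d <- D[off]
  w <- d^(-eta)
  keys <- with_seed(seed, stats::rexp(length(w))) / w
  pick <- off[order(keys)[seq_len(n_edges)]]
  src <- row(D)[pick]
  tgt <- col(D)[pick]
  ord <- order(src, tgt)
  new_connectome(
    n_nodes = n,
    edges = tibble::tibble(
      source = src[ord], target = tgt[ord],
      distance_mm = D[pick][ord], delay_steps = 0L
    )
  )
}

new_connectome <- function(n_nodes, edges) {
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %d directed edges (density %.2f%%)\n",
              x$n_nodes, nrow(x$edges),
              100 * nrow(x$edges) / (x$n_nodes * (x$n_nodes - 1))))
  if (any(x$edges$delay_steps > 0)) {
    cat(sprintf("  conduction delays: %d..%d steps\n",
                min(x$edges$delay_steps), max(x$edges$delay_steps)))
  } else {
    cat("  conduction delays: disabled\n")
  }
  invisible(x)
}

#' Assign per-edge conduction delays
#'
#' Quantises each edge's transmission lag `distance / velocity` to integration
#' steps. Rounding is round-half-to-even (base R `round`); when delays are
#' enabled every edge gets at least one step, since an enabled connection must
#' not act instantaneously. With delays disabled all delays are zero.
#'
#' @param net A `connectome`.
#' @param velocity Conduction velocity in m/s.
#' @param dt Integration step in seconds.
#' @param enabled Logical; `FALSE` zeroes all delays.
#' @return The connectome with `delay_steps` filled in.
#' @export
assign_delays <- function(net, velocity, dt, enabled = TRUE) {
  stopifnot(velocity > 0, dt > 0)
  if (!enabled) {
    net$edges$delay_steps <- 0L
    return(net)
  }
  lag_s <- (net$edges$distance_mm / 1000) / velocity
  net$edges$delay_steps <- pmax(1L, as.integer(round(lag_s / dt)))
  net
}

connectome_sparse_adjacency <- function(net) {
  Matrix::sparseMatrix(i = net$edges$source, j = net$edges$target, x = 1,
                       dims = c(net$n_nodes, net$n_nodes))
}

as_igraph <- function(net) {
  igraph::graph_from_edgelist(cbind(net$edges$source, net$edges$target),
                              directed = TRUE)
}

#' Graph-theory summary of a directed network
#'
#' Mean local clustering coefficient (Fagiolo's directed generalisation:
#' realised directed triangles through a node over the number possible given
#' its in/out/bidirectional degrees), characteristic path length (mean
#' directed shortest path over reachable ordered pairs), and global efficiency
#' (mean inverse shortest path, unreachable pairs contributing zero).
#'
#' @param net A `connectome`.
#' @return A one-row tibble with columns `clustering`, `path_length`,
#'   `efficiency`.
#' @export
graph_metrics <- function(net) {
  stopifnot(nrow(net$edges) > 0)
  A <- connectome_sparse_adjacency(net)
  S <- A + Matrix::t(A)
  tri <- Matrix::diag(S %*% S %*% S) / 2
  d_in <- Matrix::colSums(A)
  d_out <- Matrix::rowSums(A)
  d_tot <- d_in + d_out
  d_bi <- Matrix::diag(A %*% A)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  cc <- ifelse(denom > 0, tri / denom, NA_real_)
  g <- as_igraph(net)
  sp <- igraph::distances(g, mode = "out")
  off <- row(sp) != col(sp)
  finite <- off & is.finite(sp)
  tibble::tibble(
    clustering = mean(cc, na.rm = TRUE),
    path_length = mean(sp[finite]),
    efficiency = sum(1 / sp[finite]) / sum(off)
  )
}

#' Shuffle node positions while preserving the adjacency matrix
#'
#' Control condition: permutes the node-to-coordinate assignment so the
#' dynamical system (adjacency and, by default, delays) is untouched and only
#' the spatial interpretation of the analysis changes. With
#' `recompute_delays = TRUE` the delays are instead re-derived from the new
#' inter-node distances.
#'
#' @param net A `connectome`.
#' @param grid The `torus_grid` the network was sampled on.
#' @param seed Integer RNG seed for the permutation.
#' @param recompute_delays Logical (default `FALSE`).
#' @param velocity,dt Needed only when `recompute_delays = TRUE`.
#' @return List with elements `net` (edges carry updated `distance_mm`) and
#'   `perm`, the permutation used (`perm[old] = new position index`).
#' @export
shuffle_positions <- function(net, grid, seed, recompute_delays = FALSE,
                              velocity = NULL, dt = NULL) {
  perm <- with_seed(seed, sample.int(net$n_nodes))
  shuffled <- net
  shuffled$edges$distance_mm <- toroidal_distance(
    grid, perm[net$edges$source], perm[net$edges$target]
  )
  if (recompute_delays) {
    stopifnot(!is.null(velocity), !is.null(dt))
    shuffled <- assign_delays(shuffled, velocity, dt, enabled = TRUE)
  }
  list(net = shuffled, perm = perm)
}

#' Write / read an edge list as CSV
#'
#' Header `source,target,distance_mm,delay_steps`, 0-based node indices.
#' @param net A `connectome`.
#' @param path File path.
#' @export
write_edgelist_csv <- function(net, path) {
  out <- dplyr::mutate(net$edges,
                       source = .data$source - 1L,
                       target = .data$target - 1L)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_edgelist_csv
#' @param n_nodes Node count of the stored network.
#' @export
read_edgelist_csv <- function(path, n_nodes) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  edges$source <- as.integer(edges$source) + 1L
  edges$target <- as.integer(edges$target) + 1L
  edges$delay_steps <- as.integer(edges$delay_steps)
  new_connectome(n_nodes, tibble::as_tibble(edges))
}
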