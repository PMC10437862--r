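#' Newman spectral community detection with fine-tuning
#'
#' Recursive spectral bisection on the weighted modularity matrix
#' `B = W - gamma * (k %o% k) / (2m)` (k = weighted degrees, 2m = total
#' weight), splitting each group along the leading eigenvector of its
#' degree-corrected sub-matrix, followed by a Kernighan-Lin-style single-node
#' fine-tuning sweep. A split is kept only if its modularity contribution is
#' positive. Eigenvector sign ambiguity is resolved by orienting the vector so
#' its first nonzero entry is positive, making the result deterministic.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @param gamma Resolution parameter (default 1).
#' @return A `partition`: list with `labels` (per-node community, contiguous
#'   integers from 1), `n_communities`, and `modularity` (Q at the given
#'   gamma).
#' @export
detect_communities <- function(W, gamma = 1) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W)))) {
    stop("W must be symmetric")
  }
  W <- (W + t(W)) / 2
  n <- nrow(W)
  total <- sum(W)
  if (total <= 0) {
    return(new_partition(rep(1L, n), 0, gamma))
  }
  k <- colSums(W)
  B <- W - gamma * tcrossprod(k) / total

  labels <- integer(n)
  next_label <- 0L
  queue <- list(seq_len(n))
  while (length(queue) > 0) {
    g <- queue[[1]]
    queue <- queue[-1]
    s <- bisect_group(B, g)
    if (is.null(s)) {
      next_label <- next_label + 1L
      labels[g] <- next_label
    } else {
      queue <- c(queue, list(g[s > 0], g[s < 0]))
    }
  }
  Q <- modularity_from_B(B, labels, total)
  new_partition(labels, Q, gamma)
}

# Attempt to split group `g` (indices into B). Returns the +/-1 split vector,
# or NULL when no positive-modularity split exists.
bisect_group <- function(B, g) {
  ng <- length(g)
  if (ng < 2) return(NULL)
  Bg <- B[g, g, drop = FALSE]
  # degree correction for subdivision: remove each row's total so moving a
  # node does not change contributions from outside the group
  Bg <- Bg - diag(rowSums(Bg), ng)
  ev <- eigen(Bg, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (ev$values[1] <= 1e-12) return(NULL)
  nz <- which(abs(v) > 1e-12)
  if (length(nz) == 0) return(NULL)
  if (v[nz[1]] < 0) v <- -v
  s <- ifelse(v >= 0, 1, -1)
  s <- kl_fine_tune(Bg, s)
  dQ <- as.numeric(t(s) %*% Bg %*% s) # proportional to the Q contribution
  if (dQ <= 1e-12 || all(s == s[1])) return(NULL)
  s
}

# Kernighan-Lin style refinement: repeated passes; within a pass every node
# is flipped at most once, always the one with the largest gain, and the best
# intermediate state of the pass is kept.
kl_fine_tune <- function(Bg, s) {
  n <- length(s)
  obj <- function(sv) as.numeric(t(sv) %*% Bg %*% sv)
  best <- obj(s)
  repeat {
    h <- as.vector(Bg %*% s)
    avail <- rep(TRUE, n)
    s_try <- s
    traj_obj <- numeric(n)
    traj_node <- integer(n)
    cur <- obj(s)
    for (step in seq_len(n)) {
      # gain of flipping node v: -4 s_v h_v + 4 B_vv
      gains <- -4 * s_try * h + 4 * diag(Bg)
      gains[!avail] <- -Inf
      v <- which.max(gains)
      cur <- cur + gains[v]
      h <- h - 2 * s_try[v] * Bg[, v]
      s_try[v] <- -s_try[v]
      avail[v] <- FALSE
      traj_obj[step] <- cur
      traj_node[step] <- v
    }
    b <- which.max(traj_obj)
    if (traj_obj[b] > best + 1e-12) {
      flip <- traj_node[seq_len(b)]
      s[flip] <- -s[flip]
      best <- traj_obj[b]
    } else {
      break
    }
  }
  s
}

modularity_from_B <- function(B, labels, total) {
  q <- 0
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    q <- q + sum(B[idx, idx])
  }
  q / total
}

#' Modularity of a given partition
#'
#' Q at resolution `gamma` for an arbitrary labelling of a weighted network.
#' @param W Symmetric weight matrix.
#' @param labels Per-node community labels.
#' @param gamma Resolution (default 1).
#' @return Scalar Q.
#' @export
modularity_score <- function(W, labels, gamma = 1) {
  W <- (W + t(W)) / 2
  total <- sum(W)
  if (total <= 0) return(0)
  k <- colSums(W)
  B <- W - gamma * tcrossprod(k) / total
  modularity_from_B(B, labels, total)
}

new_partition <- function(labels, modularity, gamma) {
  labels <- as.integer(factor(labels, levels = unique(labels)))
  structure(list(labels = labels,
                 n_communities = length(unique(labels)),
                 modularity = modularity, gamma = gamma),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities, Q = %.4f (gamma = %g)\n",
              length(x$labels), x$n_communities, x$modularity, x$gamma))
  invisible(x)
}

#' @export
glance.partition <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$labels),
                 n_communities = x$n_communities,
                 modularity = x$modularity, gamma = x$gamma)
}

#' Track modules across consecutive windows
#'
#' Assigns persistent identifiers to per-window communities: for each module
#' of the previous window (processed in descending size order, ties toward
#' the lower tracked ID), the unclaimed module of the current window sharing
#' the greatest member overlap inherits its identifier (overlap ties toward
#' the lower raw label); modules claimed by nobody receive fresh,
#' strictly increasing IDs.
#'
#' @param partitions List of `partition` objects (or plain label vectors),
#'   one per window, over the same node set.
#' @return A `module_timeline`: list with `tracked`, a windows x nodes
#'   integer matrix of persistent IDs, and `registry`, a tibble mapping each
#'   ID to its first-seen window.
#' @export
track_modules <- function(partitions) {
  labs <- lapply(partitions, function(p) {
    if (inherits(p, "partition")) p$labels else as.integer(p)
  })
  n_win <- length(labs)
  stopifnot(n_win >= 1)
  n <- length(labs[[1]])
  tracked <- matrix(NA_integer_, nrow = n_win, ncol = n)
  first_seen <- integer(0)

  cur <- labs[[1]]
  ids <- seq_along(unique(cur))
  map <- stats::setNames(ids, sort(unique(cur)))
  tracked[1, ] <- unname(map[as.character(cur)])
  first_seen <- rep(1L, length(ids))
  next_id <- length(ids) + 1L

  if (n_win >= 2) {
    for (w in 2:n_win) {
      prev_ids <- tracked[w - 1, ]
      cur_raw <- labs[[w]]
      prev_tab <- sort(table(prev_ids), decreasing = TRUE)
      prev_order <- as.integer(names(prev_tab))
      # stable ordering: descending size, ties toward lower tracked ID
      sizes <- as.integer(prev_tab)
      prev_order <- prev_order[order(-sizes, prev_order)]
      cur_labels <- sort(unique(cur_raw))
      claimed <- logical(length(cur_labels))
      assign_map <- integer(length(cur_labels))
      for (pid in prev_order) {
        members <- prev_ids == pid
        ov <- vapply(seq_along(cur_labels), function(ci) {
          if (claimed[ci]) return(-1L)
          sum(members & cur_raw == cur_labels[ci])
        }, integer(1))
        if (max(ov) >= 1L) {
          ci <- which.max(ov) # which.max takes the first (lowest label) on ties
          claimed[ci] <- TRUE
          assign_map[ci] <- pid
        }
      }
      for (ci in which(!claimed)) {
        assign_map[ci] <- next_id
        first_seen <- c(first_seen, w)
        next_id <- next_id + 1L
      }
      tracked[w, ] <- assign_map[match(cur_raw, cur_labels)]
    }
  }
  structure(
    list(tracked = tracked,
         registry = tibble::tibble(id = seq_along(first_seen),
                                   first_seen = first_seen)),
    class = "module_timeline"
  )
}

#' @export
print.module_timeline <- function(x, ...) {
  cat(sprintf("<module_timeline> %d windows x %d nodes, %d tracked modules\n",
              nrow(x$tracked), ncol(x$tracked), nrow(x$registry)))
  invisible(x)
}

#' @export
tidy.module_timeline <- function(x, ...) {
  tibble::tibble(
    window = rep(seq_len(nrow(x$tracked)), times = ncol(x$tracked)),
    node = rep(seq_len(ncol(x$tracked)), each = nrow(x$tracked)),
    tracked_id = as.vector(x$tracked)
  )
}

#' Per-node module stability
#'
#' Fraction of windows each node spends in its most frequently associated
#' tracked module.
#'
#' @param tl A `module_timeline`.
#' @return Tibble with `node`, `modal_id`, `stability`.
#' @export
stability_map <- function(tl) {
  n_win <- nrow(tl$tracked)
  res <- apply(tl$tracked, 2, function(col) {
    tab <- table(col)
    best <- which.max(tab)
    c(as.integer(names(tab)[best]), as.integer(tab[best]))
  })
  tibble::tibble(node = seq_len(ncol(tl$tracked)),
                 modal_id = res[1, ],
                 stability = res[2, ] / n_win)
}

#' Modal module assignment per node
#'
#' The tracked module each node is most frequently part of, restricted to the
#' retained (post-transient) windows; used to define fixed module membership
#' for the module-level mean-field analysis.
#'
#' @param tl A `module_timeline`.
#' @param windows Optional integer vector of windows to use (default: all).
#' @return Integer vector of tracked IDs, one per node.
#' @export
modal_assignment <- function(tl, windows = NULL) {
  sub <- if (is.null(windows)) tl$tracked else tl$tracked[windows, , drop = FALSE]
  apply(sub, 2, function(col) {
    tab <- table(col)
    as.integer(names(tab)[which.max(tab)])
  })
}

#' Node participation coefficient
#'
#' Fraction of a node's structural edges (incoming plus outgoing) whose other
#' endpoint sits in a different functional module. Nodes of structural degree
#' zero have no defined participation and are reported `NA`.
#'
#' @param net A `connectome`.
#' @param labels Per-node module labels (a `partition` or integer vector).
#' @return Tibble with `node`, `degree`, `external`, `pc`.
#' @export
node_participation <- function(net, labels) {
  if (inherits(labels, "partition")) labels <- labels$labels
  stopifnot(length(labels) == net$n_nodes)
  src <- net$edges$source
  tgt <- net$edges$target
  cross <- labels[src] != labels[tgt]
  deg <- tabulate(src, net$n_nodes) + tabulate(tgt, net$n_nodes)
  ext <- tabulate(src[cross], net$n_nodes) + tabulate(tgt[cross], net$n_nodes)
  tibble::tibble(node = seq_len(net$n_nodes), degree = as.integer(deg),
                 external = as.integer(ext),
                 pc = ifelse(deg > 0, ext / deg, NA_real_))
}

#' Module participation coefficient
#'
#' For each module, the proportion of structural edge endpoints belonging to
#' its member nodes that attach to edges crossing the module boundary: 0 for
#' a module whose members connect only internally, 1 for one with no internal
#' edges at all.
#'
#' @inheritParams node_participation
#' @return Tibble with `module`, `n_nodes`, `internal_endpoints`,
#'   `external_endpoints`, `pc`.
#' @export
module_participation <- function(net, labels) {
  if (inherits(labels, "partition")) labels <- labels$labels
  stopifnot(length(labels) == net$n_nodes)
  np <- node_participation(net, labels)
  df <- tibble::tibble(module = labels, degree = np$degree,
                       external = np$external)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$module),
    n_nodes = dplyr::n(),
    internal_endpoints = sum(.data$degree) - sum(.data$external),
    external_endpoints = sum(.data$external),
    .groups = "drop"
  )
  tot <- out$internal_endpoints + out$external_endpoints
  out$pc <- ifelse(tot > 0, out$external_endpoints / tot, NA_real_)
  out
}

#' Toroidal centre-of-mass spread of modules
#'
#' Each module's centre of mass is the circular mean of its members'
#' coordinates along each periodic dimension; each node's distance to its
#' module's COM is measured with the minimum-image metric. Reports the
#' per-module mean and the overall node mean.
#'
#' @param grid A `torus_grid`.
#' @param labels Per-node module labels.
#' @return Tibble with `module`, `n_nodes`, `com_x`, `com_y`,
#'   `mean_distance`; overall node-mean distance in attribute
#'   `node_mean_distance`.
#' @export
com_distance <- function(grid, labels) {
  if (inherits(labels, "partition")) labels <- labels$labels
  x <- grid$coords$x_mm
  y <- grid$coords$y_mm
  mods <- sort(unique(labels))
  per_node <- numeric(length(labels))
  rows <- lapply(mods, function(m) {
    idx <- which(labels == m)
    ax <- Arg(mean(exp(2i * pi * x[idx] / grid$width)))
    ay <- Arg(mean(exp(2i * pi * y[idx] / grid$height)))
    cx <- (ax / (2 * pi)) %% 1 * grid$width
    cy <- (ay / (2 * pi)) %% 1 * grid$height
    dx <- abs(x[idx] - cx) %% grid$width
    dx <- pmin(dx, grid$width - dx)
    dy <- abs(y[idx] - cy) %% grid$height
    dy <- pmin(dy, grid$height - dy)
    d <- sqrt(dx^2 + dy^2)
    per_node[idx] <<- d
    tibble::tibble(module = m, n_nodes = length(idx), com_x = cx, com_y = cy,
                   mean_distance = if (length(idx) == 1) 0 else mean(d))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "node_mean_distance") <- mean(per_node)
  out
}

#' Assignment changes between consecutive windows
#'
#' Number of nodes whose tracked module ID differs between each pair of
#' consecutive windows.
#'
#' @param tl A `module_timeline` with at least two windows.
#' @return Tibble with `from_window`, `to_window`, `n_changes`.
#' @export
assignment_changes <- function(tl) {
  n_win <- nrow(tl$tracked)
  stopifnot(n_win >= 2)
  ch <- vapply(2:n_win, function(w) {
    sum(tl$tracked[w, ] != tl$tracked[w - 1, ])
  }, integer(1))
  tibble::tibble(from_window = seq_len(n_win - 1),
                 to_window = 2:n_win, n_changes = ch)
}

#' Write a module timeline to CSV
#'
#' Columns `window,node,tracked_id` (1-based indices).
#' @param tl A `module_timeline`.
#' @param path Output file.
#' @export
write_timeline_csv <- function(tl, path) {
  readr::write_csv(tidy(tl), path)
  invisible(path)
}
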