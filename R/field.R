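#' Module mean fields as meta-oscillators
#'
#' With every node assigned to its modal tracked module, each module is
#' summarised at every stored sample by its internal order parameter `r_m`
#' and mean phase `phi_m` (argument of the member-mean phasor, unwrapped
#' sample-to-sample). The module mean-field frequency is the least-squares
#' slope of the unwrapped mean phase over the retained half of the run,
#' divided by 2*pi. Pairwise mean-phase differences are kept for the phase
#' divergence analyses.
#'
#' @param run A `kuramoto_sim`.
#' @param assignment Integer vector of per-node module IDs (see
#'   [modal_assignment()]).
#' @param min_size Modules with fewer members are dropped (default 10).
#' @param discard Fraction of the run discarded for frequency estimates and
#'   pair statistics (default 0.5).
#' @return A `module_fields` object: list with `modules` (tibble of `module`,
#'   `n_nodes`, `freq_hz`), `times`, `r` and `phi` (modules x samples
#'   matrices, `phi` unwrapped), `pairs` (tibble of module pairs) and
#'   `pair_dphi` (pairs x samples matrix of unwrapped mean-phase
#'   differences), plus the retained-sample index.
#' @export
module_fields <- function(run, assignment, min_size = 10, discard = 0.5) {
  stopifnot(length(assignment) == nrow(run$theta))
  sizes <- table(assignment)
  keep_ids <- as.integer(names(sizes)[sizes >= min_size])
  if (length(keep_ids) == 0) stop("no module reaches min_size")
  Z <- exp(1i * run$theta)
  r <- matrix(NA_real_, length(keep_ids), ncol(run$theta))
  phi <- matrix(NA_real_, length(keep_ids), ncol(run$theta))
  for (k in seq_along(keep_ids)) {
    idx <- which(assignment == keep_ids[k])
    zm <- colMeans(Z[idx, , drop = FALSE])
    r[k, ] <- Mod(zm)
    phi[k, ] <- unwrap_phase(Arg(zm))
  }
  keep <- retained_cols(run$times, discard)
  t <- run$times[keep]
  tc <- t - mean(t)
  freq <- as.vector(phi[, keep, drop = FALSE] %*% tc) / sum(tc^2) / (2 * pi)
  mods <- tibble::tibble(module = keep_ids,
                         n_nodes = as.integer(sizes[as.character(keep_ids)]),
                         freq_hz = freq)
  pairs <- NULL
  pair_dphi <- NULL
  if (length(keep_ids) >= 2) {
    cmb <- utils::combn(seq_along(keep_ids), 2)
    pairs <- tibble::tibble(pair = seq_len(ncol(cmb)),
                            module_a = keep_ids[cmb[1, ]],
                            module_b = keep_ids[cmb[2, ]])
    pair_dphi <- phi[cmb[1, ], , drop = FALSE] - phi[cmb[2, ], , drop = FALSE]
  }
  structure(
    list(modules = mods, times = run$times, r = r, phi = phi,
         pairs = pairs, pair_dphi = pair_dphi, retained = keep,
         discard = discard),
    class = "module_fields"
  )
}

# unwrap a wrapped phase series by removing jumps > pi between samples
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phi[1], phi[1] + cumsum(d))
}

#' @export
print.module_fields <- function(x, ...) {
  cat(sprintf("<module_fields> %d modules over %d samples\n",
              nrow(x$modules), ncol(x$r)))
  print(x$modules)
  invisible(x)
}

#' @export
tidy.module_fields <- function(x, ...) {
  n_mod <- nrow(x$modules)
  tibble::tibble(
    module = rep(x$modules$module, times = ncol(x$r)),
    time = rep(x$times, each = n_mod),
    r = as.vector(x$r),
    phi = as.vector(x$phi)
  )
}

#' Inter-module interaction strength
#'
#' The node-pair interaction estimator applied to module mean phases: per
#' window, `exp(-|change in (phi_m - phi_n)|)`, averaged over the retained
#' windows.
#'
#' @param fields A `module_fields`.
#' @param width,overlap Window spec in seconds / fraction (defaults 0.1, 0.5).
#' @return Tibble of module pairs with `mean_interaction`; the global mean is
#'   in attribute `global_mean`.
#' @export
module_interaction <- function(fields, width = 0.1, overlap = 0.5) {
  if (is.null(fields$pairs)) stop("need at least two modules")
  wins <- window_boundaries(max(fields$times), width, overlap)
  i0 <- snap_to_sample(fields$times, wins$start)
  i1 <- snap_to_sample(fields$times, wins$end)
  retained_w <- which(i0 %in% fields$retained)
  if (length(retained_w) == 0) retained_w <- seq_len(nrow(wins))
  dd <- fields$pair_dphi[, i1[retained_w], drop = FALSE] -
    fields$pair_dphi[, i0[retained_w], drop = FALSE]
  I <- exp(-abs(dd))
  out <- fields$pairs
  out$mean_interaction <- rowMeans(I)
  attr(out, "global_mean") <- mean(I)
  out
}

#' Inter-module phase-difference distributions
#'
#' Density histogram of each pair's mean-phase difference modulo 2*pi over
#' the retained samples.
#'
#' @param fields A `module_fields`.
#' @param n_bins Number of equal bins over `[0, 2*pi)` (default 64).
#' @return Tibble with `pair`, `module_a`, `module_b`, `bin_mid`, `density`.
#' @export
phase_difference_histogram <- function(fields, n_bins = 64) {
  if (is.null(fields$pairs)) stop("need at least two modules")
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- lapply(seq_len(nrow(fields$pairs)), function(p) {
    d <- fields$pair_dphi[p, fields$retained] %% (2 * pi)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    tibble::tibble(pair = fields$pairs$pair[p],
                   module_a = fields$pairs$module_a[p],
                   module_b = fields$pairs$module_b[p],
                   bin_mid = mids, density = h$density)
  })
  dplyr::bind_rows(rows)
}

#' Internal desynchronisation events and their timing
#'
#' Flags samples where a module's internal order parameter falls more than
#' `threshold` below its running median, groups them into events, and
#' cross-references them against fast phase-divergence segments (samples
#' where the absolute derivative of the pair mean-phase difference exceeds
#' its median). Reports the fraction of desynchronised samples that coincide
#' with fast segments, alongside the overall time-fraction of fast segments.
#'
#' @param fields A `module_fields` with at least two modules.
#' @param threshold Drop in `r_m` below the running median that counts as
#'   desynchronised (default 0.2).
#' @param half_width Half-width of the running-median window, in samples
#'   (default 100).
#' @return List with `events` (tibble: `module`, `start_time`, `end_time`),
#'   `co_occurrence` (fraction of desynchronised samples lying in fast
#'   segments) and `fast_fraction` (time-fraction of fast segments), plus
#'   the logical sample masks.
#' @export
desync_events <- function(fields, threshold = 0.2, half_width = 100) {
  keep <- fields$retained
  t <- fields$times[keep]
  n_mod <- nrow(fields$modules)
  low_mask <- matrix(FALSE, n_mod, length(keep))
  events <- list()
  for (k in seq_len(n_mod)) {
    r <- fields$r[k, keep]
    rm <- stats::runmed(r, k = 2 * half_width + 1, endrule = "median")
    low <- r < rm - threshold
    low_mask[k, ] <- low
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    on <- which(rl$values)
    if (length(on) > 0) {
      events[[length(events) + 1]] <- tibble::tibble(
        module = fields$modules$module[k],
        start_time = t[starts[on]], end_time = t[ends[on]]
      )
    }
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(module = integer(), start_time = numeric(),
                   end_time = numeric())
  fast <- rep(FALSE, length(keep))
  if (!is.null(fields$pair_dphi)) {
    for (p in seq_len(nrow(fields$pairs))) {
      d <- fields$pair_dphi[p, keep]
      rate <- abs(c(diff(d), 0))
      fast <- fast | (rate > stats::median(rate))
    }
  }
  any_low <- colSums(low_mask) > 0
  co <- if (any(any_low)) mean(fast[any_low]) else NA_real_
  list(events = events, co_occurrence = co, fast_fraction = mean(fast),
       low_mask = low_mask, fast_mask = fast, times = t)
}
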