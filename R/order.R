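#' Kuramoto order parameter of a phase configuration
#'
#' Modulus `r` and argument `phi` of the population-mean unit phasor
#' `mean(exp(1i * theta))`. Full synchrony gives r = 1; incoherent
#' phases give r of order `1/sqrt(n)`.
#'
#' @param theta Numeric vector of phases (radians; wrapping irrelevant).
#' @return Named list with `r` and `phi`.
#' @export
order_parameter <- function(theta) {
  stopifnot(length(theta) >= 1)
  z <- mean(exp(1i * theta))
  list(r = Mod(z), phi = Arg(z))
}

# r(t) for every stored sample of a run (vectorised over columns)
order_series <- function(theta_mat) {
  n <- nrow(theta_mat)
  z <- colSums(exp(1i * theta_mat)) / n
  list(r = Mod(z), phi = Arg(z))
}

retained_cols <- function(times, discard) {
  stopifnot(discard >= 0, discard < 1)
  which(times >= discard * max(times))
}

#' Synchrony and metastability of a simulation
#'
#' Computes the order parameter `r(t)` at every retained sample, then the
#' time-mean (synchrony) and time-SD (metastability). By default the first
#' half of the run is discarded to remove the effect of initial transients.
#'
#' @param run A `kuramoto_sim`.
#' @param discard Fraction of the run discarded from the start (default 0.5).
#' @return An `order_summary`: tibble with per-sample `time`, `r`, `phi`,
#'   carrying `synchrony` and `metastability` attributes (also exposed via
#'   [glance()]).
#' @export
summarise_order <- function(run, discard = 0.5) {
  keep <- retained_cols(run$times, discard)
  os <- order_series(run$theta[, keep, drop = FALSE])
  out <- tibble::tibble(time = run$times[keep], r = os$r, phi = os$phi)
  attr(out, "synchrony") <- mean(os$r)
  attr(out, "metastability") <- stats::sd(os$r)
  class(out) <- c("order_summary", class(out))
  out
}

#' @export
glance.order_summary <- function(x, ...) {
  tibble::tibble(synchrony = attr(x, "synchrony"),
                 metastability = attr(x, "metastability"),
                 n_samples = nrow(x))
}

#' Local (neighbourhood) synchrony
#'
#' For each node, the time-mean order parameter over the node together with
#' its structural neighbours (union of in- and out-neighbours, direction
#' ignored). Nodes with no neighbours trivially give r = 1 and are excluded
#' from the network mean.
#'
#' @param run A `kuramoto_sim`.
#' @param net The `connectome` the run was simulated on.
#' @param discard Fraction of the run discarded from the start (default 0.5).
#' @return Tibble with `node`, `local_r`, `n_neighbours`, `isolated`.
#'   The network mean over non-isolated nodes is in attribute
#'   `network_local_synchrony`.
#' @export
local_synchrony <- function(run, net, discard = 0.5) {
  keep <- retained_cols(run$times, discard)
  Z <- exp(1i * run$theta[, keep, drop = FALSE])
  A <- connectome_sparse_adjacency(net)
  U <- A + Matrix::t(A)
  U@x <- rep(1, length(U@x)) # union neighbourhood, unweighted
  NB <- U + Matrix::Diagonal(net$n_nodes)
  sums <- as.matrix(NB %*% Re(Z)) + 1i * as.matrix(NB %*% Im(Z))
  sizes <- Matrix::rowSums(NB)
  local_r <- rowMeans(Mod(sums / sizes))
  isolated <- sizes <= 1
  out <- tibble::tibble(node = seq_len(net$n_nodes), local_r = local_r,
                        n_neighbours = as.integer(sizes) - 1L,
                        isolated = isolated)
  attr(out, "network_local_synchrony") <- mean(local_r[!isolated])
  out
}

#' Locate the critical coupling of a lambda sweep
#'
#' Operationalised as the coupling with maximal metastability; ties break
#' toward the smaller coupling. A flat metastability profile triggers a
#' warning and returns the smallest coupling.
#'
#' @param sweep A data frame with columns `lambda` and `metastability`
#'   (one row per coupling; aggregate replicates first).
#' @return The critical coupling value.
#' @export
critical_coupling <- function(sweep) {
  stopifnot(all(c("lambda", "metastability") %in% names(sweep)),
            nrow(sweep) >= 3)
  sweep <- dplyr::arrange(sweep, .data$lambda)
  ms <- sweep$metastability
  if (max(ms) - min(ms) <= .Machine$double.eps * max(1, abs(max(ms)))) {
    warning("metastability profile is flat; returning the smallest lambda")
    return(sweep$lambda[1])
  }
  sweep$lambda[which.max(ms)]
}

#' Effective node frequencies over the retained part of a run
#'
#' Least-squares slope of each node's unwrapped phase against time,
#' divided by 2*pi. Useful for entrainment diagnostics such as the mean
#' pairwise frequency difference near criticality.
#'
#' @param run A `kuramoto_sim`.
#' @param discard Fraction discarded from the start (default 0.5).
#' @return Tibble with `node`, `freq_hz`.
#' @export
effective_frequencies <- function(run, discard = 0.5) {
  keep <- retained_cols(run$times, discard)
  t <- run$times[keep]
  tc <- t - mean(t)
  th <- run$theta[, keep, drop = FALSE]
  slope <- as.vector(th %*% tc) / sum(tc^2)
  tibble::tibble(node = seq_len(nrow(th)), freq_hz = slope / (2 * pi))
}
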