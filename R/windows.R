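#' Sliding-window boundaries
#'
#' Maximal set of fully contained windows of the given width, advanced by
#' `width * (1 - overlap)` each step.
#'
#' @param duration Total duration in seconds.
#' @param width Window width in seconds (default 0.1).
#' @param overlap Fractional overlap between consecutive windows in `[0, 1)`
#'   (default 0.5).
#' @return Tibble with columns `window`, `start`, `end` (seconds).
#' @export
window_boundaries <- function(duration, width = 0.1, overlap = 0.5) {
  stopifnot(width > 0, overlap >= 0, overlap < 1, duration >= width)
  stride <- width * (1 - overlap)
  n_win <- floor((duration - width) / stride + 1e-9) + 1
  start <- (seq_len(n_win) - 1) * stride
  tibble::tibble(window = seq_len(n_win), start = start, end = start + width)
}

# index of the stored sample nearest to time `t`
snap_to_sample <- function(times, t) {
  vapply(t, function(ti) which.min(abs(times - ti)), integer(1))
}

#' Pairwise interaction strength over one window
#'
#' The interaction estimator `I_ij = exp(-|delta_theta_ij|)` where
#' `delta_theta_ij` is the change in the (cumulative, unwrapped) phase
#' difference between nodes i and j across the window: locked pairs give 1,
#' freely drifting pairs decay with the accumulated divergence. Window
#' boundaries are snapped to the nearest stored sample.
#'
#' @param run A `kuramoto_sim`.
#' @param start,end Window boundaries in seconds.
#' @return A symmetric `n x n` matrix with unit diagonal, entries in (0, 1].
#' @export
interaction_matrix <- function(run, start, end) {
  i0 <- snap_to_sample(run$times, start)
  i1 <- snap_to_sample(run$times, end)
  dphi <- run$theta[, i1] - run$theta[, i0]
  exp(-abs(outer(dphi, dphi, "-")))
}

#' Windowed interaction stack
#'
#' Phases at every window boundary are extracted once; per-window matrices
#' are built on demand through `get_matrix(stack, w)` so that the full
#' `windows x n x n` array is never materialised for large networks unless
#' requested via `materialise = TRUE`.
#'
#' @param run A `kuramoto_sim`.
#' @param width,overlap Window spec (seconds, fraction); defaults 0.1, 0.5.
#' @param materialise If `TRUE`, also store the list of matrices.
#' @return A `windowed_interactions` object with fields `windows` (tibble),
#'   `dphi` (nodes x windows matrix of per-window phase changes) and,
#'   optionally, `matrices`.
#' @export
interaction_stack <- function(run, width = 0.1, overlap = 0.5,
                              materialise = FALSE) {
  wins <- window_boundaries(max(run$times), width, overlap)
  i0 <- snap_to_sample(run$times, wins$start)
  i1 <- snap_to_sample(run$times, wins$end)
  dphi <- run$theta[, i1, drop = FALSE] - run$theta[, i0, drop = FALSE]
  obj <- structure(
    list(windows = wins, dphi = dphi, width = width, overlap = overlap),
    class = "windowed_interactions"
  )
  if (materialise) {
    obj$matrices <- lapply(seq_len(nrow(wins)), function(w) {
      get_matrix(obj, w)
    })
  }
  obj
}

#' @rdname interaction_stack
#' @param stack A `windowed_interactions`.
#' @param w Window index.
#' @export
get_matrix <- function(stack, w) {
  if (!is.null(stack$matrices)) return(stack$matrices[[w]])
  d <- stack$dphi[, w]
  exp(-abs(outer(d, d, "-")))
}

#' @export
print.windowed_interactions <- function(x, ...) {
  cat(sprintf("<windowed_interactions> %d windows of %g s (%.0f%% overlap), %d nodes\n",
              nrow(x$windows), x$width, 100 * x$overlap, nrow(x$dphi)))
  invisible(x)
}
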