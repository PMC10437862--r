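# Evaluate `expr` under `set.seed(seed)` without clobbering the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a master seed and index coordinates
#'
#' Deterministic counter scheme used throughout the study orchestration:
#' each (eta index, replicate, lambda index, role) combination gets its own
#' RNG stream derived from the master seed by modular multiply-and-add over
#' distinct primes, kept below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Integer index coordinates (e.g. eta index, replicate,
#'   lambda index, role code).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m)
  primes <- c(7919, 104729, 1299709, 15485863, 32452843, 49979687)
  for (k in seq_along(idx)) {
    p <- primes[(k - 1) %% length(primes) + 1]
    s <- (s * p + as.numeric(idx[k]) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
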