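#' Draw an ensemble of Kuramoto oscillators
#'
#' Intrinsic frequencies are i.i.d. Normal(`mean_hz`, `sd_hz`); initial phases
#' are i.i.d. Uniform on `[0, 2*pi)`. `noise_sd` is the standard deviation of
#' the additive per-step phase kick applied during integration, quoted for
#' the reference step of 0.1 ms.
#'
#' @param n Number of oscillators.
#' @param mean_hz,sd_hz Mean and SD of the intrinsic frequency distribution,
#'   in Hz. Defaults 60 and 3.
#' @param noise_sd Per-step phase-noise SD in radians (default 0.04 at
#'   dt = 0.1 ms).
#' @param seed Integer RNG seed.
#' @return An `oscillator_ensemble`: a tibble with columns `node`, `omega_hz`,
#'   `theta0`, plus attribute `noise_sd`.
#' @export
draw_ensemble <- function(n, mean_hz = 60, sd_hz = 3, noise_sd = 0.04, seed) {
  stopifnot(n >= 1, sd_hz >= 0, noise_sd >= 0)
  vals <- with_seed(seed, {
    omega <- stats::rnorm(n, mean_hz, sd_hz)
    theta0 <- stats::runif(n, 0, 2 * pi)
    list(omega = omega, theta0 = theta0)
  })
  out <- tibble::tibble(node = seq_len(n), omega_hz = vals$omega,
                        theta0 = vals$theta0)
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("oscillator_ensemble", class(out))
  out
}

# reference integration step the quoted noise SD is tied to
REF_DT <- 1e-4

#' Simulate the delayed, noisy Kuramoto network
#'
#' Explicit Euler integration of
#' \deqn{\dot\theta_i = 2\pi\omega_i + S_i(t) +
#'   \lambda \sum_{j \to i} \sin(\theta_j(t - d_{ji}) - \theta_i(t))}
#' where the sum runs over incoming edges, `d_ji` is the per-edge conduction
#' delay in steps, and `S_i` is an additive per-step Gaussian phase kick.
#' Intrinsic frequencies are given in Hz and converted to rad/s internally;
#' the coupling `lambda` multiplies the raw (un-normalised) sine sum.
#'
#' The delay history is seeded by backward free-running extrapolation so the
#' start is not artificially synchronous. The quoted `noise_sd` refers to a
#' 0.1 ms step; for other `dt` the kick SD is rescaled by `sqrt(dt / 0.1ms)`
#' so the phase diffusion rate is preserved.
#'
#' Phases are stored cumulative (unwrapped) every `store_stride` steps.
#'
#' @param net A `connectome` (delays already assigned; see [assign_delays()]).
#' @param ens An `oscillator_ensemble` with `net$n_nodes` rows.
#' @param coupling Global coupling strength `lambda`.
#' @param dt Integration step in seconds (default 1e-4).
#' @param duration Simulated time in seconds.
#' @param store_stride Steps between stored samples (default 10, i.e. 1 ms
#'   at the default `dt`).
#' @param seed Integer RNG seed for the noise stream.
#' @param return_noise If `TRUE`, also return the raw per-step noise kicks
#'   (for diagnostics; memory scales with `n * n_steps`).
#' @return A `kuramoto_sim` object: list with `theta` (nodes x stored
#'   samples, radians, unwrapped), `times` (seconds), and `config`.
#' @export
simulate_kuramoto <- function(net, ens, coupling, dt = 1e-4, duration,
                              store_stride = 10L, seed,
                              return_noise = FALSE) {
  stopifnot(inherits(net, "connectome"), nrow(ens) == net$n_nodes,
            dt > 0, duration >= dt, store_stride >= 1)
  n_steps <- as.integer(round(duration / dt))
  noise_sd <- attr(ens, "noise_sd")
  noise_eff <- noise_sd * sqrt(dt / REF_DT)
  res <- with_seed(seed, kuramoto_euler_cpp(
    src = net$edges$source, dst = net$edges$target,
    delay = net$edges$delay_steps,
    omega_hz = ens$omega_hz, theta0 = ens$theta0,
    lambda = coupling, dt = dt, n_steps = n_steps,
    noise_sd = noise_eff, store_stride = as.integer(store_stride),
    return_noise = return_noise
  ))
  structure(
    list(
      theta = res$theta, times = res$times,
      noise = res$noise,
      config = list(coupling = coupling, dt = dt, duration = duration,
                    store_stride = as.integer(store_stride), seed = seed,
                    noise_sd = noise_sd, noise_sd_effective = noise_eff,
                    n_nodes = net$n_nodes, n_edges = nrow(net$edges),
                    max_delay = if (nrow(net$edges)) max(net$edges$delay_steps) else 0L)
    ),
    class = "kuramoto_sim"
  )
}

#' @export
print.kuramoto_sim <- function(x, ...) {
  cat(sprintf("<kuramoto_sim> %d nodes, %.3g s at dt = %g s (lambda = %g)\n",
              x$config$n_nodes, x$config$duration, x$config$dt,
              x$config$coupling))
  cat(sprintf("  %d stored samples every %d steps; seed %d\n",
              length(x$times), x$config$store_stride, x$config$seed))
  invisible(x)
}

#' @export
tidy.kuramoto_sim <- function(x, ...) {
  tibble::tibble(
    node = rep(seq_len(nrow(x$theta)), times = ncol(x$theta)),
    time = rep(x$times, each = nrow(x$theta)),
    theta = as.vector(x$theta)
  )
}

#' @export
glance.kuramoto_sim <- function(x, ...) {
  tibble::as_tibble(x$config[c("n_nodes", "n_edges", "coupling", "dt",
                               "duration", "store_stride", "noise_sd",
                               "seed")])
}

#' Map study levels to (eta, lambda) values
#'
#' Convenience lookup for the three canonical levels used throughout the
#' study: eta 1/3/5 and lambda 4/28/60 for low/mid/high.
#'
#' @param level_eta,level_lambda One of `"low"`, `"mid"`, `"high"`.
#' @return Named list with `eta` and `lambda`.
#' @export
default_study_config <- function(level_eta, level_lambda) {
  etas <- c(low = 1, mid = 3, high = 5)
  lambdas <- c(low = 4, mid = 28, high = 60)
  if (!level_eta %in% names(etas)) stop("unknown eta level: ", level_eta)
  if (!level_lambda %in% names(lambdas)) {
    stop("unknown lambda level: ", level_lambda)
  }
  list(eta = unname(etas[level_eta]), lambda = unname(lambdas[level_lambda]))
}
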