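#' Study configuration
#'
#' Bundles every parameter of the in-silico study with defaults matching the
#' reference conditions: a 40x40 hexagonal torus at 0.5 mm spacing, 25600
#' directed edges (1% density), conduction velocity 4 m/s with delays
#' enabled, intrinsic frequencies Normal(60, 3) Hz, per-step phase noise of
#' SD 0.04 rad at dt = 0.1 ms, 10 s simulations, eta in 1..5 with 16 networks
#' per eta and a 16-point linear lambda grid at step 4 (the three
#' canonical anchors 4, 28, 60 are on the grid), 100 ms / 50% overlap
#' windows, community resolution gamma = 1, and the first half of each run
#' discarded as transient.
#'
#' @param rows,cols,spacing Lattice dimensions and spacing (mm).
#' @param n_edges Directed edge count per network.
#' @param velocity Conduction velocity (m/s).
#' @param delays Logical: conduction delays enabled.
#' @param etas Numeric vector of distance-decay exponents.
#' @param lambdas Numeric vector of coupling strengths.
#' @param n_networks Networks (replicates) per eta.
#' @param duration,dt Simulation length and step (s).
#' @param mean_hz,sd_hz,noise_sd Oscillator ensemble parameters.
#' @param window_width,window_overlap Functional-window spec.
#' @param gamma Community-detection resolution.
#' @param discard Transient fraction discarded.
#' @param store_stride Steps between stored samples.
#' @param min_module_size Minimum module size for mean-field analysis.
#' @param master_seed Master RNG seed; all per-run seeds derive from it.
#' @return A `study_config` list.
#' @export
study_config <- function(rows = 40, cols = 40, spacing = 0.5,
                         n_edges = 25600, velocity = 4, delays = TRUE,
                         etas = 1:5,
                         lambdas = seq(4, 64, by = 4),
                         n_networks = 16, duration = 10, dt = 1e-4,
                         mean_hz = 60, sd_hz = 3, noise_sd = 0.04,
                         window_width = 0.1, window_overlap = 0.5,
                         gamma = 1, discard = 0.5, store_stride = 10L,
                         min_module_size = 10L, master_seed = 1L) {
  stopifnot(length(etas) >= 1, length(lambdas) >= 1, n_networks >= 1)
  structure(as.list(environment()), class = "study_config")
}

#' Enumerate the runs of a study
#'
#' One row per (eta, network replicate, lambda) with the derived seeds for
#' network generation, ensemble draw and simulation noise.
#'
#' @param cfg A `study_config`.
#' @return Tibble with columns `eta`, `replicate`, `lambda` and the three
#'   derived seeds.
#' @export
enumerate_runs <- function(cfg) {
  grid <- tidyr::expand_grid(
    eta_idx = seq_along(cfg$etas),
    replicate = seq_len(cfg$n_networks),
    lambda_idx = seq_along(cfg$lambdas)
  )
  dplyr::mutate(
    grid,
    eta = cfg$etas[.data$eta_idx],
    lambda = cfg$lambdas[.data$lambda_idx],
    network_seed = purrr::map2_int(.data$eta_idx, .data$replicate,
      ~ derive_seed(cfg$master_seed, .x, .y, 0L, 1L)),
    ensemble_seed = purrr::pmap_int(
      list(.data$eta_idx, .data$replicate, .data$lambda_idx),
      ~ derive_seed(cfg$master_seed, ..1, ..2, ..3, 2L)),
    sim_seed = purrr::pmap_int(
      list(.data$eta_idx, .data$replicate, .data$lambda_idx),
      ~ derive_seed(cfg$master_seed, ..1, ..2, ..3, 3L))
  )
}

#' Analyse one simulation end-to-end
#'
#' Runs the full analysis chain on a finished simulation: order metrics,
#' local synchrony, windowed interactions, per-window community detection,
#' module tracking, stability, participation coefficients, centre-of-mass
#' spread and assignment changes. Community analysis uses only the retained
#' (post-transient) windows.
#'
#' @param run A `kuramoto_sim`.
#' @param net The `connectome` simulated.
#' @param grid The `torus_grid`.
#' @param cfg A `study_config` (window spec, gamma, discard, module floor).
#' @param detail If `TRUE`, attach the timeline, per-window partitions and
#'   module fields to the result.
#' @return List with `summary` (one-row tibble) and, when `detail = TRUE`,
#'   `timeline`, `partitions`, `fields`, `stack`.
#' @export
analyse_run <- function(run, net, grid, cfg = study_config(),
                        detail = FALSE) {
  os <- summarise_order(run, cfg$discard)
  ls <- local_synchrony(run, net, cfg$discard)
  stack <- interaction_stack(run, cfg$window_width, cfg$window_overlap)
  win_keep <- which(stack$windows$start >= cfg$discard * max(run$times))
  if (length(win_keep) < 2) win_keep <- seq_len(nrow(stack$windows))
  partitions <- lapply(win_keep, function(w) {
    detect_communities(get_matrix(stack, w), cfg$gamma)
  })
  tl <- track_modules(partitions)
  stab <- stability_map(tl)
  assign <- modal_assignment(tl)
  pc_node <- mean(vapply(seq_along(win_keep), function(k) {
    mean(node_participation(net, partitions[[k]])$pc, na.rm = TRUE)
  }, numeric(1)))
  pc_module <- mean(vapply(seq_along(win_keep), function(k) {
    mean(module_participation(net, partitions[[k]])$pc, na.rm = TRUE)
  }, numeric(1)))
  com <- mean(vapply(seq_along(win_keep), function(k) {
    attr(com_distance(grid, partitions[[k]]), "node_mean_distance")
  }, numeric(1)))
  ch <- assignment_changes(tl)
  summary <- tibble::tibble(
    synchrony = attr(os, "synchrony"),
    metastability = attr(os, "metastability"),
    local_synchrony = attr(ls, "network_local_synchrony"),
    mean_stability = mean(stab$stability),
    mean_node_pc = pc_node,
    mean_module_pc = pc_module,
    mean_com_distance = com,
    mean_assignment_changes = mean(ch$n_changes),
    n_windows = length(win_keep),
    mean_modularity = mean(vapply(partitions, function(p) p$modularity,
                                  numeric(1)))
  )
  out <- list(summary = summary)
  if (detail) {
    fields <- tryCatch(
      module_fields(run, assign, cfg$min_module_size, cfg$discard),
      error = function(e) NULL
    )
    out$timeline <- tl
    out$partitions <- partitions
    out$fields <- fields
    out$stack <- stack
    out$stability <- stab
    out$assignment <- assign
  }
  out
}

#' Run the full study sweep
#'
#' For every (eta, network replicate, lambda): sample a fresh network, draw a
#' fresh oscillator ensemble (intrinsic frequencies are re-randomised per
#' simulation), integrate, and run the analysis chain. Failures are logged
#' and skipped rather than aborting the sweep. Identical master seeds give
#' identical results.
#'
#' @param cfg A `study_config`.
#' @param variant One of `"base"`, `"no_delay"` (all conduction delays
#'   zeroed) or `"shuffled"` (node positions permuted after sampling; the
#'   dynamics are untouched and only the spatial analysis changes).
#' @param detail Keep per-run detail objects in a list-column.
#' @param out_dir Optional directory: per-run summary CSVs and the aggregate
#'   CSV are written there.
#' @param progress Print one line per completed run.
#' @return Tibble: one row per run with parameters, seeds and summary
#'   metrics (plus a `detail` list-column when requested).
#' @export
run_study <- function(cfg = study_config(), variant = c("base", "no_delay",
                                                        "shuffled"),
                      detail = FALSE, out_dir = NULL, progress = FALSE) {
  variant <- match.arg(variant)
  grid <- build_torus_grid(cfg$rows, cfg$cols, cfg$spacing)
  runs <- enumerate_runs(cfg)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  nets <- new.env(parent = emptyenv()) # cache networks per (eta, replicate)
  results <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    row <- runs[i, ]
    key <- sprintf("e%d_r%d", row$eta_idx, row$replicate)
    if (is.null(nets[[key]])) {
      net <- sample_network(grid, row$eta, cfg$n_edges, row$network_seed)
      net <- assign_delays(net, cfg$velocity, cfg$dt,
                           enabled = cfg$delays && variant != "no_delay")
      g <- grid
      if (variant == "shuffled") {
        sh <- shuffle_positions(net, grid,
                                derive_seed(cfg$master_seed, row$eta_idx,
                                            row$replicate, 0L, 4L))
        net <- sh$net
        # node i now sits at lattice position perm[i]
        g$coords$x_mm <- grid$coords$x_mm[sh$perm]
        g$coords$y_mm <- grid$coords$y_mm[sh$perm]
      }
      nets[[key]] <- list(net = net, grid = g)
    }
    cached <- nets[[key]]
    res <- tryCatch({
      ens <- draw_ensemble(grid$rows * grid$cols, cfg$mean_hz, cfg$sd_hz,
                           cfg$noise_sd, row$ensemble_seed)
      run <- simulate_kuramoto(cached$net, ens, row$lambda, cfg$dt,
                               cfg$duration, cfg$store_stride, row$sim_seed)
      analyse_run(run, cached$net, cached$grid, cfg, detail = detail)
    }, error = function(e) {
      warning(sprintf("run %d (eta=%g, rep=%d, lambda=%g) failed: %s",
                      i, row$eta, row$replicate, row$lambda,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      srow <- dplyr::bind_cols(
        row[, c("eta", "replicate", "lambda", "network_seed",
                "ensemble_seed", "sim_seed")],
        res$summary
      )
      if (detail) srow$detail <- list(res)
      results[[i]] <- srow
      if (!is.null(out_dir)) {
        readr::write_csv(srow[, setdiff(names(srow), "detail")],
                         file.path(out_dir, sprintf("run_%04d.csv", i)))
      }
    }
    if (progress) {
      message(sprintf("[%d/%d] eta=%g rep=%d lambda=%g done",
                      i, nrow(runs), row$eta, row$replicate, row$lambda))
    }
  }
  agg <- dplyr::bind_rows(results)
  if (!is.null(out_dir)) {
    readr::write_csv(agg[, setdiff(names(agg), "detail")],
                     file.path(out_dir, "aggregate.csv"))
  }
  agg
}
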