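#' Plot the order parameter of a run
#'
#' Time course of `r(t)` with the synchrony (time mean) and the one-SD
#' metastability band overlaid.
#'
#' @param object An `order_summary` (from [summarise_order()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.order_summary <- function(object, ...) {
  syn <- attr(object, "synchrony")
  met <- attr(object, "metastability")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$r)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = syn, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(syn - met, syn + met),
                        linetype = "dotted", colour = "red") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "order parameter r")
}

#' Synchrony and metastability across a coupling sweep
#'
#' @param sweep Tibble with columns `lambda`, `synchrony`, `metastability`
#'   and optionally `eta` (mapped to colour); replicates are averaged.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  grp <- intersect("eta", names(sweep))
  long <- tidyr::pivot_longer(sweep, c("synchrony", "metastability"),
                              names_to = "metric")
  long <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(grp, "lambda", "metric")))),
    value = mean(.data$value), .groups = "drop"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$value))
  if (length(grp)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$eta)))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(lambda), colour = expression(eta), y = NULL)
}

#' Map a per-node statistic onto the lattice
#'
#' @param grid A `torus_grid`.
#' @param value Per-node numeric vector (e.g. stability or participation).
#' @param name Legend title.
#' @return A ggplot of the hexagonal sheet coloured by `value`.
#' @export
plot_node_map <- function(grid, value, name = "value") {
  df <- dplyr::mutate(grid$coords, value = value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Plot module mean-field dynamics
#'
#' Internal order parameter of each module over time together with the
#' pairwise mean-phase differences (modulo 2*pi), the signature panel of the
#' cluster-synchronisation analysis.
#'
#' @param object A `module_fields`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.module_fields <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$r,
                                        colour = factor(.data$module))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(r[m]), colour = "module")
  if (!is.null(object$pair_dphi)) {
    pd <- tibble::tibble(
      time = rep(object$times, each = nrow(object$pairs)),
      pair = rep(object$pairs$pair, times = length(object$times)),
      dphi = as.vector(object$pair_dphi) %% (2 * pi)
    )
    p <- p + ggplot2::geom_line(
      data = pd,
      ggplot2::aes(x = .data$time, y = .data$dphi / (2 * pi),
                   group = .data$pair),
      colour = "darkgreen", linewidth = 0.3, inherit.aes = FALSE
    ) +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . * 2 * pi,
                                     name = expression(Delta * phi ~ (rad)))
      )
  }
  p
}
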