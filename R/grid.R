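#' Build a toroidal hexagonal lattice
#'
#' Lays out `rows * cols` nodes in offset-row hexagonal packing and wraps the
#' sheet onto a torus so that every node has six nearest neighbours at exactly
#' `spacing` millimetres and there are no edge effects. Odd-numbered rows are
#' shifted right by half a spacing; the vertical pitch between rows is
#' `spacing * sqrt(3) / 2`. The row count must be even, otherwise the offset
#' pattern cannot wrap seamlessly in the vertical direction.
#'
#' @param rows,cols Even integers (>= 2): lattice dimensions.
#' @param spacing Distance between adjacent nodes, in millimetres.
#' @return A `torus_grid` object: a list with fields `rows`, `cols`,
#'   `spacing`, the periodic extents `width` and `height` (mm), and `coords`,
#'   a tibble with columns `node` (1-based index), `x_mm`, `y_mm`.
#' @examples
#' grid <- build_torus_grid(6, 6, 0.5)
#' grid$coords
#' @export
build_torus_grid <- function(rows, cols, spacing) {
  stopifnot(is.numeric(rows), is.numeric(cols), is.numeric(spacing),
            length(rows) == 1, length(cols) == 1, length(spacing) == 1,
            rows >= 2, cols >= 2, spacing > 0)
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows %% 2L != 0L) {
    stop("`rows` must be even: odd-row hexagonal offsets cannot wrap periodically.")
  }
  if (cols %% 2L != 0L) {
    stop("`cols` must be even for a seamless periodic lattice.")
  }
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  x <- (c + 0.5 * (r %% 2L)) * spacing
  y <- r * spacing * sqrt(3) / 2
  structure(
    list(
      rows = rows, cols = cols, spacing = spacing,
      width = cols * spacing,
      height = rows * spacing * sqrt(3) / 2,
      coords = tibble::tibble(node = seq_len(rows * cols), x_mm = x, y_mm = y)
    ),
    class = "torus_grid"
  )
}

#' @export
print.torus_grid <- function(x, ...) {
  cat(sprintf("<torus_grid> %d x %d hexagonal lattice (%d nodes), spacing %g mm\n",
              x$rows, x$cols, x$rows * x$cols, x$spacing))
  cat(sprintf("  periodic extent: %g x %g mm\n", x$width, x$height))
  invisible(x)
}

n_nodes <- function(grid) grid$rows * grid$cols

#' Toroidal (minimum-image) distance between nodes
#'
#' Euclidean distance on the periodic sheet, taken as the minimum over all
#' periodic images of the rectangular fundamental domain. `u` and `v` are
#' vectorised and recycled against each other.
#'
#' @param grid A `torus_grid`.
#' @param u,v Node indices (1-based).
#' @return Distances in millimetres.
#' @export
toroidal_distance <- function(grid, u, v) {
  n <- n_nodes(grid)
  if (any(u < 1 | u > n) || any(v < 1 | v > n)) {
    stop("node index out of range")
  }
  dx <- abs(grid$coords$x_mm[u] - grid$coords$x_mm[v]) %% grid$width
  dx <- pmin(dx, grid$width - dx)
  dy <- abs(grid$coords$y_mm[u] - grid$coords$y_mm[v]) %% grid$height
  dy <- pmin(dy, grid$height - dy)
  sqrt(dx^2 + dy^2)
}

#' All-pairs toroidal distance matrix
#'
#' @param grid A `torus_grid`.
#' @return An `n x n` symmetric matrix of minimum-image distances (mm).
#' @export
toroidal_distance_matrix <- function(grid) {
  x <- grid$coords$x_mm
  y <- grid$coords$y_mm
  dx <- abs(outer(x, x, "-")) %% grid$width
  dx <- pmin(dx, grid$width - dx)
  dy <- abs(outer(y, y, "-")) %% grid$height
  dy <- pmin(dy, grid$height - dy)
  sqrt(dx^2 + dy^2)
}

#' Write grid coordinates to CSV
#'
#' Columns `node,x_mm,y_mm` with 0-based node indices.
#' @param grid A `torus_grid`.
#' @param path Output file.
#' @export
write_grid_csv <- function(grid, path) {
  out <- dplyr::mutate(grid$coords, node = .data$node - 1L)
  readr::write_csv(out, path)
  invisible(path)
}
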