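#' Define an equal-area analysis grid
#'
#' The grid lives in a projected equal-area plane with kilometre units (the
#' processing convention for European-scale fragmentation products, which use
#' a Lambert azimuthal equal-area projection). Reporting cells (default
#' 1 km \eqn{\times} 1 km) carry the mesh values; each reporting cell is
#' subdivided `subcell_factor` times per axis into fine subcells on which the
#' barrier geometry is rasterized.
#'
#' Matrix orientation: subcell and cell matrices are stored with row 1 at the
#' grid origin (bottom), so `mask[r, c]` covers
#' `y` in `origin_y + (r-1)*s` to `origin_y + r*s`.
#'
#' @param n_rows,n_cols number of reporting-cell rows/columns (positive).
#' @param cell_size reporting-cell edge length in km (default 1).
#' @param origin_x,origin_y coordinates of the lower-left grid corner (km).
#' @param subcell_factor fine subdivision per axis of each reporting cell
#'   (default 10, i.e. 100 m subcells under 1-km cells).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1, origin_x = 0, origin_y = 0,
                      subcell_factor = 10) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, subcell_factor >= 1)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = as.numeric(cell_size),
    origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
    subcell_factor = as.integer(subcell_factor)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g km (%g km2 total), subcell factor %d\n",
              x$n_rows, x$n_cols, x$cell_size, grid_total_area(x), x$subcell_factor))
  invisible(x)
}

#' Total grid area in km2
#' @param grid a `grid_spec`.
#' @export
grid_total_area <- function(grid) grid$n_rows * grid$n_cols * grid$cell_size^2

#' Number of reporting cells
#' @param grid a `grid_spec`.
#' @export
grid_n_cells <- function(grid) grid$n_rows * grid$n_cols

subcell_size <- function(grid) grid$cell_size / grid$subcell_factor
sub_dims <- function(grid) c(grid$n_rows * grid$subcell_factor,
                             grid$n_cols * grid$subcell_factor)

#' Reporting-cell centers
#'
#' Cell ids are `(row - 1) * n_cols + col` with row 1 at the bottom of the
#' grid; the id order is the fixed row-major order used throughout the
#' package (e.g. for the deterministic representative-point rule).
#'
#' @param grid a `grid_spec`.
#' @param cells optional integer vector of cell ids; default all cells.
#' @return data.frame with columns `cell`, `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid_n_cells(grid))
  row <- ((cells - 1L) %/% grid$n_cols) + 1L
  col <- ((cells - 1L) %% grid$n_cols) + 1L
  data.frame(cell = cells, row = row, col = col,
             x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y + (row - 0.5) * grid$cell_size)
}

#' Construct a barrier grid
#'
#' The fragmentation geometry: a boolean mask at subcell resolution, `TRUE`
#' where a barrier (road, railway, building footprint) blocks movement.
#'
#' @param grid a `grid_spec`.
#' @param mask logical matrix of dimension
#'   `(n_rows * subcell_factor, n_cols * subcell_factor)`; row 1 at the grid
#'   origin. Default all open.
#' @return An object of class `barrier_grid`.
#' @export
barrier_grid <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  sd <- sub_dims(grid)
  if (is.null(mask)) mask <- matrix(FALSE, sd[1], sd[2])
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask), as.integer(sd)))
    stop(sprintf("mask must be %d x %d for this grid", sd[1], sd[2]))
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(grid = grid, mask = mask), class = "barrier_grid")
}

#' @export
print.barrier_grid <- function(x, ...) {
  cat(sprintf("barrier_grid: %d x %d cells, barrier area %.4g of %.4g km2 (%.1f%%)\n",
              x$grid$n_rows, x$grid$n_cols, barrier_area(x), grid_total_area(x$grid),
              100 * barrier_area(x) / grid_total_area(x$grid)))
  invisible(x)
}

#' Barrier area of a barrier grid (km2)
#' @param barrier a `barrier_grid`.
#' @export
barrier_area <- function(barrier) sum(barrier$mask) * subcell_size(barrier$grid)^2
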