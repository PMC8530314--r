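#' Effective mesh size per reporting cell, cross-boundary connections (CBC)
#'
#' For reporting cell k with full cell area A_k (barrier area included),
#' patches i intersecting it with intersection areas A_ik and complete patch
#' areas A_i:
#' \deqn{meff_{CBC}(k) = \frac{1}{A_k} \sum_i A_{ik} A_i}
#' Connections reaching beyond the cell boundary are credited to the cell,
#' which removes the boundary problem of the cutting-out procedure and makes
#' the metric area-proportionately additive: the mean of per-cell CBC values
#' over equal-area cells equals the global effective mesh size.
#' A fully barrier-covered cell has meff 0.
#'
#' @param patches a `patch_map`.
#' @return A `mesh_raster` (matrix of km2 values plus grid and procedure tag).
#' @export
meff_cbc <- function(patches) {
  stopifnot(inherits(patches, "patch_map"))
  grid <- patches$grid
  a_k <- grid$cell_size^2
  v <- numeric(grid_n_cells(grid))
  t <- patches$cell_tab
  if (nrow(t) > 0) {
    s <- rowsum(t$area_km2 * patches$patch_area[t$patch], t$cell)
    v[as.integer(rownames(s))] <- s[, 1] / a_k
  }
  mesh_raster(grid, v, "CBC")
}

#' Effective mesh size per reporting cell, cutting-out (CUT) procedure
#'
#' Cell boundaries are treated as additional barriers:
#' \deqn{meff_{CUT}(k) = \frac{1}{A_k} \sum_i A_{ik}^2}
#' CUT values never exceed the cell area and never exceed the CBC value.
#'
#' @param patches a `patch_map`.
#' @return A `mesh_raster`.
#' @export
meff_cut <- function(patches) {
  stopifnot(inherits(patches, "patch_map"))
  grid <- patches$grid
  a_k <- grid$cell_size^2
  v <- numeric(grid_n_cells(grid))
  t <- patches$cell_tab
  if (nrow(t) > 0) {
    s <- rowsum(t$area_km2^2, t$cell)
    v[as.integer(rownames(s))] <- s[, 1] / a_k
  }
  mesh_raster(grid, v, "CUT")
}

#' Construct a mesh raster
#' @param grid a `grid_spec`.
#' @param values numeric vector (cell-id order) or matrix `(n_rows, n_cols)`
#'   of per-cell effective mesh size in km2.
#' @param procedure `"CBC"` or `"CUT"` (or `"external"` for imported rasters).
#' @export
mesh_raster <- function(grid, values, procedure = c("CBC", "CUT", "external")) {
  procedure <- match.arg(procedure)
  if (!is.matrix(values)) {
    stopifnot(length(values) == grid_n_cells(grid))
    values <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  }
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(grid = grid, meff = values, procedure = procedure),
            class = "mesh_raster")
}

#' @export
print.mesh_raster <- function(x, ...) {
  cat(sprintf("mesh_raster (%s): %d x %d cells, meff range [%.4g, %.4g] km2\n",
              x$procedure, x$grid$n_rows, x$grid$n_cols,
              min(x$meff), max(x$meff)))
  invisible(x)
}

#' Per-cell meff values in cell-id order
#' @param mesh a `mesh_raster`.
#' @export
mesh_values <- function(mesh) as.numeric(t(mesh$meff))

#' Effective mesh density from effective mesh size
#'
#' `seff = 1000 / meff`, reported in meshes per 1000 km2 (the EEA reporting
#' convention). A meff of 0 km2 (fully barrier-covered landscape) maps to the
#' `Inf` sentinel, classified "very high" downstream.
#'
#' @param meff_km2 non-negative numeric vector of mesh sizes (km2).
#' @return numeric vector of densities (meshes per 1000 km2), `Inf` where
#'   `meff_km2` is 0.
#' @export
seff_from_meff <- function(meff_km2) {
  if (any(is.na(meff_km2)) || any(meff_km2 < 0, na.rm = TRUE))
    stop("meff must be non-negative")
  ifelse(meff_km2 == 0, Inf, 1000 / meff_km2)
}

#' Global effective mesh size of a landscape
#'
#' The probability that two uniform random points in the study area are
#' connected, times the total area: \eqn{\sum_i A_i^2 / A_{total}} (km2).
#'
#' @param patches a `patch_map`.
#' @export
global_meff <- function(patches) {
  sum(patches$patch_area^2) / grid_total_area(patches$grid)
}

cell_sub_window <- function(grid, cell) {
  f <- grid$subcell_factor
  row <- ((cell - 1L) %/% grid$n_cols) + 1L
  col <- ((cell - 1L) %% grid$n_cols) + 1L
  list(rows = ((row - 1L) * f + 1L):(row * f),
       cols = ((col - 1L) * f + 1L):(col * f),
       x0 = grid$origin_x + (col - 1L) * grid$cell_size,
       y0 = grid$origin_y + (row - 1L) * grid$cell_size)
}

#' Monte-Carlo oracle for per-cell CBC mesh size
#'
#' Estimates the expected size of the area accessible from a uniform random
#' point in the cell without crossing a barrier: each sample point
#' contributes the complete area of its patch (0 on a barrier subcell). The
#' estimator is unbiased for `meff_cbc` of the cell; it is test-support code,
#' deterministic given `(seed, n_samples)`.
#'
#' @param patches a `patch_map`.
#' @param cell reporting-cell id.
#' @param n_samples number of sample points (>= 1).
#' @param seed integer seed (mandatory).
#' @return list with `estimate`, `se` (standard error), `n`.
#' @export
mc_oracle_meff_cbc <- function(patches, cell, n_samples, seed) {
  stopifnot(n_samples >= 1, is.numeric(seed))
  grid <- patches$grid
  w <- cell_sub_window(grid, cell)
  set.seed(as.integer(seed))
  cs <- grid$cell_size
  px <- runif(n_samples, 0, cs)
  py <- runif(n_samples, 0, cs)
  s <- subcell_size(grid)
  i <- pmin(grid$subcell_factor, floor(py / s) + 1L)
  j <- pmin(grid$subcell_factor, floor(px / s) + 1L)
  lab <- patches$labels[w$rows, w$cols, drop = FALSE][cbind(i, j)]
  val <- ifelse(lab > 0, patches$patch_area[pmax(lab, 1L)], 0)
  list(estimate = mean(val),
       se = if (n_samples > 1) sd(val) / sqrt(n_samples) else 0,
       n = n_samples)
}

#' Monte-Carlo oracle for per-cell CUT mesh size
#'
#' Estimates the probability that two independent uniform points in the cell
#' lie in the same patch (cell boundaries acting as barriers), times the
#' cell area. Unbiased for `meff_cut` of the cell.
#'
#' @inheritParams mc_oracle_meff_cbc
#' @return list with `estimate`, `se`, `n`.
#' @export
mc_oracle_meff_cut <- function(patches, cell, n_samples, seed) {
  stopifnot(n_samples >= 1, is.numeric(seed))
  grid <- patches$grid
  w <- cell_sub_window(grid, cell)
  set.seed(as.integer(seed))
  cs <- grid$cell_size
  s <- subcell_size(grid)
  f <- grid$subcell_factor
  labwin <- patches$labels[w$rows, w$cols, drop = FALSE]
  draw_lab <- function() {
    px <- runif(n_samples, 0, cs); py <- runif(n_samples, 0, cs)
    i <- pmin(f, floor(py / s) + 1L); j <- pmin(f, floor(px / s) + 1L)
    labwin[cbind(i, j)]
  }
  l1 <- draw_lab(); l2 <- draw_lab()
  val <- ifelse(l1 > 0 & l1 == l2, cs^2, 0)
  list(estimate = mean(val),
       se = if (n_samples > 1) sd(val) / sqrt(n_samples) else 0,
       n = n_samples)
}
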