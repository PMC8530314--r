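#' Label barrier-free patches
#'
#' Connected-component labeling of open (non-barrier) subcells with
#' 4-connectivity (rook moves), so a one-subcell-wide rasterized road fully
#' severs patches. Patch areas are exact subcell counts times the subcell
#' area; patches truncated by the study-area edge use their within-extent
#' area as their complete area (the dataset boundary is the edge of the
#' world).
#'
#' @param barrier a `barrier_grid`.
#' @return An object of class `patch_map` with elements:
#'   \describe{
#'     \item{grid}{the `grid_spec`}
#'     \item{labels}{integer matrix at subcell resolution, 0 = barrier}
#'     \item{patch_area}{numeric vector; complete area of patch `i` in km2}
#'     \item{cell_tab}{data.frame `(cell, patch, area_km2)` of per-reporting-cell
#'       patch intersection areas (the A_ik bookkeeping)}
#'   }
#' @export
label_patches <- function(barrier) {
  stopifnot(inherits(barrier, "barrier_grid"))
  grid <- barrier$grid
  if (length(barrier$mask) == 0) stop("empty landscape")
  lab <- label_patches_cpp(!barrier$mask)
  sub_a <- subcell_size(grid)^2
  tab <- cell_patch_counts_cpp(lab$labels, grid$subcell_factor)
  structure(list(
    grid = grid,
    labels = lab$labels,
    patch_area = as.numeric(lab$counts) * sub_a,
    cell_tab = data.frame(cell = tab$cell, patch = tab$patch,
                          area_km2 = tab$count * sub_a)
  ), class = "patch_map")
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf("patch_map: %d patches, open area %.4g km2 of %.4g km2\n",
              length(x$patch_area), sum(x$patch_area), grid_total_area(x$grid)))
  invisible(x)
}

#' Number of patches
#' @param patches a `patch_map`.
#' @export
n_patches <- function(patches) length(patches$patch_area)
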