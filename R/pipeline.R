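#' Fragmentation category scheme
#'
#' The standard effective-mesh-density categories (meshes per 1000 km2) used
#' in European fragmentation reporting, with upper-closed intervals:
#' very_low (<= 1.5), low (> 1.5 - 10), medium (> 10 - 50), high (> 50 - 250),
#' very_high (> 250). The "anthropogenic" class (fully sealed landscapes,
#' `Inf` density) is merged into very_high.
#'
#' @param thresholds strictly increasing numeric vector of four upper bounds.
#' @param labels five category labels.
#' @export
category_scheme <- function(thresholds = c(1.5, 10, 50, 250),
                            labels = c("very_low", "low", "medium", "high", "very_high")) {
  stopifnot(length(thresholds) == length(labels) - 1,
            all(diff(thresholds) > 0), all(thresholds > 0))
  structure(list(thresholds = thresholds, labels = labels),
            class = "category_scheme")
}

#' Categorize effective mesh density values
#'
#' Interval membership with upper-closed bounds; the `Inf` sentinel (fully
#' barrier-covered landscape) falls in the top category.
#'
#' @param seff numeric vector of densities (meshes per 1000 km2); `Inf`
#'   allowed, negatives are an error.
#' @param scheme a `category_scheme`.
#' @return factor with the scheme's labels; `NA` in, `NA` out.
#' @export
categorize <- function(seff, scheme = category_scheme()) {
  if (any(seff < 0, na.rm = TRUE)) stop("seff must be non-negative")
  # left-open intervals (t_i, t_{i+1}]: a value equal to a threshold falls below
  idx <- findInterval(seff, scheme$thresholds, left.open = TRUE) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Filter sites for analysis
#'
#' Retains non-marine sites covering at least one reporting-cell center;
#' every exclusion is reported with its reason (`"marine"` is checked first,
#' then `"no cell center"`).
#'
#' @param sites list of `site_polygon` objects.
#' @param grid a `grid_spec`.
#' @return list with `retained` (sites), `interior_cells` (list of covered
#'   cell ids, parallel to `retained`), and `exclusions`
#'   (data.frame `site_id`, `reason`).
#' @export
filter_sites <- function(sites, grid) {
  ids <- vapply(sites, function(s) s$site_id, "")
  if (anyDuplicated(ids)) stop(sprintf("duplicate site_id: %s",
                                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  retained <- list(); interior <- list()
  exc_id <- character(0); exc_reason <- character(0)
  for (s in sites) {
    if (s$is_marine) {
      exc_id <- c(exc_id, s$site_id); exc_reason <- c(exc_reason, "marine")
      next
    }
    cov <- cells_covered_by_polygon(s, grid)
    if (length(cov) == 0) {
      exc_id <- c(exc_id, s$site_id); exc_reason <- c(exc_reason, "no cell center")
      next
    }
    retained[[length(retained) + 1L]] <- s
    interior[[length(interior) + 1L]] <- cov
  }
  list(retained = retained, interior_cells = interior,
       exclusions = data.frame(site_id = exc_id, reason = exc_reason,
                               stringsAsFactors = FALSE))
}

#' Assign interior and buffer cells to a site
#'
#' Interior cells are those whose center lies in the site polygon (closed
#' rule); buffer cells are those whose center lies in the buffer annulus and
#' not in the interior. Each cell is assigned only once per site, never to
#' both the site and its buffer. Would-be buffer centers falling outside the
#' grid extent are counted in `n_buffer_outside_extent` and dropped.
#'
#' @param site a `site_polygon` (already retained by [filter_sites()]).
#' @param grid a `grid_spec`.
#' @param buffer_km buffer distance (default 5).
#' @return list `interior` (cell ids), `buffer` (cell ids),
#'   `n_buffer_outside_extent` (count of dropped exterior centers).
#' @export
assign_cells <- function(site, grid, buffer_km = 5) {
  ring <- buffer_ring(site, buffer_km)
  bb <- polygon_bbox(site)
  cand <- cells_in_bbox(grid, bb, pad = buffer_km)
  inside <- polygon_contains(site, cand$x, cand$y)
  d <- polygon_distance(site, cand$x, cand$y)
  interior <- sort(cand$cell[inside])
  buf <- sort(cand$cell[!inside & d > 0 & d <= buffer_km])
  # centers of the grid extended beyond its extent that would fall in the ring
  n_out <- count_ring_centers_outside(site, grid, buffer_km)
  list(interior = interior, buffer = buf, n_buffer_outside_extent = n_out)
}

count_ring_centers_outside <- function(site, grid, buffer_km) {
  bb <- polygon_bbox(site)
  cs <- grid$cell_size
  col0 <- floor((bb["xmin"] - buffer_km - grid$origin_x) / cs - 1)
  col1 <- ceiling((bb["xmax"] + buffer_km - grid$origin_x) / cs + 1)
  row0 <- floor((bb["ymin"] - buffer_km - grid$origin_y) / cs - 1)
  row1 <- ceiling((bb["ymax"] + buffer_km - grid$origin_y) / cs + 1)
  rows <- rep(row0:row1, each = col1 - col0 + 1)
  cols <- rep(col0:col1, times = row1 - row0 + 1)
  out <- rows < 1 | rows > grid$n_rows | cols < 1 | cols > grid$n_cols
  if (!any(out)) return(0L)
  x <- grid$origin_x + (cols[out] - 0.5) * cs
  y <- grid$origin_y + (rows[out] - 0.5) * cs
  d <- polygon_distance(site, x, y)
  sum(d > 0 & d <= buffer_km)
}

#' Aggregate per-cell mesh sizes over a cell set
#'
#' The arithmetic mean of the per-cell meff values: because the metric is
#' area-proportionately additive and the cells have equal area, this equals
#' the CBC mesh size of the merged cell set treated as one reporting unit.
#'
#' @param cells integer vector of cell ids (non-empty).
#' @param mesh a `mesh_raster`.
#' @return mesh size in km2.
#' @export
aggregate_meff <- function(cells, mesh) {
  if (length(cells) == 0) stop("no cells")
  v <- mesh_values(mesh)
  mean(v[cells])
}

#' Build the per-site fragmentation record
#'
#' Computes site-level mesh sizes from the interior and buffer cell sets,
#' converts to densities, takes the difference
#' `seff_diff = seff_surrounding - seff_within` (positive when the site is
#' less fragmented than its surroundings), classifies both sides, and flags
#' marginal fragmentation (both densities at or below `marginal_threshold`).
#' The difference class uses exact equality of the computed densities; if
#' both sides are the `Inf` sentinel the difference is 0 ("equal"). A site
#' with an empty buffer set gets `NA` surrounding values and is excluded from
#' difference statistics downstream.
#'
#' @param site a `site_polygon`.
#' @param assignment result of [assign_cells()] for the site.
#' @param mesh a `mesh_raster`.
#' @param scheme a `category_scheme`.
#' @param marginal_threshold density below which fragmentation counts as
#'   marginal (meshes per 1000 km2, default 0.9).
#' @param age_years optional site age (years since first designation).
#' @return one-row data.frame (a SiteRecord).
#' @export
site_record <- function(site, assignment, mesh, scheme = category_scheme(),
                        marginal_threshold = 0.9, age_years = NA_real_) {
  interior <- assignment$interior
  buf <- assignment$buffer
  meff_w <- aggregate_meff(interior, mesh)
  seff_w <- seff_from_meff(meff_w)
  if (length(buf) > 0) {
    meff_s <- aggregate_meff(buf, mesh)
    seff_s <- seff_from_meff(meff_s)
    seff_diff <- if (is.infinite(seff_s) && is.infinite(seff_w)) 0 else seff_s - seff_w
    diff_class <- if (seff_diff > 0) "less_fragmented"
                  else if (seff_diff < 0) "more_fragmented" else "equal"
    marginal <- seff_w <= marginal_threshold && seff_s <= marginal_threshold
    cat_s <- as.character(categorize(seff_s, scheme))
  } else {
    meff_s <- NA_real_; seff_s <- NA_real_; seff_diff <- NA_real_
    diff_class <- NA_character_; marginal <- NA
    cat_s <- NA_character_
  }
  data.frame(
    site_id = site$site_id,
    n_cells_within = length(interior),
    n_cells_buffer = length(buf),
    n_buffer_outside_extent = assignment$n_buffer_outside_extent,
    meff_within_km2 = meff_w,
    meff_surrounding_km2 = meff_s,
    seff_within_per1000km2 = seff_w,
    seff_surrounding_per1000km2 = seff_s,
    seff_diff_per1000km2 = seff_diff,
    category_within = as.character(categorize(seff_w, scheme)),
    category_surrounding = cat_s,
    diff_class = diff_class,
    marginal_flag = marginal,
    area_km2 = polygon_area(site),
    age_years = age_years,
    biogeo_region = site$biogeo_region,
    admin_region = site$admin_region,
    stringsAsFactors = FALSE
  )
}

#' Join protection ages from a registry
#'
#' Emulates an intersection with a protected-area registry (WDPA-like): a
#' site may be covered by several registry entries (its own designation plus
#' overlapping protected areas). The age is computed from the earliest year
#' among entries with status `"designated"`; entries with any other status
#' (e.g. `"proposed"`) are ignored. Sites with no designated entry get `NA`
#' (reported and excluded from age regressions). Rows with malformed years
#' are skipped with a warning.
#'
#' @param site_ids character vector of site ids.
#' @param registry data.frame with columns `site_id`, `status`, `year`.
#' @param reference_year year against which ages are computed (default 2017).
#' @return numeric vector of ages (years), parallel to `site_ids`.
#' @export
join_age <- function(site_ids, registry, reference_year = 2017) {
  stopifnot(all(c("site_id", "status", "year") %in% names(registry)))
  yr <- suppressWarnings(as.numeric(registry$year))
  bad <- is.na(yr)
  if (any(bad)) {
    warning(sprintf("skipping %d registry rows with malformed year", sum(bad)))
    registry <- registry[!bad, , drop = FALSE]
    yr <- yr[!bad]
  }
  keep <- registry$status == "designated"
  earliest <- tapply(yr[keep], registry$site_id[keep], min)
  age <- reference_year - as.numeric(earliest[site_ids])
  unname(age)
}

#' Per-region summary of site fragmentation
#'
#' Medians of the raw site-level densities (never of categories) per region,
#' then categorized with the same scheme; the median damps the influence of
#' outliers. Sites without a region label or without a defined surrounding
#' density are excluded from the respective statistic; empty regions are
#' omitted.
#'
#' @param records data.frame of site records ([site_record()] rows).
#' @param region_col name of the region label column (default
#'   `"admin_region"`).
#' @param scheme a `category_scheme`.
#' @return data.frame, one row per region.
#' @export
regional_summary <- function(records, region_col = "admin_region",
                             scheme = category_scheme()) {
  reg <- records[[region_col]]
  keep <- !is.na(reg)
  records <- records[keep, , drop = FALSE]
  reg <- reg[keep]
  out <- lapply(split(records, reg), function(r) {
    med_w <- median(r$seff_within_per1000km2)
    ss <- r$seff_surrounding_per1000km2
    med_s <- if (any(!is.na(ss))) median(ss[!is.na(ss)]) else NA_real_
    data.frame(region = r[[region_col]][1], n_sites = nrow(r),
               median_seff_within_per1000km2 = med_w,
               median_seff_surrounding_per1000km2 = med_s,
               median_category_within = as.character(categorize(med_w, scheme)),
               median_category_surrounding =
                 if (is.na(med_s)) NA_character_ else as.character(categorize(med_s, scheme)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$region), , drop = FALSE]
}

#' Deterministic representative interior point of a site
#'
#' The center of the site's first covered interior cell in the package-wide
#' row-major cell order; used to assign a site to exactly one admin region.
#'
#' @param interior_cells integer vector of interior cell ids.
#' @param grid a `grid_spec`.
#' @return numeric `c(x, y)`.
#' @export
representative_point <- function(interior_cells, grid) {
  cc <- cell_centers(grid, min(interior_cells))
  c(x = cc$x, y = cc$y)
}
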