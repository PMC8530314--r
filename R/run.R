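# Pipeline drivers binding the stages into the standard workflow:
# simulate -> compute-mesh -> analyze -> summarize. Results go to files,
# logging goes to stderr, so runs stay scriptable.

log_msg <- function(...) message(sprintf(...))

#' Run the scenario generator and write its bundle to disk
#'
#' Writes `barrier.asc`, `sites.geojson`, `registry.csv`,
#' `regions_admin.csv` / `regions_biogeo.csv` (tessellation seeds),
#' `ground_truth.csv` and a `manifest.txt` (key = value) recording the full
#' configuration and seed.
#'
#' @param config a `scenario_config`.
#' @param out_dir output directory (created if missing).
#' @return the scenario bundle, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_scenario(config)
  write_barrier_asc(bundle$barrier, file.path(out_dir, "barrier.asc"))
  write_sites_geojson(bundle$sites, file.path(out_dir, "sites.geojson"))
  write_table_csv(bundle$registry, file.path(out_dir, "registry.csv"))
  rg <- bundle$regions
  write_table_csv(data.frame(region_id = rg$admin$ids, x = rg$admin$x, y = rg$admin$y),
                  file.path(out_dir, "regions_admin.csv"))
  write_table_csv(data.frame(region_id = rg$biogeo$ids, x = rg$biogeo$x, y = rg$biogeo$y),
                  file.path(out_dir, "regions_biogeo.csv"))
  write_table_csv(bundle$ground_truth$first_designated_year,
                  file.path(out_dir, "ground_truth.csv"))
  g <- config$grid
  manifest <- c(
    sprintf("seed = %d", as.integer(config$seed)),
    sprintf("grid = %d x %d cells of %g km, subcell_factor %d, origin (%g, %g)",
            g$n_rows, g$n_cols, g$cell_size, g$subcell_factor, g$origin_x, g$origin_y),
    sprintf("road_intensity = %g", config$road_intensity),
    sprintf("settlement_intensity = %g", config$settlement_intensity),
    sprintf("field_length_scale_km = %g", config$field_length_scale_km),
    sprintf("field_sd_log = %g", config$field_sd_log),
    sprintf("n_sites = %d", config$n_sites),
    sprintf("site_area_range = [%g, %g]", config$site_area_range[1], config$site_area_range[2]),
    sprintf("protection_factor = %g", config$protection_factor),
    sprintf("marine_fraction = %g", config$marine_fraction),
    sprintf("n_admin_regions = %d", config$n_admin_regions),
    sprintf("age_range = [%d, %d]", config$age_range[1], config$age_range[2]),
    sprintf("reference_year = %d", config$reference_year),
    sprintf("realized_n_lines = %d", bundle$ground_truth$n_lines),
    sprintf("realized_n_settlements = %d", bundle$ground_truth$n_settlements)
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  log_msg("simulate: %d sites, %d road chords, %d settlements -> %s",
          length(bundle$sites), bundle$ground_truth$n_lines,
          bundle$ground_truth$n_settlements, out_dir)
  invisible(bundle)
}

#' Compute the mesh raster from a barrier geometry file
#'
#' @param barrier_path path to a barrier ASCII grid (1 = barrier).
#' @param out_path output path for the mesh raster (.asc).
#' @param procedure `"CBC"` (default) or `"CUT"`.
#' @param cell_size reporting-cell edge in km (default 1).
#' @return the `mesh_raster`, invisibly.
#' @export
run_compute_mesh <- function(barrier_path, out_path, procedure = c("CBC", "CUT"),
                             cell_size = 1) {
  procedure <- match.arg(procedure)
  barrier <- read_barrier_asc(barrier_path, cell_size = cell_size)
  patches <- label_patches(barrier)
  mesh <- if (procedure == "CBC") meff_cbc(patches) else meff_cut(patches)
  write_mesh_asc(mesh, out_path)
  log_msg("compute-mesh: %s over %d patches -> %s", procedure,
          n_patches(patches), out_path)
  invisible(mesh)
}

#' Site-level fragmentation analysis of a site list against a mesh raster
#'
#' In-memory core of [run_analyze()]: filters sites, assigns interior and
#' buffer cells, aggregates mesh values, builds site records, joins ages and
#' admin regions.
#'
#' @param sites list of `site_polygon`s.
#' @param mesh a `mesh_raster`.
#' @param registry optional age registry (data.frame `site_id`, `status`,
#'   `year`).
#' @param regions_admin optional admin tessellation (`region_seeds` or list
#'   of polygons) used to label sites by their representative interior point.
#' @param buffer_km buffer distance (default 5).
#' @param scheme a `category_scheme`.
#' @param marginal_threshold marginal-fragmentation bound (default 0.9).
#' @param reference_year age reference year (default 2017).
#' @return list with `records` (data.frame) and `exclusions` (data.frame).
#' @export
analyze_sites <- function(sites, mesh, registry = NULL, regions_admin = NULL,
                          buffer_km = 5, scheme = category_scheme(),
                          marginal_threshold = 0.9, reference_year = 2017) {
  grid <- mesh$grid
  flt <- filter_sites(sites, grid)
  ages <- if (!is.null(registry)) {
    ids <- vapply(flt$retained, function(s) s$site_id, "")
    join_age(ids, registry, reference_year = reference_year)
  } else rep(NA_real_, length(flt$retained))
  recs <- vector("list", length(flt$retained))
  for (i in seq_along(flt$retained)) {
    st <- flt$retained[[i]]
    asg <- assign_cells(st, grid, buffer_km = buffer_km)
    if (!is.null(regions_admin)) {
      rp <- representative_point(asg$interior, grid)
      st$admin_region <- region_assign(regions_admin, rp[1], rp[2])
    }
    recs[[i]] <- site_record(st, asg, mesh, scheme = scheme,
                             marginal_threshold = marginal_threshold,
                             age_years = ages[i])
  }
  records <- if (length(recs) > 0) do.call(rbind, recs) else
    site_record_empty()
  list(records = records, exclusions = flt$exclusions)
}

site_record_empty <- function() {
  r <- site_record(site_polygon("x", cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
                   list(interior = 1L, buffer = integer(0),
                        n_buffer_outside_extent = 0L),
                   mesh_raster(grid_spec(1, 1), matrix(1, 1, 1), "CBC"))
  r[0, , drop = FALSE]
}

#' Run the site-level analysis from files
#'
#' Reads the site vector file, mesh raster, optional admin-region seeds and
#' optional registry; writes `sites.csv` (one site record per row, fixed
#' column order), `regions.csv` (admin-region medians) and `exclusions.csv`.
#'
#' @param sites_path GeoJSON site file.
#' @param mesh_path mesh raster (.asc).
#' @param out_dir output directory.
#' @param registry_path optional registry CSV.
#' @param regions_path optional admin-region seed CSV (`region_id`, `x`, `y`).
#' @inheritParams analyze_sites
#' @return list with `records` and `exclusions`, invisibly.
#' @export
run_analyze <- function(sites_path, mesh_path, out_dir, registry_path = NULL,
                        regions_path = NULL, buffer_km = 5,
                        scheme = category_scheme(), marginal_threshold = 0.9,
                        reference_year = 2017) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sites <- read_sites_geojson(sites_path)
  mesh <- read_mesh_asc(mesh_path)
  registry <- if (!is.null(registry_path)) read_table_csv(registry_path) else NULL
  regions <- if (!is.null(regions_path)) {
    rr <- read_table_csv(regions_path)
    structure(list(ids = rr$region_id, x = rr$x, y = rr$y), class = "region_seeds")
  } else NULL
  res <- analyze_sites(sites, mesh, registry = registry, regions_admin = regions,
                       buffer_km = buffer_km, scheme = scheme,
                       marginal_threshold = marginal_threshold,
                       reference_year = reference_year)
  write_table_csv(res$records, file.path(out_dir, "sites.csv"))
  write_table_csv(regional_summary(res$records, "admin_region", scheme),
                  file.path(out_dir, "regions.csv"))
  write_table_csv(res$exclusions, file.path(out_dir, "exclusions.csv"))
  log_msg("analyze: %d sites retained, %d excluded -> %s",
          nrow(res$records), nrow(res$exclusions), out_dir)
  invisible(res)
}

#' Summarize site records: regressions and tables
#'
#' Reads `sites.csv`, fits the within~surrounding regressions (overall and
#' per biogeographical region), the area and age regressions, and writes
#' `regressions.csv` plus `tables.csv` (long format: table, group, metric,
#' value).
#'
#' @param sites_csv path to a `sites.csv` written by [run_analyze()].
#' @param out_dir output directory.
#' @param scheme a `category_scheme`.
#' @param transform transform for the within~surrounding and area fits.
#' @return list with `regressions` and `tables`, invisibly.
#' @export
run_summarize <- function(sites_csv, out_dir, scheme = category_scheme(),
                          transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_table_csv(sites_csv)
  reg <- summarize_records(records, scheme = scheme, transform = transform)
  write_table_csv(reg$regressions, file.path(out_dir, "regressions.csv"))
  write_table_csv(reg$tables_long, file.path(out_dir, "tables.csv"))
  log_msg("summarize: %d regression rows -> %s", nrow(reg$regressions), out_dir)
  invisible(reg)
}

#' In-memory record summaries
#' @param records data.frame of site records.
#' @param scheme a `category_scheme`.
#' @param transform transform tag for the density fits.
#' @return list with `regressions`, `tables` (the [category_tables()] list),
#'   `descriptive`, and `tables_long` (single long-format data.frame).
#' @export
summarize_records <- function(records, scheme = category_scheme(),
                              transform = "log1p") {
  fits <- rbind(
    fit_within_vs_surrounding(records, by_region = TRUE, transform = transform),
    fit_area_vs_within(records, transform = transform),
    if (any(is.finite(records$age_years))) fit_age_vs_diff(records) else NULL
  )
  tabs <- category_tables(records, scheme)
  desc <- descriptive_stats(records)
  long <- rbind(
    data.frame(table = paste0("categories_", tabs$categories$side),
               group = tabs$categories$category,
               metric = "n", value = tabs$categories$n),
    data.frame(table = paste0("categories_", tabs$categories$side),
               group = tabs$categories$category,
               metric = "n_rel", value = tabs$categories$n_rel),
    data.frame(table = paste0("categories_", tabs$categories$side),
               group = tabs$categories$category,
               metric = "area_km2", value = tabs$categories$area_km2),
    data.frame(table = paste0("categories_", tabs$categories$side),
               group = tabs$categories$category,
               metric = "area_rel", value = tabs$categories$area_rel),
    data.frame(table = "diff_class", group = tabs$diff_class$class,
               metric = "n", value = tabs$diff_class$n),
    data.frame(table = "diff_class", group = tabs$diff_class$class,
               metric = "fraction", value = tabs$diff_class$fraction),
    data.frame(table = "marginal", group = "all", metric = "fraction",
               value = tabs$marginal$fraction),
    do.call(rbind, lapply(names(desc)[-1], function(m)
      data.frame(table = "descriptive", group = desc$region, metric = m,
                 value = desc[[m]])))
  )
  list(regressions = fits, tables = tabs, descriptive = desc, tables_long = long)
}
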