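# Seeded synthetic landscapes: random-chord road networks thinned by a smooth
# log-Gaussian intensity field, settlement disks, protected-site polygons,
# region tessellations and an age registry with known ground truth.

MODULUS <- 2147483647

derive_seed <- function(seed, tag, i = 0) {
  s <- as.double(seed %% MODULUS)
  s <- (s * 69069 + as.double(tag)) %% MODULUS
  s <- (s * 69069 + as.double(i)) %% MODULUS
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Scenario configuration for the synthetic-landscape generator
#'
#' The defaults describe the emulated study conditions: a 600 x 600 km
#' equal-area window with 1-km reporting cells and 200-m barrier subcells;
#' 100 protected sites with log-uniform areas between 1 and 5556 km2 (so the
#' expected total site area covers roughly 18% of the window, the terrestrial
#' protected-area share the pipeline targets); site ages between 2 and 37
#' years against a 2017 reference; a road-chord process and settlement disks
#' whose local intensity follows a smooth log-Gaussian field shared by site
#' interiors and surroundings (the mechanism that couples interior and
#' exterior fragmentation); and a protection factor `f` multiplying barrier
#' intensity inside sites (1 = no protection effect, 0 = interiors kept free
#' of barriers).
#'
#' @param seed integer seed (mandatory; every random choice derives from it).
#' @param grid a `grid_spec` for the landscape.
#' @param road_intensity expected number of road chords per 100 km2 of grid
#'   area.
#' @param settlement_intensity expected settlements per 100 km2.
#' @param settlement_radius_meanlog,settlement_radius_sdlog lognormal radius
#'   distribution (km), clamped to `settlement_radius_range`.
#' @param settlement_radius_range radius bounds (km).
#' @param field_length_scale_km Gaussian smoothing length-scale of the
#'   log-intensity field (km).
#' @param field_sd_log marginal standard deviation of the log field.
#' @param n_sites number of protected-site polygons.
#' @param site_area_range log-uniform site-area bounds (km2).
#' @param protection_factor multiplier `f` in `[0, 1]` on barrier intensity
#'   inside sites.
#' @param marine_fraction fraction of sites flagged marine (a labeled
#'   stratum exercising the filter; no ocean geometry is simulated).
#' @param n_admin_regions number of admin (NUTS-3-like) tessellation seeds.
#' @param biogeo_labels labels for the coarse biogeographical tessellation.
#' @param age_range integer bounds on site age in years.
#' @param reference_year year against which ages are defined.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            grid = grid_spec(600, 600, cell_size = 1, subcell_factor = 5),
                            road_intensity = 0.12,
                            settlement_intensity = 0.6,
                            settlement_radius_meanlog = log(0.4),
                            settlement_radius_sdlog = 0.5,
                            settlement_radius_range = c(0.1, 2),
                            field_length_scale_km = 40,
                            field_sd_log = 1.2,
                            n_sites = 100,
                            site_area_range = c(1, 5556),
                            protection_factor = 0.75,
                            marine_fraction = 0.1,
                            n_admin_regions = 30,
                            biogeo_labels = c("Alpine", "Atlantic", "BlackSea",
                                              "Boreal", "Continental", "Macaronesian",
                                              "Mediterranean", "Pannonian", "Steppic"),
                            age_range = c(2L, 37L),
                            reference_year = 2017) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            inherits(grid, "grid_spec"),
            road_intensity >= 0, settlement_intensity >= 0,
            protection_factor >= 0, protection_factor <= 1,
            marine_fraction >= 0, marine_fraction < 1,
            site_area_range[1] > 0, site_area_range[2] >= site_area_range[1],
            age_range[1] >= 0, age_range[2] >= age_range[1])
  structure(as.list(environment()), class = "scenario_config")
}

#' Smooth log-Gaussian intensity field at reporting-cell resolution
#'
#' Seeded white noise smoothed with a circular Gaussian kernel of the
#' configured length-scale, standardized to the configured log-scale
#' standard deviation, exponentiated, and normalized to spatial mean exactly
#' 1. The field multiplies both the road-chord and the settlement intensity,
#' so neighbouring areas (a site and its buffer) share their local level of
#' development pressure.
#'
#' @param config a `scenario_config`.
#' @return matrix `(n_rows, n_cols)` of positive multipliers, mean 1.
#' @export
generate_field <- function(config) {
  g <- config$grid
  z <- with_seed(derive_seed(config$seed, 11L), {
    matrix(rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
  })
  sigma <- config$field_length_scale_km / g$cell_size
  if (sigma > 0) {
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    half <- min(half, (min(g$n_rows, g$n_cols) - 1L) %/% 2L) # small grids
    k <- exp(-0.5 * ((-half:half) / sigma)^2)
    k <- k / sum(k)
    z <- apply_circular_filter(z, k)
    z <- t(apply_circular_filter(t(z), k))
  }
  z <- (z - mean(z)) / sd(z) * config$field_sd_log
  # clamp the log field at 2.5 sd: keeps the multiplier bounded (the thinning
  # bound of the Cox processes) without visibly changing the body of the
  # distribution
  z <- pmin(pmax(z, -2.5 * config$field_sd_log), 2.5 * config$field_sd_log)
  fld <- exp(z)
  fld / mean(fld)
}

apply_circular_filter <- function(m, k) {
  out <- stats::filter(m, k, method = "convolution", sides = 2, circular = TRUE)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

field_at <- function(field, grid, x, y) {
  cs <- grid$cell_size
  row <- pmin(grid$n_rows, pmax(1L, floor((y - grid$origin_y) / cs) + 1L))
  col <- pmin(grid$n_cols, pmax(1L, floor((x - grid$origin_x) / cs) + 1L))
  field[cbind(row, col)]
}

#' Generate protected-site polygons
#'
#' Convex-ish star-shaped polygons (perturbed, rotated ellipses) with areas
#' drawn log-uniformly from the configured range and rescaled to the drawn
#' area exactly; placed uniformly so the polygon fits inside the grid.
#' Marine flags are assigned at the configured fraction;
#' biogeographical-region labels come from the nearest-seed tessellation at
#' the site centroid.
#'
#' @param config a `scenario_config`.
#' @param regions_biogeo optional `region_seeds` tessellation (generated from
#'   the config seed when missing).
#' @return list of `site_polygon` objects.
#' @export
generate_sites <- function(config, regions_biogeo = NULL) {
  g <- config$grid
  if (config$n_sites == 0) return(list())
  if (is.null(regions_biogeo)) regions_biogeo <- generate_regions(config)$biogeo
  xmin <- g$origin_x; xmax <- g$origin_x + g$n_cols * g$cell_size
  ymin <- g$origin_y; ymax <- g$origin_y + g$n_rows * g$cell_size
  lapply(seq_len(config$n_sites), function(i) {
    with_seed(derive_seed(config$seed, 23L, i), {
      a <- exp(runif(1, log(config$site_area_range[1]), log(config$site_area_range[2])))
      nv <- 28L
      th <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
      ar <- runif(1, 0.55, 1)
      r0 <- sqrt(a / pi)
      A <- r0 / sqrt(ar); B <- r0 * sqrt(ar)
      phi <- runif(1, 0, 2 * pi)
      re <- A * B / sqrt((B * cos(th))^2 + (A * sin(th))^2)
      e <- rnorm(nv)
      e <- as.numeric(stats::filter(c(e, e, e), rep(1 / 5, 5), sides = 2))[(nv + 1):(2 * nv)]
      r <- re * exp(0.25 * e)
      xs <- r * cos(th + phi); ys <- r * sin(th + phi)
      ring <- cbind(xs, ys)
      ring <- ring * sqrt(a / abs(ring_signed_area(ring)))
      rx <- range(ring[, 1]); ry <- range(ring[, 2])
      w <- diff(rx); h <- diff(ry)
      cx <- runif(1, xmin - rx[1], xmax - rx[2])
      cy <- runif(1, ymin - ry[1], ymax - ry[2])
      if (w >= (xmax - xmin)) cx <- (xmin + xmax) / 2 - mean(rx)
      if (h >= (ymax - ymin)) cy <- (ymin + ymax) / 2 - mean(ry)
      ring[, 1] <- ring[, 1] + cx
      ring[, 2] <- ring[, 2] + cy
      marine <- runif(1) < config$marine_fraction
      ctr <- colMeans(ring)
      bio <- region_assign(regions_biogeo, ctr[1], ctr[2])
      site_polygon(sprintf("S%04d", i), ring, is_marine = marine,
                   biogeo_region = bio)
    })
  })
}

#' Region tessellations (biogeographical and admin)
#'
#' Nearest-seed (Voronoi) tessellations of the grid: a coarse one with the
#' configured biogeographical labels and a finer admin (NUTS-3-like) one.
#'
#' @param config a `scenario_config`.
#' @return list with `biogeo` and `admin`, each a `region_seeds` object.
#' @export
generate_regions <- function(config) {
  g <- config$grid
  xmax <- g$origin_x + g$n_cols * g$cell_size
  ymax <- g$origin_y + g$n_rows * g$cell_size
  mk <- function(ids, tag) {
    with_seed(derive_seed(config$seed, tag), {
      structure(list(ids = ids,
                     x = runif(length(ids), g$origin_x, xmax),
                     y = runif(length(ids), g$origin_y, ymax)),
                class = "region_seeds")
    })
  }
  list(biogeo = mk(config$biogeo_labels, 31L),
       admin = mk(sprintf("R%02d", seq_len(config$n_admin_regions)), 37L))
}

#' Assign points to regions
#'
#' Nearest-seed assignment for `region_seeds` tessellations; point-in-polygon
#' assignment when regions are supplied as a list of `site_polygon`-style
#' polygons (first containing polygon wins, `NA` when none contains the
#' point).
#'
#' @param regions a `region_seeds` object or a list of `site_polygon`s.
#' @param x,y point coordinates (km).
#' @return character vector of region ids.
#' @export
region_assign <- function(regions, x, y) {
  if (inherits(regions, "region_seeds")) {
    n <- length(x)
    out <- character(n)
    for (k in seq_len(n)) {
      d2 <- (regions$x - x[k])^2 + (regions$y - y[k])^2
      out[k] <- regions$ids[which.min(d2)]
    }
    return(out)
  }
  out <- rep(NA_character_, length(x))
  for (p in regions) {
    hit <- is.na(out) & polygon_contains(p, x, y)
    out[hit] <- p$site_id
  }
  out
}

#' Generate the barrier geometry
#'
#' Road chords from a field-thinned random-line process (random angle and
#' offset; retention probability proportional to the mean intensity-field
#' value along the chord, so low-pressure areas get fewer roads) plus
#' settlement disks from a field-thinned point process, rasterized one
#' subcell wide with a supercover traversal so 4-connected patches are
#' properly severed. Inside each site, each chord's and each settlement's
#' in-site portion is removed with probability `1 - f` (independently per
#' object-site pair), realizing the protection effect.
#'
#' The chord count is coupled across intensities by inverse-CDF sampling and
#' per-object derived seeds: raising `road_intensity` with the same seed
#' yields a superset of barriers.
#'
#' @param config a `scenario_config`.
#' @param sites list of `site_polygon`s benefiting from protection (default
#'   none).
#' @param field optional intensity field from [generate_field()].
#' @return a `barrier_grid`; attributes `n_lines` and `n_settlements` record
#'   the realized object counts.
#' @export
generate_barriers <- function(config, sites = list(), field = NULL) {
  g <- config$grid
  if (is.null(field)) field <- generate_field(config)
  nr_sub <- g$n_rows * g$subcell_factor
  nc_sub <- g$n_cols * g$subcell_factor
  s_sub <- subcell_size(g)
  area <- grid_total_area(g)
  fmax <- max(field)
  xmin <- g$origin_x; xmax <- g$origin_x + g$n_cols * g$cell_size
  ymin <- g$origin_y; ymax <- g$origin_y + g$n_rows * g$cell_size
  f <- config$protection_factor

  # --- road chords -------------------------------------------------------
  lam_lines <- config$road_intensity * area / 100
  u1 <- with_seed(derive_seed(config$seed, 41L), runif(2))
  n_cand <- qpois(u1[1], lam_lines * fmax)
  # one fixed-stride parameter stream per process: candidate i always reads
  # the same draws, so raising the intensity extends the candidate list
  # without disturbing earlier candidates (monotone coupling)
  line_prm <- if (n_cand > 0)
    matrix(with_seed(derive_seed(config$seed, 43L), runif(3 * n_cand)),
           ncol = 3, byrow = TRUE) else NULL
  line_idx <- list(); line_of <- list()
  n_lines <- 0L
  if (n_cand > 0) {
    for (i in seq_len(n_cand)) {
      prm <- line_prm[i, ]
      theta <- prm[1] * pi
      nx <- cos(theta); ny <- sin(theta)
      corners_p <- c(nx * xmin + ny * ymin, nx * xmin + ny * ymax,
                     nx * xmax + ny * ymin, nx * xmax + ny * ymax)
      p <- min(corners_p) + prm[2] * (max(corners_p) - min(corners_p))
      # endpoints far outside the grid along the line direction
      L <- 2 * (xmax - xmin + ymax - ymin)
      mx <- (xmin + xmax) / 2; my <- (ymin + ymax) / 2
      base_x <- mx + (p - (nx * mx + ny * my)) * nx
      base_y <- my + (p - (nx * mx + ny * my)) * ny
      x0 <- base_x - ny * L; y0 <- base_y + nx * L
      x1 <- base_x + ny * L; y1 <- base_y - nx * L
      cells_rep <- supercover_indices_cpp(x0, y0, x1, y1, g$origin_x, g$origin_y,
                                          g$cell_size, g$n_rows, g$n_cols)
      if (length(cells_rep) == 0) next
      gbar <- mean(field[cells_rep])
      if (prm[3] >= gbar / fmax) next # field thinning
      n_lines <- n_lines + 1L
      idx <- supercover_indices_cpp(x0, y0, x1, y1, g$origin_x, g$origin_y,
                                    s_sub, nr_sub, nc_sub)
      line_idx[[n_lines]] <- idx
      line_of[[n_lines]] <- rep.int(i, length(idx))
    }
  }
  # --- settlement disks --------------------------------------------------
  lam_set <- config$settlement_intensity * area / 100
  n_cand_s <- qpois(u1[2], lam_set * fmax)
  n_settle <- 0L
  disk_idx <- list(); disk_of <- list()
  if (n_cand_s > 0) {
    prm <- matrix(with_seed(derive_seed(config$seed, 53L), runif(4 * n_cand_s)),
                  ncol = 4, byrow = TRUE)
    xs <- xmin + prm[, 1] * (xmax - xmin)
    ys <- ymin + prm[, 2] * (ymax - ymin)
    acc <- prm[, 3] < field_at(field, g, xs, ys) / fmax # field thinning
    rs <- exp(config$settlement_radius_meanlog +
              config$settlement_radius_sdlog * stats::qnorm(prm[, 4]))
    rs <- pmin(pmax(rs, config$settlement_radius_range[1]),
               config$settlement_radius_range[2])
    for (i in which(acc)) {
      n_settle <- n_settle + 1L
      idx <- disk_subcells(xs[i], ys[i], rs[i], g, nr_sub, nc_sub, s_sub)
      disk_idx[[n_settle]] <- idx
      disk_of[[n_settle]] <- rep.int(n_cand + i, length(idx)) # ids after lines
    }
  }

  # --- per-object, per-site protection thinning --------------------------
  # Each barrier object's subcells falling inside a site are removed with
  # probability 1 - f, independently per (object, site) pair.
  all_idx <- c(if (n_lines > 0) unlist(line_idx) else integer(0),
               if (n_settle > 0) unlist(disk_idx) else integer(0))
  all_obj <- c(if (n_lines > 0) unlist(line_of) else integer(0),
               if (n_settle > 0) unlist(disk_of) else integer(0))
  keep <- rep(TRUE, length(all_idx))
  if (length(all_idx) > 0 && length(sites) > 0 && f < 1) {
    sub_row <- ((all_idx - 1L) %% nr_sub) + 1L
    sub_col <- ((all_idx - 1L) %/% nr_sub) + 1L
    px <- g$origin_x + (sub_col - 0.5) * s_sub
    py <- g$origin_y + (sub_row - 0.5) * s_sub
    for (j in seq_along(sites)) {
      st <- sites[[j]]
      bb <- polygon_bbox(st)
      cand <- which(px >= bb["xmin"] & px <= bb["xmax"] &
                    py >= bb["ymin"] & py <= bb["ymax"] & keep)
      if (length(cand) == 0) next
      inside <- cand[polygon_contains(st, px[cand], py[cand])]
      if (length(inside) == 0) next
      for (oi in unique(all_obj[inside])) {
        rm_draw <- with_seed(derive_seed(config$seed, 47L, oi * 1009L + j), runif(1))
        if (rm_draw < 1 - f) keep[inside[all_obj[inside] == oi]] <- FALSE
      }
    }
  }
  barrier_sub <- unique(all_idx[keep])

  mask <- matrix(FALSE, nr_sub, nc_sub)
  if (length(barrier_sub) > 0) mask[barrier_sub] <- TRUE
  out <- barrier_grid(g, mask)
  attr(out, "n_lines") <- n_lines
  attr(out, "n_settlements") <- n_settle
  out
}

disk_subcells <- function(x, y, r, g, nr_sub, nc_sub, s_sub) {
  r0 <- max(1L, floor((y - r - g$origin_y) / s_sub) + 1L)
  r1 <- min(nr_sub, ceiling((y + r - g$origin_y) / s_sub))
  c0 <- max(1L, floor((x - r - g$origin_x) / s_sub) + 1L)
  c1 <- min(nc_sub, ceiling((x + r - g$origin_x) / s_sub))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  cy <- g$origin_y + (rows - 0.5) * s_sub
  cx <- g$origin_x + (cols - 0.5) * s_sub
  d2 <- outer((cy - y)^2, (cx - x)^2, "+")
  hit <- which(d2 <= r^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(integer(0))
  (cols[hit[, 2]] - 1L) * nr_sub + rows[hit[, 1]]
}

#' Generate an age registry
#'
#' Each site receives one own entry (status `"designated"` with high
#' probability, else `"proposed"`) dated `reference_year - age` with age
#' uniform on the configured range, plus up to two additional overlapping
#' entries with random status and later-or-equal years. The planted earliest
#' designated year per site (or `NA` when no designated entry exists) is the
#' recoverable ground truth.
#'
#' @param config a `scenario_config`.
#' @param sites list of `site_polygon`s.
#' @return list with `registry` (data.frame `site_id`, `status`, `year`) and
#'   `truth` (data.frame `site_id`, `first_designated_year`).
#' @export
generate_registry <- function(config, sites) {
  rows <- list()
  for (i in seq_along(sites)) {
    sid <- sites[[i]]$site_id
    rows[[i]] <- with_seed(derive_seed(config$seed, 61L, i), {
      age <- config$age_range[1] +
        sample.int(config$age_range[2] - config$age_range[1] + 1L, 1) - 1L
      y0 <- config$reference_year - age
      status0 <- if (runif(1) < 0.97) "designated" else "proposed"
      n_extra <- sample.int(3L, 1) - 1L
      st <- status0; yr <- y0
      if (n_extra > 0) {
        ymax <- max(y0, config$reference_year - config$age_range[1])
        st <- c(st, sample(c("designated", "proposed"), n_extra, replace = TRUE))
        yr <- c(yr, y0 + sample.int(ymax - y0 + 1L, n_extra, replace = TRUE) - 1L)
      }
      data.frame(site_id = sid, status = st, year = yr, stringsAsFactors = FALSE)
    })
  }
  registry <- do.call(rbind, rows)
  des <- registry[registry$status == "designated", , drop = FALSE]
  first <- tapply(des$year, des$site_id, min)
  ids <- vapply(sites, function(s) s$site_id, "")
  truth <- data.frame(site_id = ids,
                      first_designated_year = as.numeric(first[ids]),
                      stringsAsFactors = FALSE)
  list(registry = registry, truth = truth)
}

#' Generate a full scenario bundle
#'
#' Composes the intensity field, region tessellations, site polygons, age
#' registry and barrier geometry into one reproducible bundle with its
#' planted ground truth. With `protection_factor = 1` interior and exterior
#' barrier intensity are identical in distribution; with `f < 1` interiors
#' are systematically less fragmented.
#'
#' @param config a `scenario_config`.
#' @return An object of class `scenario_bundle`: list with `config`,
#'   `field`, `regions`, `sites`, `registry`, `barrier`, `ground_truth`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  field <- generate_field(config)
  regions <- generate_regions(config)
  sites <- generate_sites(config, regions_biogeo = regions$biogeo)
  reg <- generate_registry(config, sites)
  barrier <- generate_barriers(config, sites = sites, field = field)
  structure(list(
    config = config, field = field, regions = regions, sites = sites,
    registry = reg$registry, barrier = barrier,
    ground_truth = list(protection_factor = config$protection_factor,
                        first_designated_year = reg$truth,
                        n_lines = attr(barrier, "n_lines"),
                        n_settlements = attr(barrier, "n_settlements"))
  ), class = "scenario_bundle")
}
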