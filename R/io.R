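# File formats: ESRI ASCII grid for rasters (plain text, georeferenced by
# corner + cellsize), GeoJSON for site polygons, CSV for tables. All numeric
# CSV output uses "." as decimal separator regardless of locale; the Inf
# density sentinel is serialized as the literal string "inf".

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param mat numeric/logical matrix with row 1 at the grid origin (bottom);
#'   written top row first as the format requires.
#' @param path output path (.asc).
#' @param origin_x,origin_y lower-left corner (km).
#' @param cellsize cell edge (km).
#' @export
write_asc <- function(mat, path, origin_x = 0, origin_y = 0, cellsize = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(mat)),
               sprintf("nrows %d", nrow(mat)),
               sprintf("xllcorner %.10g", origin_x),
               sprintf("yllcorner %.10g", origin_y),
               sprintf("cellsize %.10g", cellsize),
               "NODATA_value -9999"), con)
  m <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  storage.mode(m) <- "double"
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(m[i, ], format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path input path.
#' @return list with `mat` (row 1 at the bottom), `origin_x`, `origin_y`,
#'   `cellsize`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  ncols <- as.integer(vals["ncols"]); nrows <- as.integer(vals["nrows"])
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != ncols * nrows) stop("corrupt ASCII grid: cell count mismatch")
  m <- matrix(body, nrows, ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]
  list(mat = m, origin_x = unname(vals["xllcorner"]),
       origin_y = unname(vals["yllcorner"]), cellsize = unname(vals["cellsize"]))
}

#' Write a barrier grid (.asc, 1 = barrier, 0 = open)
#' @param barrier a `barrier_grid`.
#' @param path output path.
#' @export
write_barrier_asc <- function(barrier, path) {
  g <- barrier$grid
  write_asc(barrier$mask * 1L, path, g$origin_x, g$origin_y, subcell_size(g))
}

#' Read a barrier grid from an ASCII grid
#' @param path input path.
#' @param cell_size reporting-cell edge (km, default 1); the subcell factor
#'   is inferred from the file's cellsize.
#' @export
read_barrier_asc <- function(path, cell_size = 1) {
  a <- read_asc(path)
  f <- round(cell_size / a$cellsize)
  if (abs(f * a$cellsize - cell_size) > 1e-6 * cell_size)
    stop("file cellsize is not an integer subdivision of the reporting cell")
  nr <- nrow(a$mat) / f; nc <- ncol(a$mat) / f
  if (nr != round(nr) || nc != round(nc))
    stop("grid dimensions are not a multiple of the subcell factor")
  g <- grid_spec(nr, nc, cell_size, a$origin_x, a$origin_y, subcell_factor = f)
  barrier_grid(g, a$mat != 0)
}

#' Write a mesh raster (.asc, km2 values, procedure recorded in a sidecar tag)
#' @param mesh a `mesh_raster`.
#' @param path output path; a `path.procedure.txt` sidecar records CBC/CUT.
#' @export
write_mesh_asc <- function(mesh, path) {
  g <- mesh$grid
  write_asc(mesh$meff, path, g$origin_x, g$origin_y, g$cell_size)
  writeLines(mesh$procedure, paste0(path, ".procedure.txt"))
  invisible(path)
}

#' Read a mesh raster from an ASCII grid
#'
#' Accepts externally produced per-cell mesh-size rasters (km2 at reporting
#' resolution), bypassing the barrier-to-patch stage.
#'
#' @param path input path.
#' @param subcell_factor recorded on the grid spec (default 10).
#' @export
read_mesh_asc <- function(path, subcell_factor = 10) {
  a <- read_asc(path)
  g <- grid_spec(nrow(a$mat), ncol(a$mat), a$cellsize, a$origin_x, a$origin_y,
                 subcell_factor = subcell_factor)
  proc_file <- paste0(path, ".procedure.txt")
  proc <- if (file.exists(proc_file)) readLines(proc_file, n = 1) else "external"
  if (!proc %in% c("CBC", "CUT")) proc <- "external"
  mesh_raster(g, a$mat, proc)
}

#' Write site polygons as GeoJSON
#' @param sites list of `site_polygon`s.
#' @param path output path (.geojson).
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- lapply(sites, function(s) {
    coords <- lapply(s$rings, function(r) {
      rc <- rbind(r, r[1, , drop = FALSE]) # close the ring
      lapply(seq_len(nrow(rc)), function(i) c(rc[i, 1], rc[i, 2]))
    })
    geom <- if (length(coords) == 1)
      list(type = "Polygon", coordinates = coords)
    else
      list(type = "MultiPolygon", coordinates = lapply(coords, list))
    list(type = "Feature",
         properties = list(site_id = s$site_id, is_marine = s$is_marine,
                           biogeo_region = s$biogeo_region,
                           admin_region = s$admin_region),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read site polygons from GeoJSON
#' @param path input path; features need `site_id`, `is_marine`,
#'   `biogeo_region` properties.
#' @export
read_sites_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  lapply(j$features, function(f) {
    ring_from <- function(ring_json) {
      m <- do.call(rbind, lapply(ring_json, function(p) c(p[[1]], p[[2]])))
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    }
    geom <- f$geometry
    rings <- if (geom$type == "Polygon") {
      lapply(geom$coordinates, ring_from)
    } else if (geom$type == "MultiPolygon") {
      lapply(geom$coordinates, function(pp) ring_from(pp[[1]]))
    } else stop("unsupported geometry type: ", geom$type)
    pr <- f$properties
    site_polygon(pr$site_id, rings,
                 is_marine = isTRUE(pr$is_marine),
                 biogeo_region = if (is.null(pr$biogeo_region)) NA_character_ else pr$biogeo_region,
                 admin_region = if (is.null(pr$admin_region)) NA_character_ else pr$admin_region)
  })
}

fmt_cell <- function(x) {
  if (is.numeric(x)) {
    out <- formatC(x, format = "g", digits = 6)
    out[is.na(x)] <- ""
    out[is.infinite(x) & x > 0] <- "inf"
    out[is.infinite(x) & x < 0] <- "-inf"
    out
  } else {
    out <- as.character(x)
    out[is.na(out)] <- ""
    out
  }
}

#' Write an analysis table as CSV
#'
#' Fixed column order, UTF-8, "." decimal, 6 significant digits, `Inf`
#' serialized as `"inf"`; deterministic byte-for-byte given equal input.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an analysis table written by [write_table_csv()]
#' @param path input path.
#' @export
read_table_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v)) {
      w <- v
      if (all(w %in% c("TRUE", "FALSE", "")) && any(w != "")) {
        v[v == ""] <- NA
        df[[nm]] <- as.logical(v)
        next
      }
      w[w == "inf"] <- "Inf"; w[w == "-inf"] <- "-Inf"
      suppressWarnings(num <- as.numeric(w))
      if (all(is.na(num) == (w == "" | is.na(w)))) {
        num[w == ""] <- NA
        if (!all(w == "" | is.na(w))) { df[[nm]] <- num; next }
      }
      v[v == ""] <- NA
      df[[nm]] <- v
    }
  }
  df
}
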