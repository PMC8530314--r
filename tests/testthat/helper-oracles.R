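# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms/code paths than the package internals.

# Queue-based flood fill (4-connectivity) over a logical barrier mask;
# returns the multiset of patch subcell counts.
oracle_patch_counts <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- mask # barrier counts as seen
  counts <- numeric(0)
  for (start in which(!seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    n <- 0
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      n <- n + 1
      i <- ((cur - 1) %% nr) + 1
      j <- ((cur - 1) %/% nr) + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] < 1 || nb[1] > nr || nb[2] < 1 || nb[2] > nc) next
        idx <- (nb[2] - 1) * nr + nb[1]
        if (!seen[idx]) { seen[idx] <- TRUE; queue <- c(queue, idx) }
      }
    }
    counts <- c(counts, n)
  }
  sort(counts)
}

# Point-in-polygon through mgcv's independent implementation (single ring).
oracle_in_polygon <- function(ring, x, y) {
  bnd <- rbind(ring, ring[1, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, cbind(x, y)))
}

# Plain-R point-to-polygon distance (0 inside), single ring.
oracle_dist_polygon <- function(ring, x, y) {
  n <- nrow(ring)
  inside <- oracle_in_polygon(ring, x, y)
  d <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- ring[i, 1]; ay <- ring[i, 2]
    bx <- ring[j, 1]; by <- ring[j, 2]
    vx <- bx - ax; vy <- by - ay
    l2 <- vx^2 + vy^2
    t <- if (l2 > 0) pmax(0, pmin(1, ((x - ax) * vx + (y - ay) * vy) / l2)) else 0
    d <- pmin(d, sqrt((ax + t * vx - x)^2 + (ay + t * vy - y)^2))
  }
  ifelse(inside, 0, d)
}

# Random simple star-shaped polygon for property tests.
random_test_polygon <- function(center, mean_radius, nv = 16) {
  th <- sort(runif(nv, 0, 2 * pi))
  r <- mean_radius * exp(runif(nv, -0.45, 0.45))
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Random barrier landscape for mesh-metric property tests.
random_landscape <- function(seed, n = 20, f = 10, road_intensity = 0.8,
                             settlement_intensity = 2) {
  cfg <- scenario_config(seed = seed,
                         grid = grid_spec(n, n, 1, subcell_factor = f),
                         road_intensity = road_intensity,
                         settlement_intensity = settlement_intensity,
                         field_length_scale_km = 6, field_sd_log = 0.8,
                         n_sites = 0)
  generate_barriers(cfg)
}

# A small synthetic mesh raster with prescribed per-cell values.
flat_mesh <- function(values, n_rows, n_cols, cell_size = 1) {
  mesh_raster(grid_spec(n_rows, n_cols, cell_size), values, "CBC")
}
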