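square_site <- function(id, x0, y0, w, ...) {
  site_polygon(id, cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w)), ...)
}

test_that("site filtering excludes marine and center-less sites with reasons", {
  g <- grid_spec(10, 10, 1)
  sites <- list(
    square_site("keep", 2, 2, 3),
    square_site("marine", 5, 5, 4, is_marine = TRUE),
    site_polygon("sliver", cbind(c(0.6, 3.4, 3.4, 0.6), c(0.6, 0.6, 0.9, 0.9)))
  )
  flt <- filter_sites(sites, g)
  expect_equal(vapply(flt$retained, function(s) s$site_id, ""), "keep")
  expect_equal(flt$exclusions$reason[flt$exclusions$site_id == "marine"], "marine")
  expect_equal(flt$exclusions$reason[flt$exclusions$site_id == "sliver"], "no cell center")
  expect_error(filter_sites(list(square_site("a", 1, 1, 2), square_site("a", 4, 4, 2)), g),
               "duplicate")
})

test_that("retained set equals brute-force recomputation on a random fixture", {
  g <- grid_spec(12, 12, 1)
  set.seed(41)
  sites <- lapply(1:50, function(k) {
    site_polygon(sprintf("s%02d", k),
                 random_test_polygon(runif(2, 1, 11), runif(1, 0.2, 2)),
                 is_marine = runif(1) < 0.2)
  })
  flt <- filter_sites(sites, g)
  cc <- cell_centers(g)
  want <- vapply(sites, function(s) {
    !s$is_marine && any(oracle_in_polygon(s$rings[[1]], cc$x, cc$y))
  }, TRUE)
  expect_equal(vapply(flt$retained, function(s) s$site_id, ""),
               vapply(sites[want], function(s) s$site_id, ""))
})

test_that("interior and buffer cell sets are disjoint and match brute force", {
  g <- grid_spec(30, 30, 1)
  set.seed(42)
  cc <- cell_centers(g)
  for (k in 1:30) {
    ring <- random_test_polygon(runif(2, 6, 24), runif(1, 0.5, 4))
    st <- site_polygon("s", ring)
    asg <- assign_cells(st, g, buffer_km = 5)
    expect_length(intersect(asg$interior, asg$buffer), 0)
    inside <- oracle_in_polygon(ring, cc$x, cc$y)
    d <- oracle_dist_polygon(ring, cc$x, cc$y)
    expect_equal(asg$interior, sort(cc$cell[inside]))
    expect_equal(asg$buffer, sort(cc$cell[!inside & d <= 5]))
  }
})

test_that("one-cell site on an 11x11 grid gets the full annulus of centers", {
  g <- grid_spec(11, 11, 1)
  st <- square_site("c", 5, 5, 1) # exactly the central cell
  asg <- assign_cells(st, g, buffer_km = 5)
  expect_equal(asg$interior, 61L)
  cc <- cell_centers(g)
  d <- oracle_dist_polygon(st$rings[[1]], cc$x, cc$y)
  expect_equal(asg$buffer, sort(cc$cell[d > 0 & d <= 5]))
  expect_gt(length(asg$buffer), 0)
  # the 5-km ring around the central cell fits the 11x11 grid exactly
  expect_equal(asg$n_buffer_outside_extent, 0L)
  # a corner cell's ring reaches beyond the extent: dropped centers counted
  asg_corner <- assign_cells(square_site("k", 1, 1, 1), g, buffer_km = 5)
  expect_gt(asg_corner$n_buffer_outside_extent, 0)
  expect_length(intersect(asg_corner$interior, asg_corner$buffer), 0)
})

test_that("aggregation is the arithmetic mean and equals merged-unit CBC", {
  mesh <- flat_mesh(c(2, 4, 6, 8), 2, 2)
  expect_equal(aggregate_meff(c(1L, 2L), mesh), 3)
  expect_equal(aggregate_meff(3L, mesh), 6)
  expect_error(aggregate_meff(integer(0), mesh), "no cells")
  # additivity identity on a real landscape: the mean over a cell set equals
  # the CBC value of the merged reporting unit (computed from the patch map)
  p <- label_patches(random_landscape(8, n = 12, f = 8))
  mesh_r <- meff_cbc(p)
  set.seed(8)
  cells <- sample(grid_n_cells(p$grid), 25)
  t <- p$cell_tab[p$cell_tab$cell %in% cells, , drop = FALSE]
  merged <- sum(t$area_km2 * p$patch_area[t$patch]) /
    (length(cells) * p$grid$cell_size^2)
  expect_equal(aggregate_meff(cells, mesh_r), merged, tolerance = 1e-12)
})

test_that("site records encode densities, differences, classes and flags", {
  g <- grid_spec(4, 4, 1)
  mesh <- flat_mesh(c(rep(100, 8), rep(50, 8)), 4, 4)
  st <- square_site("s1", 0, 0, 2)
  rec <- site_record(st, list(interior = 1:8, buffer = 9:16,
                              n_buffer_outside_extent = 0L), mesh)
  expect_equal(rec$seff_within_per1000km2, 10)
  expect_equal(rec$seff_surrounding_per1000km2, 20)
  expect_equal(rec$seff_diff_per1000km2, 10)
  expect_equal(rec$diff_class, "less_fragmented")
  expect_false(rec$marginal_flag)
  expect_equal(rec$area_km2, 4)

  # identical sides: an exact tie
  mesh_eq <- flat_mesh(rep(80, 16), 4, 4)
  rec_eq <- site_record(st, list(interior = 1:8, buffer = 9:16,
                                 n_buffer_outside_extent = 0L), mesh_eq)
  expect_equal(rec_eq$seff_diff_per1000km2, 0)
  expect_equal(rec_eq$diff_class, "equal")

  # both sides at or below 0.9 meshes per 1000 km2: marginal fragmentation
  mesh_m <- flat_mesh(c(rep(2000, 8), rep(1500, 8)), 4, 4)
  rec_m <- site_record(st, list(interior = 1:8, buffer = 9:16,
                                n_buffer_outside_extent = 0L), mesh_m)
  expect_true(rec_m$marginal_flag)

  # empty buffer: surrounding undefined, flagged out of the diff statistics
  rec_nb <- site_record(st, list(interior = 1:8, buffer = integer(0),
                                 n_buffer_outside_extent = 4L), mesh)
  expect_true(is.na(rec_nb$seff_surrounding_per1000km2))
  expect_true(is.na(rec_nb$diff_class))
})

test_that("categorization respects the upper-closed interval boundaries", {
  sc <- category_scheme()
  eps <- 1e-9
  vals <- c(0, 1.5, 1.5 + eps, 10, 10 + eps, 50, 50 + eps, 250, 250 + eps, Inf)
  want <- c("very_low", "very_low", "low", "low", "medium", "medium", "high",
            "high", "very_high", "very_high")
  expect_equal(as.character(categorize(vals, sc)), want)
  expect_error(categorize(-0.1, sc), "non-negative")
})

test_that("age join uses the earliest designated year and ignores other statuses", {
  registry <- data.frame(
    site_id = c("A", "A", "B", "C", "C"),
    status = c("designated", "designated", "designated", "proposed", "proposed"),
    year = c(2004, 1985, 2015, 1990, 2001))
  ages <- join_age(c("A", "B", "C", "D"), registry, reference_year = 2017)
  expect_equal(ages, c(32, 2, NA, NA))
  # malformed years are skipped with a warning, others still join
  reg2 <- rbind(registry, data.frame(site_id = "B", status = "designated", year = "bad"))
  expect_warning(ages2 <- join_age("B", reg2, reference_year = 2017), "malformed")
  expect_equal(ages2, 2)
})

test_that("regional medians use raw values and resist outliers", {
  rec <- data.frame(
    site_id = sprintf("s%d", 1:4),
    admin_region = c("R1", "R1", "R1", "R2"),
    seff_within_per1000km2 = c(1, 2, 9, 40),
    seff_surrounding_per1000km2 = c(2, 3, 8, 60))
  rs <- regional_summary(rec)
  r1 <- rs[rs$region == "R1", ]
  expect_equal(r1$median_seff_within_per1000km2, 2)
  expect_equal(r1$median_category_within, "low")
  r2 <- rs[rs$region == "R2", ] # one-site region carries its own values
  expect_equal(r2$median_seff_within_per1000km2, 40)
  # replacing the max with 10x the max leaves the median unchanged
  rec2 <- rec
  rec2$seff_within_per1000km2[3] <- 90
  expect_equal(regional_summary(rec2)[1, "median_seff_within_per1000km2"], 2)
})
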