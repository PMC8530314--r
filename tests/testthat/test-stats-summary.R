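make_records <- function(seff_w, seff_s, area = NULL, age = NULL, region = "A") {
  n <- length(seff_w)
  data.frame(
    site_id = sprintf("s%03d", seq_len(n)),
    seff_within_per1000km2 = seff_w,
    seff_surrounding_per1000km2 = seff_s,
    seff_diff_per1000km2 = seff_s - seff_w,
    category_within = as.character(categorize(seff_w)),
    category_surrounding = as.character(categorize(seff_s)),
    diff_class = ifelse(seff_s - seff_w > 0, "less_fragmented",
                        ifelse(seff_s - seff_w < 0, "more_fragmented", "equal")),
    marginal_flag = seff_w <= 0.9 & seff_s <= 0.9,
    area_km2 = if (is.null(area)) rep(10, n) else area,
    age_years = if (is.null(age)) rep(NA_real_, n) else age,
    biogeo_region = rep_len(region, n),
    admin_region = rep_len(region, n),
    stringsAsFactors = FALSE)
}

test_that("closed-form OLS is exact on perfect fits and rejects degenerate input", {
  x <- 1:10
  f <- ols(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$p_slope, 0)
  expect_error(ols(rep(3, 5), rnorm(5)), "degenerate predictor")
  expect_error(ols(1:2, 1:2), "at least 3")
  # constant response: slope 0, R2 defined as 0
  fc <- ols(1:6, rep(4, 6))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
})

test_that("OLS agrees with lm and a normal-equations oracle to 1e-10", {
  set.seed(31)
  for (k in 1:10) {
    n <- sample(10:200, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 5))
    y <- runif(1, -3, 3) * x + rnorm(n)
    f <- ols(x, y)
    lmf <- lm(y ~ x)
    expect_equal(f$slope, unname(coef(lmf)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(lmf)[1]), tolerance = 1e-10)
    expect_equal(f$r_squared, summary(lmf)$r.squared, tolerance = 1e-10)
    expect_equal(f$p_slope, summary(lmf)$coefficients[2, 4], tolerance = 1e-8)
    beta <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
    expect_equal(c(f$intercept, f$slope), as.numeric(beta), tolerance = 1e-10)
  }
})

test_that("within~surrounding fit works on the transformed scale per region", {
  set.seed(7)
  xs <- abs(rnorm(400, 2, 1))
  ys <- pmax(0, 0.3 + 0.9 * log1p(xs) + rnorm(400, sd = 0.2))
  rec <- make_records(expm1(ys), xs, region = rep(c("A", "B"), each = 200))
  fits <- fit_within_vs_surrounding(rec, by_region = TRUE)
  expect_equal(fits$group, c("all", "A", "B"))
  expect_equal(fits$transform, rep("log1p", 3))
  expect_lt(abs(fits$slope[1] - 0.9), 0.1)
  # shuffling record order changes nothing
  fits2 <- fit_within_vs_surrounding(rec[sample(nrow(rec)), ], by_region = TRUE)
  expect_equal(fits2, fits)
  # a region with n < 3 is flagged, not fitted
  rec_small <- rec
  rec_small$biogeo_region <- "A"
  rec_small$biogeo_region[1:2] <- "B"
  f3 <- fit_within_vs_surrounding(rec_small, by_region = TRUE)
  expect_equal(f3$note[f3$group == "B"], "insufficient n")
  expect_true(is.na(f3$slope[f3$group == "B"]))
})

test_that("noise-free relationships give R2 of 1 in the density fits", {
  xs <- seq(0.5, 60, length.out = 50)
  ys <- expm1(0.3 + 0.9 * log1p(xs))
  rec <- make_records(ys, xs)
  f <- fit_within_vs_surrounding(rec)
  expect_equal(f$slope, 0.9, tolerance = 1e-10)
  expect_equal(f$intercept, 0.3, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("area and age regressions use the documented scales", {
  set.seed(11)
  area <- exp(runif(300, 0, 8))
  seff_w <- expm1(pmax(0, 3 - 0.4 * log1p(area) + rnorm(300, sd = 0.1)))
  rec <- make_records(seff_w, seff_w, area = area, age = sample(2:37, 300, TRUE))
  fa <- fit_area_vs_within(rec)
  expect_lt(fa$slope, 0) # larger sites are less fragmented by construction
  expect_equal(fa$transform, "log1p")
  fage <- fit_age_vs_diff(rec) # diff is 0 everywhere here: flat response
  expect_equal(fage$slope, 0, tolerance = 1e-12)
  expect_equal(fage$transform, "raw")
})

test_that("category tables count sites and area with unit fraction sums", {
  rec <- make_records(c(1, 5, 20, 100, 300), c(1.2, 4, 30, 60, 500),
                      area = c(10, 20, 30, 40, 50))
  tabs <- category_tables(rec)
  within <- tabs$categories[tabs$categories$side == "within", ]
  expect_equal(within$n, c(1, 1, 1, 1, 1))
  expect_equal(sum(within$n_rel), 1, tolerance = 1e-12)
  expect_equal(sum(within$area_rel), 1, tolerance = 1e-12)
  expect_equal(within$area_km2, c(10, 20, 30, 40, 50))
  expect_equal(sum(tabs$diff_class$fraction), 1, tolerance = 1e-12)
  # all sites in one category: fraction 1
  rec1 <- make_records(rep(20, 4), rep(30, 4))
  t1 <- category_tables(rec1)
  w1 <- t1$categories[t1$categories$side == "within", ]
  expect_equal(w1$n_rel[w1$category == "medium"], 1)
  # marginal flags: subset independent of diff_class
  expect_equal(tabs$marginal$fraction, 0)
})

test_that("descriptive statistics aggregate per region with a consistent total", {
  rec <- make_records(c(2, 3, 4, 5), c(3, 4, 5, 6), area = c(1, 3, 5, 7),
                      age = c(10, 20, 30, 40), region = c("A", "A", "B", "B"))
  d <- descriptive_stats(rec)
  expect_equal(d$region, c("A", "B", "Total"))
  expect_equal(d$n_sites, c(2, 2, 4))
  expect_equal(d$mean_area_km2, c(2, 6, 4))
  expect_equal(d$rel_number, c(0.5, 0.5, 1))
  expect_equal(d$rel_area, c(0.25, 0.75, 1))
  expect_equal(d$mean_age_years, c(15, 35, 25))
  # single-region fixture: shares are 100%
  d1 <- descriptive_stats(make_records(1:3, 2:4))
  expect_equal(d1$rel_number, c(1, 1))
  expect_equal(d1$rel_area, c(1, 1))
})
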