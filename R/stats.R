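#' Closed-form ordinary least squares for one predictor
#'
#' Least-squares slope and intercept, R2 = 1 - SSE/SST, and a two-sided
#' p-value for the slope from the t statistic with n - 2 degrees of freedom.
#' Implemented from the normal equations so the fitting contract has no
#' external dependency; `stats::lm` serves as an independent cross-check in
#' the test-suite, never as the implementation.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @param group,transform optional labels carried into the summary.
#' @return one-row data.frame: `group`, `transform`, `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `n`, `note`.
#' @export
ols <- function(x, y, group = "all", transform = "raw") {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite observations")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("degenerate predictor")
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - yb)^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  se <- sqrt(sse / (n - 2) / sxx)
  tstat <- if (se == 0) sign(slope) * Inf else slope / se
  p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
  if (slope == 0 && se == 0) p <- 1
  data.frame(group = group, transform = transform, slope = slope,
             intercept = intercept, r_squared = r2, p_slope = p, n = n,
             note = "", stringsAsFactors = FALSE)
}

flagged_fit <- function(group, transform, n, note) {
  data.frame(group = group, transform = transform, slope = NA_real_,
             intercept = NA_real_, r_squared = NA_real_, p_slope = NA_real_,
             n = n, note = note, stringsAsFactors = FALSE)
}

#' Regress interior on surrounding fragmentation
#'
#' Fits `seff_within ~ seff_surrounding` over all records and, optionally,
#' per biogeographical region. Both sides are log(x+1) transformed by
#' default (the transform that brings the strongly right-skewed density
#' distributions close to normality); coefficients are reported on the
#' transformed scale and tagged accordingly. Records without a defined
#' (finite) surrounding density are dropped; regions with fewer than 3 such
#' records yield a row flagged `"insufficient n"`.
#'
#' @param records data.frame of site records.
#' @param by_region also fit one model per `biogeo_region`.
#' @param transform `"log1p"` (default) or `"raw"`.
#' @return data.frame of regression summaries (first row: overall fit).
#' @export
fit_within_vs_surrounding <- function(records, by_region = FALSE,
                                      transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  tr <- if (transform == "log1p") function(v) log1p(v) else identity
  ok <- is.finite(records$seff_within_per1000km2) &
        is.finite(records$seff_surrounding_per1000km2)
  r <- records[ok, , drop = FALSE]
  fits <- ols(tr(r$seff_surrounding_per1000km2), tr(r$seff_within_per1000km2),
              group = "all", transform = transform)
  if (by_region) {
    for (g in sort(unique(r$biogeo_region))) {
      rr <- r[!is.na(r$biogeo_region) & r$biogeo_region == g, , drop = FALSE]
      f <- if (nrow(rr) < 3) flagged_fit(g, transform, nrow(rr), "insufficient n")
           else ols(tr(rr$seff_surrounding_per1000km2),
                    tr(rr$seff_within_per1000km2), group = g, transform = transform)
      fits <- rbind(fits, f)
    }
  }
  fits
}

#' Regress interior fragmentation on site area
#'
#' Site area (km2) as predictor, interior density as response; log(x+1) on
#' both sides by default for comparability with the within~surrounding fit
#' (raw scale available behind the flag).
#'
#' @inheritParams fit_within_vs_surrounding
#' @export
fit_area_vs_within <- function(records, transform = c("log1p", "raw")) {
  transform <- match.arg(transform)
  tr <- if (transform == "log1p") function(v) log1p(v) else identity
  ok <- is.finite(records$area_km2) & is.finite(records$seff_within_per1000km2)
  r <- records[ok, , drop = FALSE]
  ols(tr(r$area_km2), tr(r$seff_within_per1000km2),
      group = "area_vs_within", transform = transform)
}

#' Regress the fragmentation difference on site age
#'
#' Age (years since first designation) as predictor and
#' `seff_diff = seff_surrounding - seff_within` as response, on the raw
#' scale (the difference can be negative). Records with missing age or
#' undefined difference are excluded.
#'
#' @param records data.frame of site records.
#' @export
fit_age_vs_diff <- function(records) {
  ok <- is.finite(records$age_years) & is.finite(records$seff_diff_per1000km2)
  r <- records[ok, , drop = FALSE]
  ols(r$age_years, r$seff_diff_per1000km2, group = "age_vs_diff", transform = "raw")
}

#' Category, difference-class and marginal tables
#'
#' Absolute and relative site counts and area coverage per fragmentation
#' category (for the interior and the surrounding side), the distribution of
#' difference classes, and the marginal-fragmentation fraction. Relative
#' columns each sum to 1 over defined records.
#'
#' @param records data.frame of site records.
#' @param scheme a `category_scheme` (defines the category order).
#' @return list with data.frames `categories` (columns `side`, `category`,
#'   `n`, `n_rel`, `area_km2`, `area_rel`), `diff_class` (`class`, `n`,
#'   `fraction`), and `marginal` (`n`, `n_defined`, `fraction`).
#' @export
category_tables <- function(records, scheme = category_scheme()) {
  side_tab <- function(cat_col, side) {
    cat <- factor(records[[cat_col]], levels = scheme$labels)
    keep <- !is.na(cat)
    n <- as.integer(table(cat[keep]))
    area <- as.numeric(tapply(records$area_km2[keep], cat[keep], sum, default = 0))
    data.frame(side = side, category = scheme$labels, n = n,
               n_rel = if (sum(n) > 0) n / sum(n) else rep(NA_real_, length(n)),
               area_km2 = area,
               area_rel = if (sum(area) > 0) area / sum(area) else rep(NA_real_, length(area)),
               stringsAsFactors = FALSE)
  }
  categories <- rbind(side_tab("category_within", "within"),
                      side_tab("category_surrounding", "surrounding"))
  dc <- factor(records$diff_class,
               levels = c("less_fragmented", "equal", "more_fragmented"))
  nd <- as.integer(table(dc[!is.na(dc)]))
  diff_class <- data.frame(class = levels(dc), n = nd,
                           fraction = if (sum(nd) > 0) nd / sum(nd) else rep(NA_real_, 3),
                           stringsAsFactors = FALSE)
  mf <- records$marginal_flag
  n_def <- sum(!is.na(mf))
  marginal <- data.frame(n = sum(mf, na.rm = TRUE), n_defined = n_def,
                         fraction = if (n_def > 0) sum(mf, na.rm = TRUE) / n_def else NA_real_)
  list(categories = categories, diff_class = diff_class, marginal = marginal)
}

#' Descriptive statistics per region
#'
#' Region-wise site counts, mean/min/max area, mean age, and shares of the
#' total site number and total site area, plus a `Total` row equal to the
#' column aggregates.
#'
#' @param records data.frame of site records.
#' @param by name of the region column (default `"biogeo_region"`).
#' @return data.frame, one row per region plus a `Total` row.
#' @export
descriptive_stats <- function(records, by = "biogeo_region") {
  reg <- records[[by]]
  keep <- !is.na(reg)
  r <- records[keep, , drop = FALSE]
  reg <- reg[keep]
  n_tot <- nrow(r)
  a_tot <- sum(r$area_km2)
  one <- function(rr, label) {
    data.frame(region = label, n_sites = nrow(rr),
               mean_area_km2 = mean(rr$area_km2),
               min_area_km2 = min(rr$area_km2),
               max_area_km2 = max(rr$area_km2),
               mean_age_years = if (any(is.finite(rr$age_years)))
                 mean(rr$age_years[is.finite(rr$age_years)]) else NA_real_,
               rel_number = nrow(rr) / n_tot,
               rel_area = sum(rr$area_km2) / a_tot,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(reg)), function(g) one(r[reg == g, , drop = FALSE], g))
  res <- do.call(rbind, c(rows, list(one(r, "Total"))))
  rownames(res) <- NULL
  res
}
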