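#' Trend residuals
#'
#' Residuals are what remains after subtracting the smoothed trend level
#' from the observed yields, `r_t = Y_t - a_t`, defined at observed years
#' only.
#'
#' @param y observed series aligned with the fit.
#' @param fit a `trend_fit` for the same years.
#' @param years year labels for `y` (default: the fit's years).
#' @return data frame `year, residual`.
#' @export
trend_residuals <- function(y, fit, years = fit$years) {
  stopifnot(inherits(fit, "trend_fit"))
  if (length(y) != length(years))
    yt_stop("alignment_error", "series and years differ in length")
  idx <- match(years, fit$years)
  if (any(is.na(idx)))
    yt_stop("alignment_error", "series years not covered by the fit")
  obs <- !is.na(y)
  data.frame(year = as.integer(years[obs]),
             residual = y[obs] - fit$a[idx][obs])
}

#' Decadal coefficient of variation
#'
#' Per decade, the CV is the standard deviation of the trend residuals
#' (denominator `n - 1`) divided by the mean of the raw yields.  Calendar
#' decades 1900-1909, ..., 2010-2016 (last truncated); decades with fewer
#' than `min_n` observations are suppressed.  Categories cut the CV at
#' 10%, 20%, 30% and 40% into classes 1-5.
#'
#' @param y raw series; `residuals` a data frame from [trend_residuals()].
#' @param years year labels for `y`.
#' @param decade_starts first years of the decades.
#' @param min_n minimum observations per decade (default 5).
#' @param category_edges inner CV edges between the 5 categories.
#' @param last_year inclusive end of the final (truncated) decade.
#' @return data frame `decade, mean_yield, sd_resid, cv, category, n`.
#' @export
decadal_cv <- function(y, residuals, years,
                       decade_starts = seq(1900L, 2010L, 10L),
                       min_n = 5L, category_edges = c(0.10, 0.20, 0.30, 0.40),
                       last_year = 2016L) {
  stopifnot(length(y) == length(years), is.data.frame(residuals))
  rows <- lapply(decade_starts, function(d0) {
    d1 <- min(d0 + 9L, last_year)
    sel_y <- years >= d0 & years <= d1 & !is.na(y)
    sel_r <- residuals$year >= d0 & residuals$year <= d1
    n <- sum(sel_r)
    if (n < min_n) return(NULL)
    m <- mean(y[sel_y])
    if (!is.finite(m) || m <= 0)
      yt_stop("undefined_cv_error",
              sprintf("non-positive decade mean in %d-%d", d0, d1))
    s <- sd(residuals$residual[sel_r])
    cv <- s / m
    data.frame(decade = d0, mean_yield = m, sd_resid = s, cv = cv,
               category = cv_category(cv, category_edges), n = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(decade = integer(0), mean_yield = numeric(0),
                      sd_resid = numeric(0), cv = numeric(0),
                      category = integer(0), n = integer(0))
  out
}

cv_category <- function(cv, edges = c(0.10, 0.20, 0.30, 0.40)) {
  as.integer(findInterval(cv, edges, left.open = TRUE)) + 1L
}

#' Taylor power-law fit of residual variability
#'
#' Ordinary least squares of `log10(sd_resid)` on `log10(mean_yield)`
#' across decade-by-department points of one crop; under Taylor's law
#' `sd = alpha * mean^beta` the slope estimates the exponent `beta`.
#'
#' @param stats data frame with columns `mean_yield` and `sd_resid`
#'   (e.g. pooled [decadal_cv()] rows).
#' @return list with `slope`, `intercept` (log10 scale), `r_squared`, `n`.
#' @export
taylor_power_fit <- function(stats) {
  use <- !is.na(stats$mean_yield) & !is.na(stats$sd_resid) &
    stats$mean_yield > 0 & stats$sd_resid > 0
  x <- log10(stats$mean_yield[use]); yv <- log10(stats$sd_resid[use])
  if (sum(use) < 3 || length(unique(x)) < 2)
    yt_stop("insufficient_data",
            "need >= 3 points with positive mean and SD, >= 2 distinct means")
  fit <- lm(yv ~ x)
  # r^2 computed directly; summary.lm warns on exact power-law input
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = stats::cor(x, yv)^2, n = sum(use))
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' `G1 = g1 * sqrt(n (n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)`.
#'
#' @param x numeric vector of residuals (length >= 3 after NA removal).
#' @export
residual_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) yt_stop("insufficient_data", "need >= 3 residuals")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  if (m2 == 0) yt_stop("undefined_skewness", "zero variance")
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Cross-department quantile trends
#'
#' Per-year min, max and the 5, 10, 25, 50, 75, 90 and 95% empirical
#' quantiles (linear interpolation between order statistics) of yields
#' across departments, for one crop.
#'
#' @param panel a `yield_panel`.
#' @param crop crop name.
#' @param season_type season type (default `"aggregate"`; use `NULL` to
#'   pool all season types).
#' @param probs quantile probabilities.
#' @return data frame with one row per year: `year, n_depts, min, max` and
#'   one `q*` column per probability; years with a single department are
#'   flagged `degenerate`.
#' @export
quantile_trends <- function(panel, crop, season_type = "aggregate",
                            probs = c(0.05, 0.10, 0.25, 0.50, 0.75,
                                      0.90, 0.95)) {
  stopifnot(inherits(panel, "yield_panel"))
  sub <- panel[panel$crop == crop & !is.na(panel$yield_t_ha), , drop = FALSE]
  if (!is.null(season_type))
    sub <- sub[sub$season_type == season_type, , drop = FALSE]
  rows <- lapply(sort(unique(sub$year)), function(yr) {
    v <- sub$yield_t_ha[sub$year == yr]
    q <- quantile(v, probs = probs, type = 7, names = FALSE)
    out <- data.frame(year = yr, n_depts = length(v), min = min(v),
                      max = max(v), degenerate = length(v) < 2)
    out[paste0("q", sprintf("%02d", round(100 * probs)))] <- as.list(q)
    out
  })
  do.call(rbind, rows)
}

#' Cross-crop correlation of national residual series
#'
#' Pearson correlation, with two-sided p-values, of national yield-residual
#' series between every pair of crops over their maximal common span; run
#' separately for the national mean series and the 5% and 95% percentile
#' series when supplied.  Pairs sharing fewer than `min_years` common
#' years are marked not assessable (`NA`).
#'
#' @param series named list (one element per crop) of data frames
#'   `year, residual`.
#' @param min_years minimum common years (default 10).
#' @return list with `r` and `p` matrices (symmetric, unit diagonal),
#'   `n_years` matrix, and the long-format `pairs` data frame.
#' @export
cross_crop_residual_correlation <- function(series, min_years = 10L) {
  stopifnot(is.list(series), length(series) >= 2, !is.null(names(series)))
  crops <- names(series)
  k <- length(crops)
  r <- matrix(NA_real_, k, k, dimnames = list(crops, crops))
  p <- r
  nmat <- matrix(0L, k, k, dimnames = list(crops, crops))
  diag(r) <- 1; diag(p) <- 0
  pairs <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    a <- series[[i]]; b <- series[[j]]
    common <- intersect(a$year[!is.na(a$residual)],
                        b$year[!is.na(b$residual)])
    nmat[i, j] <- nmat[j, i] <- length(common)
    if (length(common) >= min_years) {
      ct <- cor.test(a$residual[match(common, a$year)],
                     b$residual[match(common, b$year)], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      crop_a = crops[i], crop_b = crops[j], r = r[i, j], p = p[i, j],
      n_years = length(common), significant = !is.na(p[i, j]) & p[i, j] < 0.05)
  }
  list(r = r, p = p, n_years = nmat, pairs = do.call(rbind, pairs))
}
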