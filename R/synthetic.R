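#' Random deviates from a standardized skew-normal
#'
#' Skew-normal noise with mean 0, standard deviation `sd` and sample
#' skewness targeting `skewness`; the shape parameter is solved from the
#' standard skew-normal moment formula.  Yield residuals in long panels are
#' left-skewed (severe loss years are more common than windfall years), so
#' the generator's noise family must reproduce that.
#'
#' @param n number of deviates.
#' @param sd target standard deviation (may be a vector of length `n`).
#' @param skewness target skewness, in (-0.995, 0.995).
#' @export
rskewnorm <- function(n, sd = 1, skewness = 0) {
  if (abs(skewness) >= 0.995)
    yt_stop("validation_error", "skewness target outside the skew-normal range")
  if (skewness == 0) return(rnorm(n, 0, sd))
  delta <- uniroot(function(d) sn_skewness(d) - skewness,
                   c(-0.9999, 0.9999), tol = 1e-12)$root
  u0 <- abs(rnorm(n)); u1 <- rnorm(n)
  x <- delta * u0 + sqrt(1 - delta^2) * u1
  mu <- delta * sqrt(2 / pi)
  sigma <- sqrt(1 - 2 * delta^2 / pi)
  (x - mu) / sigma * sd
}

# Skewness of a skew-normal with delta parameter d.
sn_skewness <- function(d) {
  m <- d * sqrt(2 / pi)
  (4 - pi) / 2 * m^3 / (1 - m^2)^1.5
}

#' Synthetic panel scenario
#'
#' Defines the generative model for a departmental yield panel emulating
#' the statistical structure of the historical French data: sigmoid mean
#' yield growth (roughly four-fold over the century), heteroscedastic noise
#' whose SD follows a Taylor power law in the mean, left-skewed residuals,
#' multiplicative war-period dips, sparse missingness, a small rate of
#' injected outliers (annotation errors), per-year cropping areas, and
#' fertilizer series correlated with the yield trend at a configurable
#' target.
#'
#' Stagnation is modelled after the observed pattern of the stagnating
#' French crops: a stagnating series follows its own sigmoid
#' (`stagnation_trend`) whose plateau is essentially reached by the early
#' 1990s (strong growth until about 1990, little after), and from the onset
#' year the trend drifts down at `stagnation_decline` per year — stagnation
#' subsumes slight decline, which is what the stagnating crops show after
#' the late 1990s.  Setting `stagnation_decline = 0` freezes the trend
#' exactly instead.  Non-stagnating series follow `trend`, still rising
#' through the window.  Stagnating departments are chosen per crop so that
#' their combined cropping area is as close as possible to
#' `stagnating_area_share` of the crop total.
#'
#' @param n_departments number of departments.
#' @param crops crop subset (named logistic parameters exist for
#'   `soft_wheat`, `maize`, `potatoes`; other crops reuse soft wheat's
#'   scaled by their absolute bound).
#' @param years year span.
#' @param trend list per crop: `y0` (base yield), `y_max` (logistic
#'   asymptote), `t0` (midpoint year), `k` (logistic rate per year).  The
#'   defaults give roughly four-fold realized growth from 1900 to 2016 with
#'   the asymptote still unreached, so non-stagnating series keep growing
#'   at about 1%/yr through the 1997-2016 test window (as the major French
#'   crops without stagnation do), while frozen series emulate the observed
#'   plateau (soft wheat freezing near 6.5 t/ha).
#' @param dept_spread lognormal SD of the departmental productivity
#'   multiplier.
#' @param stagnating_area_share target stagnating area fraction per crop.
#' @param stagnation_trend list per crop of logistic parameters used by
#'   stagnating series; `NULL` entries default to
#'   `list(y0 = y0, y_max = 4 * y0, t0 = 1965, k = 0.08)`: strong growth
#'   until about 1990, a near-plateau through the 1990s.
#' @param stagnation_decline relative trend change per year after the
#'   onset for stagnating series (default -0.003, the slight decline the
#'   stagnating crops show; 0 freezes the trend exactly).
#' @param onset_year stagnation onset year.
#' @param noise_alpha,noise_beta Taylor-law coefficients: `sd = alpha *
#'   mean^beta`.
#' @param skewness residual skewness target.
#' @param war_periods list of `(first, last)` year pairs.
#' @param war_factor multiplicative trend factor inside war periods.
#' @param missing_rate fraction of records with missing yield.
#' @param outlier_rate fraction of non-missing yields corrupted.
#' @param outlier_factor multiplicative corruption factor.
#' @param area_meanlog,area_sdlog lognormal department base area (ha).
#' @param fertilizer_r named target trend correlations per driver.
#' @param seed master seed; all randomness derives from it.
#' @export
yield_scenario <- function(n_departments = 16L,
                           crops = c("soft_wheat", "maize", "potatoes"),
                           years = 1900:2016,
                           trend = list(
                             soft_wheat = list(y0 = 1.75, y_max = 10.5,
                                               t0 = 2004, k = 0.035),
                             maize = list(y0 = 2.2, y_max = 13.2,
                                          t0 = 2004, k = 0.035),
                             potatoes = list(y0 = 7, y_max = 42,
                                             t0 = 2004, k = 0.035)),
                           dept_spread = 0.10,
                           stagnating_area_share = 0.6,
                           stagnation_trend = NULL,
                           stagnation_decline = -0.003,
                           onset_year = 1997L,
                           noise_alpha = 0.175, noise_beta = 0.7,
                           skewness = -0.2,
                           war_periods = list(c(1914L, 1918L),
                                              c(1939L, 1945L)),
                           war_factor = 0.7,
                           missing_rate = 0.02,
                           outlier_rate = 0.02, outlier_factor = 12,
                           area_meanlog = log(3e4), area_sdlog = 0.8,
                           fertilizer_r = c(N = 0.7, K2O = 0.35, P2O5 = 0),
                           seed = 42L) {
  if (is.null(stagnation_trend)) stagnation_trend <- list()
  for (crop in crops) {
    if (is.null(stagnation_trend[[crop]]) && !is.null(trend[[crop]]))
      stagnation_trend[[crop]] <- list(y0 = trend[[crop]]$y0,
                                       y_max = 4 * trend[[crop]]$y0,
                                       t0 = 1965, k = 0.08)
  }
  scn <- list(n_departments = as.integer(n_departments), crops = crops,
              years = as.integer(years), trend = trend,
              dept_spread = dept_spread,
              stagnating_area_share = stagnating_area_share,
              stagnation_trend = stagnation_trend,
              stagnation_decline = stagnation_decline,
              onset_year = as.integer(onset_year),
              noise_alpha = noise_alpha, noise_beta = noise_beta,
              skewness = skewness, war_periods = war_periods,
              war_factor = war_factor, missing_rate = missing_rate,
              outlier_rate = outlier_rate, outlier_factor = outlier_factor,
              area_meanlog = area_meanlog, area_sdlog = area_sdlog,
              fertilizer_r = fertilizer_r, seed = as.integer(seed))
  validate_scenario(scn)
  structure(scn, class = "yield_scenario")
}

validate_scenario <- function(scn) {
  bad <- character(0)
  for (crop in scn$crops) {
    tr <- scn$trend[[crop]]
    if (is.null(tr)) { bad <- c(bad, paste("trend missing for", crop)); next }
    if (!(tr$y_max > tr$y0 && tr$y0 > 0))
      bad <- c(bad, paste("trend for", crop, "needs y_max > y0 > 0"))
  }
  if (!(scn$noise_beta > 0 && scn$noise_beta <= 1))
    bad <- c(bad, "noise_beta must be in (0, 1]")
  for (f in c("missing_rate", "outlier_rate", "stagnating_area_share"))
    if (scn[[f]] < 0 || scn[[f]] > 1) bad <- c(bad, paste(f, "not in [0,1]"))
  if (abs(scn$skewness) >= 0.995) bad <- c(bad, "skewness out of range")
  if (scn$stagnation_decline >= 0.005 || scn$stagnation_decline < -0.05)
    bad <- c(bad, "stagnation_decline must be in [-0.05, 0.005)")
  if (any(scn$fertilizer_r >= 1) || any(scn$fertilizer_r < 0))
    bad <- c(bad, "fertilizer target correlations must be in [0, 1)")
  if (length(bad) > 0)
    yt_stop("validation_error",
            paste("invalid scenario:", paste(bad, collapse = "; ")))
  invisible(scn)
}

logistic_trend <- function(years, tr, mult = 1) {
  mult * (tr$y0 + (tr$y_max - tr$y0) / (1 + exp(-tr$k * (years - tr$t0))))
}

# Choose the department subset whose area share is closest to the target.
pick_stagnating <- function(areas, target) {
  ord <- sample(seq_along(areas))
  share <- cumsum(areas[ord]) / sum(areas)
  n_in <- which.min(abs(share - target))
  if (target == 0) return(rep(FALSE, length(areas)))
  sel <- rep(FALSE, length(areas))
  sel[ord[seq_len(n_in)]] <- TRUE
  sel
}

#' Generate a synthetic yield panel with ground truth
#'
#' @param scn a [yield_scenario()].
#' @return list with `panel` (a `yield_panel`), and `truth` containing
#'   `trend` (per record: true trend level and relative growth), `series`
#'   (per crop-department: stagnating flag, onset year, department
#'   multiplier, base area), `outliers` (corrupted record keys with the
#'   uncorrupted value), and the scenario.
#' @export
generate_panel <- function(scn) {
  stopifnot(inherits(scn, "yield_scenario"))
  set.seed(scn$seed)
  years <- scn$years
  T <- length(years)
  depts <- sprintf("D%02d", seq_len(scn$n_departments))

  war <- rep(1, T)
  for (wp in scn$war_periods)
    war[years >= wp[1] & years <= wp[2]] <- scn$war_factor

  mult <- setNames(exp(rnorm(scn$n_departments, 0, scn$dept_spread)), depts)
  base_area <- setNames(
    exp(rnorm(scn$n_departments, scn$area_meanlog, scn$area_sdlog)), depts)

  records <- list(); truth_trend <- list(); truth_series <- list()
  outliers <- list()
  for (crop in scn$crops) {
    tr <- scn$trend[[crop]]
    stag <- pick_stagnating(base_area, scn$stagnating_area_share)
    names(stag) <- depts
    for (d in depts) {
      if (stag[[d]]) {
        base <- logistic_trend(years, scn$stagnation_trend[[crop]], mult[[d]])
        frozen <- base[match(scn$onset_year, years)]
        post <- years >= scn$onset_year
        base[post] <- frozen *
          (1 + scn$stagnation_decline)^(years[post] - scn$onset_year)
      } else {
        base <- logistic_trend(years, tr, mult[[d]])
      }
      g_true <- c(NA, diff(base)) / base
      mean_t <- base * war
      sd_t <- scn$noise_alpha * mean_t^scn$noise_beta
      noise <- rskewnorm(T, sd = sd_t, skewness = scn$skewness)
      y <- pmax(mean_t + noise, 0.01 * mean_t)
      area <- base_area[[d]] * exp(rnorm(T, 0, 0.05))
      prod <- y * area

      miss <- runif(T) < scn$missing_rate
      y[miss] <- NA; prod[miss] <- NA
      out_sel <- !miss & runif(T) < scn$outlier_rate
      if (any(out_sel)) {
        outliers[[length(outliers) + 1L]] <- data.frame(
          department_id = d, crop = crop, season_type = "aggregate",
          year = years[out_sel], true_yield = y[out_sel],
          stringsAsFactors = FALSE)
        y[out_sel] <- y[out_sel] * scn$outlier_factor
      }

      records[[length(records) + 1L]] <- data.frame(
        department_id = d, crop = crop, season_type = "aggregate",
        year = years, area_ha = area, production_t = prod, yield_t_ha = y,
        stringsAsFactors = FALSE)
      truth_trend[[length(truth_trend) + 1L]] <- data.frame(
        department_id = d, crop = crop, year = years, trend = mean_t,
        g = g_true, stringsAsFactors = FALSE)
      truth_series[[length(truth_series) + 1L]] <- data.frame(
        department_id = d, crop = crop, stagnating = stag[[d]],
        onset_year = if (stag[[d]]) scn$onset_year else NA_integer_,
        multiplier = mult[[d]], base_area = base_area[[d]],
        stringsAsFactors = FALSE)
    }
  }

  panel <- yield_panel(do.call(rbind, records),
                       year_range = range(years), check_yield = FALSE)
  truth <- list(
    trend = do.call(rbind, truth_trend),
    series = do.call(rbind, truth_series),
    outliers = if (length(outliers) > 0) do.call(rbind, outliers) else
      data.frame(department_id = character(0), crop = character(0),
                 season_type = character(0), year = integer(0),
                 true_yield = numeric(0)),
    scenario = scn)
  list(panel = panel, truth = truth)
}

#' Generate department-level fertilizer driver series
#'
#' Each driver is built as `c * (department mean yield trend) + noise` over
#' 1946-2013, with the noise variance solved in closed form so that the
#' correlation with the trend signal equals the scenario target:
#' `var(noise) = var(signal) * (1 - r^2) / r^2`.  A target of 0 yields an
#' independent pure-noise series; targets of 1 or more are rejected (no
#' finite noise variance attains them).
#'
#' @param scn the [yield_scenario()].
#' @param truth ground truth from [generate_panel()].
#' @param span inclusive driver year span (default 1946-2013).
#' @return data frame `department_id, driver, year, value` (tonnes).
#' @export
generate_drivers <- function(scn, truth, span = c(1946L, 2013L)) {
  stopifnot(inherits(scn, "yield_scenario"))
  if (any(scn$fertilizer_r >= 1))
    yt_stop("validation_error",
            "target correlation >= 1 requires zero noise variance")
  set.seed(derive_seed(scn$seed, "drivers"))
  years <- span[1]:span[2]
  tt <- truth$trend[truth$trend$year %in% years, ]
  rows <- list()
  for (d in unique(tt$department_id)) {
    sig <- tapply(tt$trend[tt$department_id == d],
                  tt$year[tt$department_id == d], mean)
    sig <- as.numeric(sig)
    # scale to tonnes of nutrient at department level
    sig <- sig * 1000
    v_s <- var(sig)
    for (drv in names(scn$fertilizer_r)) {
      r <- scn$fertilizer_r[[drv]]
      val <- if (r == 0) {
        abs(rnorm(length(years), mean(sig), sd(sig)))
      } else {
        sig + rnorm(length(years), 0, sqrt(v_s * (1 - r^2) / r^2))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        department_id = d, driver = drv, year = years,
        value = pmax(val, 0), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Deterministic reference fixture
#'
#' A small crafted panel (4 departments x 3 crops x 1900-2016) used in
#' tests and documentation.  It is generated in code with a pinned seed and
#' is identical on every platform.  By construction it contains stagnating
#' and non-stagnating crop-departments and exactly one violation of each
#' outlier rule at known keys (listed in `truth$outliers` with
#' `rule`):
#'
#' * `D01 soft_wheat 1985`: yield 12 t/ha, above the 10 t/ha absolute bound;
#' * `D02 maize 1970`: yield 0.3 t/ha, more than 10-fold below the series
#'   long-term mean (the following year is softened to 4 t/ha so the
#'   recovery is not itself a 20-fold jump);
#' * `D03 maize 1959/1960`: 0.65 then 14 t/ha, a more than 20-fold
#'   year-on-year increase that stays inside the absolute and mean-ratio
#'   bands (D03's maize series is a flat 6 t/ha reference series).
#'
#' The low noise level (Taylor alpha 0.1) keeps all natural values clear of
#' the outlier rules, so the flagged set equals the injected set.
#'
#' @return list with `panel` and `truth` (as [generate_panel()], plus
#'   `truth$outliers$rule`).
#' @export
reference_fixture <- function() {
  scn <- yield_scenario(
    n_departments = 4L,
    crops = c("soft_wheat", "maize", "potatoes"),
    trend = list(
      soft_wheat = list(y0 = 1.75, y_max = 10.5, t0 = 2004, k = 0.035),
      maize = list(y0 = 2.75, y_max = 16.5, t0 = 2004, k = 0.035),
      potatoes = list(y0 = 7, y_max = 42, t0 = 2004, k = 0.035)),
    dept_spread = 0.05,
    stagnating_area_share = 0.5,
    noise_alpha = 0.10,
    missing_rate = 0.01, outlier_rate = 0,
    seed = 1900L)
  gen <- generate_panel(scn)
  panel <- gen$panel
  df <- as.data.frame(panel)
  key <- function(d, cr, yr) which(df$department_id == d & df$crop == cr &
                                     df$season_type == "aggregate" &
                                     df$year == yr)

  # flat maize reference series in D3 (also a stagnating series: zero growth)
  sel <- df$department_id == "D03" & df$crop == "maize"
  wig <- 0.2 * sin(seq_len(sum(sel)))
  df$yield_t_ha[sel] <- 6 + wig
  df$production_t[sel] <- df$yield_t_ha[sel] * df$area_ha[sel]

  inject <- function(d, cr, yr, value) {
    i <- key(d, cr, yr)
    df$yield_t_ha[i] <<- value
  }
  inject("D01", "soft_wheat", 1985, 12)     # absolute bound
  inject("D02", "maize", 1970, 0.3)         # mean-ratio, low side
  inject("D02", "maize", 1971, 4.0)         # softened recovery (not a flag)
  inject("D03", "maize", 1959, 0.65)        # jump baseline (not a flag)
  inject("D03", "maize", 1960, 14)          # jump violation

  panel <- yield_panel(df, year_range = range(scn$years), check_yield = FALSE)
  truth <- gen$truth
  truth$outliers <- data.frame(
    department_id = c("D01", "D02", "D03"),
    crop = c("soft_wheat", "maize", "maize"),
    season_type = "aggregate",
    year = c(1985L, 1970L, 1960L),
    true_yield = NA_real_,
    rule = c("absolute", "mean_ratio", "jump"),
    stringsAsFactors = FALSE)
  truth$series$stagnating[truth$series$department_id == "D03" &
                            truth$series$crop == "maize"] <- TRUE
  truth$series$onset_year[truth$series$department_id == "D03" &
                            truth$series$crop == "maize"] <- 1900L
  list(panel = panel, truth = truth)
}
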