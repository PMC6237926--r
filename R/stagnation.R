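#' Configuration for stagnation detection
#'
#' Yields are scored as stagnating when their annual *relative* growth rate
#' predominantly stays inside an equivalence interval around a low detection
#' threshold.  Defaults: interval 0 to 0.5%/yr centred on 0.25%/yr, test
#' window 1997-2016 (the last 20 data years), a series is "likely
#' stagnating" when the overall score is at least 0.5.
#'
#' @param interval `(L, U)` relative-growth bounds (fraction/yr).
#' @param threshold detection threshold, the interval centre.
#' @param window inclusive `(first, last)` test years.
#' @param likely_cutoff overall-score cutoff for the likely flag.
#' @param score_table named scores for positions `P1`..`P10`, see
#'   [classify_position()] and [default_score_table()].
#' @export
stagnation_config <- function(interval = c(0, 0.005), threshold = 0.0025,
                              window = c(1997L, 2016L), likely_cutoff = 0.5,
                              score_table = default_score_table()) {
  stopifnot(length(interval) == 2, interval[1] < threshold,
            threshold < interval[2], window[1] <= window[2],
            all(score_table >= 0 & score_table <= 1),
            setequal(names(score_table), paste0("P", 1:10)))
  structure(list(interval = as.numeric(interval), threshold = threshold,
                 window = as.integer(window), likely_cutoff = likely_cutoff,
                 score_table = score_table[paste0("P", 1:10)]),
            class = "stagnation_config")
}

#' Default position scores
#'
#' Scores express confidence that the true growth rate lies below the upper
#' stagnation bound: 1 when the confidence interval lies wholly at or below
#' it, 0 when wholly above, graded by the point estimate's cell when the
#' interval straddles the bound.  Monotone under downward shifts of the
#' interval, which makes the overall score monotone in the growth path.
#'
#' @export
default_score_table <- function() {
  c(P1 = 1.0, P2 = 1.0, P3 = 1.0, P4 = 0.75, P5 = 0.5, P6 = 0.25,
    P7 = 1.0, P8 = 0.5, P9 = 0.25, P10 = 0.0)
}

# Cell of a value relative to [L, U]: below (strict), in (inclusive),
# above (strict).
interval_cell <- function(x, L, U) {
  ifelse(x < L, "below", ifelse(x > U, "above", "in"))
}

#' Classify the position of a growth-rate confidence interval
#'
#' Each of the CI's endpoints and the point estimate falls below, within or
#' above the stagnation interval `[L, U]`; under the ordering constraint
#' `low <= point <= high` exactly ten combinations are reachable, labelled
#' `P1` (wholly below) through `P10` (wholly above):
#'
#' | label | low   | point | high  |
#' |-------|-------|-------|-------|
#' | P1    | below | below | below |
#' | P2    | below | below | in    |
#' | P3    | below | in    | in    |
#' | P4    | below | below | above |
#' | P5    | below | in    | above |
#' | P6    | below | above | above |
#' | P7    | in    | in    | in    |
#' | P8    | in    | in    | above |
#' | P9    | in    | above | above |
#' | P10   | above | above | above |
#'
#' @param ci `(low, high)` confidence bounds.
#' @param point point estimate, `low <= point <= high`.
#' @param interval `(L, U)` stagnation bounds.
#' @return a label `"P1"`..`"P10"`.
#' @export
classify_position <- function(ci, point, interval = c(0, 0.005)) {
  low <- ci[1]; high <- ci[2]
  if (is.na(low) || is.na(high) || low > high)
    yt_stop("interval_error", "invalid confidence interval (low > high)")
  if (point < low || point > high)
    yt_stop("interval_error", "point estimate outside its interval")
  L <- interval[1]; U <- interval[2]
  key <- paste(interval_cell(low, L, U), interval_cell(point, L, U),
               interval_cell(high, L, U))
  lab <- c("below below below" = "P1", "below below in" = "P2",
           "below in in" = "P3", "below below above" = "P4",
           "below in above" = "P5", "below above above" = "P6",
           "in in in" = "P7", "in in above" = "P8",
           "in above above" = "P9", "above above above" = "P10")[key]
  unname(lab)
}

#' Score a fitted trend for yield stagnation
#'
#' For every window year with an estimate, the 90% CI of the relative growth
#' rate is classified with [classify_position()] and scored by the
#' configured table; the overall score is the mean of per-year scores.  For
#' a likely-stagnating series the onset year is the first year at or after
#' the window start with relative growth strictly below the upper bound.
#'
#' @param fit a `trend_fit`.
#' @param cfg a [stagnation_config()].
#' @return a `stagnation_result`: list with `per_year` (data frame `year`,
#'   `position`, `score`), `overall`, `likely`, `onset_year` (NA when not
#'   likely or never below), `n_years_scored`.
#' @export
stagnation_score <- function(fit, cfg = stagnation_config()) {
  stopifnot(inherits(fit, "trend_fit"), inherits(cfg, "stagnation_config"))
  in_window <- fit$years >= cfg$window[1] & fit$years <= cfg$window[2] &
    !is.na(fit$g)
  if (!any(in_window))
    yt_stop("not_assessable", "no window years with growth estimates")
  yrs <- fit$years[in_window]
  pos <- vapply(which(in_window), function(i)
    classify_position(c(fit$g_lo[i], fit$g_hi[i]), fit$g[i], cfg$interval),
    "")
  score <- unname(cfg$score_table[pos])
  overall <- mean(score)
  likely <- overall >= cfg$likely_cutoff
  onset <- NA_integer_
  if (likely) {
    cand <- fit$years >= cfg$window[1] & !is.na(fit$g) &
      fit$g < cfg$interval[2]
    if (any(cand)) onset <- min(fit$years[cand])
  }
  structure(list(per_year = data.frame(year = yrs, position = pos,
                                       score = score),
                 overall = overall, likely = likely, onset_year = onset,
                 n_years_scored = length(yrs)),
            class = "stagnation_result")
}

#' Onset year of stagnation
#'
#' First year at or after the window start where the relative growth rate is
#' strictly below the upper stagnation bound.  Only defined for series
#' already classified as likely stagnating.
#'
#' @inheritParams stagnation_score
#' @return the onset year, or `NA` when growth never drops below the bound.
#' @export
onset_year <- function(fit, cfg = stagnation_config()) {
  res <- stagnation_score(fit, cfg)
  if (!res$likely)
    yt_stop("contract_violation",
            "onset year is only defined for likely-stagnating series")
  res$onset_year
}

#' Cropping-area share of stagnating departments
#'
#' Area-weighted share of assessed departments classified likely
#' stagnating, for one crop.  Department weights are their cropping areas
#' averaged over window years with area data (summed across season types).
#'
#' @param results data frame with columns `department_id` and `likely`
#'   (one row per assessed department).
#' @param panel the `yield_panel` providing areas.
#' @param crop crop name.
#' @param cfg a [stagnation_config()] (for the window).
#' @return fraction in `[0, 1]`.
#' @export
area_share_stagnating <- function(results, panel, crop,
                                  cfg = stagnation_config()) {
  stopifnot(is.data.frame(results),
            all(c("department_id", "likely") %in% names(results)),
            inherits(panel, "yield_panel"))
  sub <- panel[panel$crop == crop & panel$year >= cfg$window[1] &
                 panel$year <= cfg$window[2] & !is.na(panel$area_ha), ,
               drop = FALSE]
  mean_area <- vapply(results$department_id, function(d) {
    a <- sub$area_ha[sub$department_id == d]
    if (length(a) == 0) NA_real_ else {
      # sum season types within a year, then average over years
      mean(tapply(a, sub$year[sub$department_id == d], sum))
    }
  }, 0)
  if (any(is.na(mean_area)))
    yt_stop("undefined_share_error",
            paste("no window-area data for department(s):",
                  paste(results$department_id[is.na(mean_area)],
                        collapse = ", ")))
  total <- sum(mean_area)
  if (total <= 0) yt_stop("undefined_share_error", "zero total area")
  sum(mean_area[results$likely]) / total
}

#' Compare mean yields between stagnating and non-stagnating departments
#'
#' Two-sided Welch two-sample t-test on per-department mean yields over the
#' test window.
#'
#' @param stagnating,non_stagnating numeric vectors of per-department mean
#'   yields (each of length >= 2).
#' @return list with `mean_stagnating`, `mean_non_stagnating`,
#'   `sd_stagnating`, `sd_non_stagnating`, `difference`, `p_value`.
#' @export
compare_group_yields <- function(stagnating, non_stagnating) {
  if (length(stagnating) < 2 || length(non_stagnating) < 2)
    yt_stop("insufficient_group", "each group needs >= 2 departments")
  if (sd(stagnating) == 0 && sd(non_stagnating) == 0 &&
      mean(stagnating) == mean(non_stagnating)) {
    p <- 1  # degenerate identical-constant groups; t is 0/0
  } else {
    p <- t.test(stagnating, non_stagnating, var.equal = FALSE)$p.value
  }
  list(mean_stagnating = mean(stagnating),
       mean_non_stagnating = mean(non_stagnating),
       sd_stagnating = sd(stagnating),
       sd_non_stagnating = sd(non_stagnating),
       difference = mean(stagnating) - mean(non_stagnating),
       p_value = p)
}

#' Sensitivity of the stagnating-area share to detection settings
#'
#' Recomputes per-department stagnation scores and the stagnating area
#' share over a grid of upper stagnation bounds and window start years.
#' The interval is `(0, U)` with threshold `U/2`; the window end is kept
#' from `cfg`.
#'
#' @param fits named list of `trend_fit` objects, names = department IDs.
#' @param panel the `yield_panel` providing areas.
#' @param crop crop name.
#' @param upper_bounds numeric vector of upper bounds (fraction/yr).
#' @param window_starts integer vector of window start years.
#' @param cfg base [stagnation_config()].
#' @return data frame `threshold, window_start, area_share, n_likely`.
#' @export
sensitivity_sweep <- function(fits, panel, crop,
                              upper_bounds = c(0.0025, 0.005, 0.0075),
                              window_starts = c(1992L, 1997L, 2002L),
                              cfg = stagnation_config()) {
  stopifnot(length(upper_bounds) > 0, length(window_starts) > 0)
  grid <- expand.grid(threshold = upper_bounds, window_start = window_starts,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    U <- grid$threshold[i]
    cfg_i <- stagnation_config(interval = c(cfg$interval[1], U),
                               threshold = (cfg$interval[1] + U) / 2,
                               window = c(grid$window_start[i],
                                          cfg$window[2]),
                               likely_cutoff = cfg$likely_cutoff,
                               score_table = cfg$score_table)
    likely <- vapply(fits, function(f)
      tryCatch(stagnation_score(f, cfg_i)$likely, yieldtrends_error =
                 function(e) NA), TRUE)
    res <- data.frame(department_id = names(fits), likely = likely)
    res <- res[!is.na(res$likely), , drop = FALSE]
    share <- if (nrow(res) == 0) NA_real_ else
      area_share_stagnating(res, panel, crop, cfg_i)
    data.frame(threshold = U, window_start = grid$window_start[i],
               area_share = share, n_likely = sum(res$likely))
  })
  do.call(rbind, rows)
}
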