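#' Correlation of a yield series with a driver series
#'
#' Pearson correlation over the common span of a departmental yield series
#' and an auxiliary driver series (e.g. total mineral N fertilizer, tonnes).
#' In `"raw"` mode the levels are correlated; in `"detrended"` mode a local
#' linear trend model is fitted to each series and the trend residuals are
#' correlated, which guards against spurious correlation of two rising
#' trends.
#'
#' @param y data frame `year, value` (yields).
#' @param d data frame `year, value` (driver).
#' @param mode `"raw"` or `"detrended"`.
#' @param min_years minimum common non-missing years (default 10).
#' @param min_obs minimum observations for the detrending fit (default 30).
#' @return list with `r`, `p`, `n_years`, `mode`.
#' @export
driver_correlation <- function(y, d, mode = c("raw", "detrended"),
                               min_years = 10L, min_obs = 30L) {
  mode <- match.arg(mode)
  stopifnot(all(c("year", "value") %in% names(y)),
            all(c("year", "value") %in% names(d)))
  common <- intersect(y$year[!is.na(y$value)], d$year[!is.na(d$value)])
  if (length(common) < min_years)
    yt_stop("not_assessable",
            sprintf("only %d common years (need >= %d)",
                    length(common), min_years))
  if (mode == "raw") {
    yv <- y$value[match(common, y$year)]
    dv <- d$value[match(common, d$year)]
  } else {
    yv <- detrend_on(y, common, min_obs)
    dv <- detrend_on(d, common, min_obs)
  }
  ct <- cor.test(yv, dv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_years = length(common),
       mode = mode)
}

# Fit a DLM on the series' full common-support span and return residuals at
# the requested years.
detrend_on <- function(s, years_wanted, min_obs) {
  yrs <- seq(min(s$year), max(s$year))
  v <- s$value[match(yrs, s$year)]
  fit <- fit_dlm(v, years = yrs, min_obs = min_obs)
  res <- trend_residuals(v, fit, years = yrs)
  res$residual[match(years_wanted, res$year)]
}

#' Summarize driver correlations across departments
#'
#' @param rs numeric vector of per-department correlation coefficients.
#' @param ps matching vector of p-values (optional).
#' @return list with `mean_r`, `n`, and `share_significant` (fraction with
#'   `p < 0.05`; `NA` when p-values are not supplied).
#' @export
summarize_driver_correlations <- function(rs, ps = NULL) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) yt_stop("insufficient_data", "no correlation values")
  share <- if (is.null(ps)) NA_real_ else mean(ps[!is.na(ps)] < 0.05)
  list(mean_r = mean(rs), n = length(rs), share_significant = share)
}
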