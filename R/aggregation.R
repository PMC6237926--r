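#' National area-weighted yield series
#'
#' Per year, the national mean yield is the area-weighted mean over
#' departments reporting both yield and area; departments missing either
#' are excluded that year.
#'
#' @param panel a `yield_panel`.
#' @param crop crop name.
#' @param season_type season type (default `"aggregate"`).
#' @return data frame `crop, season_type, year, mean_yield, n_depts,
#'   total_area`.
#' @export
national_aggregate <- function(panel, crop, season_type = "aggregate") {
  stopifnot(inherits(panel, "yield_panel"))
  sub <- panel[panel$crop == crop & panel$season_type == season_type &
                 !is.na(panel$yield_t_ha) & !is.na(panel$area_ha) &
                 panel$area_ha > 0, , drop = FALSE]
  rows <- lapply(sort(unique(sub$year)), function(yr) {
    g <- sub[sub$year == yr, ]
    data.frame(crop = crop, season_type = season_type, year = yr,
               mean_yield = sum(g$area_ha * g$yield_t_ha) / sum(g$area_ha),
               n_depts = nrow(g), total_area = sum(g$area_ha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(crop = character(0), season_type = character(0),
                      year = integer(0), mean_yield = numeric(0),
                      n_depts = integer(0), total_area = numeric(0))
  out
}

#' Decadal growth-rate categories
#'
#' For each crop-department fit the mean relative growth rate per decade is
#' computed, then binned into five categories (1 = lowest, negative growth;
#' 5 = strongest growth).  Category counts are normalized per decade so the
#' total over the five categories is 1 in every decade.  Default edges
#' place the stagnation detection threshold (0.25%/yr) at a bin boundary:
#' `(-Inf, 0], (0, 0.25%], (0.25%, 1%], (1%, 3%], (3%, Inf)`.
#'
#' @param fits named list of `trend_fit` objects; names identify the
#'   crop-department series (e.g. `"D01|maize|aggregate"`).
#' @param edges inner bin edges (4 increasing values, fraction/yr).
#' @param decade_starts first years of the decades.
#' @param last_year inclusive end of the final decade.
#' @param exclude optional character vector of name patterns to drop
#'   (e.g. `"wine"`).
#' @return data frame `decade, category, count, normalized_area`.
#' @export
decadal_growth_categories <- function(fits,
                                      edges = c(0, 0.0025, 0.01, 0.03),
                                      decade_starts = seq(1900L, 2010L, 10L),
                                      last_year = 2016L, exclude = NULL) {
  stopifnot(length(edges) == 4, all(diff(edges) > 0))
  if (!is.null(exclude))
    fits <- fits[!grepl(paste(exclude, collapse = "|"), names(fits))]
  rows <- list()
  for (d0 in decade_starts) {
    d1 <- min(d0 + 9L, last_year)
    means <- vapply(fits, function(f) {
      sel <- f$years >= d0 & f$years <= d1 & !is.na(f$g)
      if (!any(sel)) NA_real_ else mean(f$g[sel])
    }, 0)
    means <- means[!is.na(means)]
    counts <- integer(5)
    if (length(means) > 0) {
      cat_idx <- findInterval(means, edges, left.open = TRUE) + 1L
      counts <- tabulate(cat_idx, nbins = 5L)
    }
    norm <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, 5)
    rows[[length(rows) + 1L]] <- data.frame(
      decade = d0, category = 1:5, count = counts, normalized_area = norm)
  }
  do.call(rbind, rows)
}

#' Drop departments with small cropping area
#'
#' Departments whose long-term mean area for the crop is strictly below the
#' `q` quantile of long-term mean areas across departments are removed for
#' that crop only.  With fewer than 10 departments holding area data the
#' filter is skipped with a warning.
#'
#' @param panel a `yield_panel`.
#' @param crop crop name.
#' @param q quantile (default 0.10).
#' @return the reduced `yield_panel`; the dropped department IDs are in
#'   attribute `"dropped"`.
#' @export
filter_small_area <- function(panel, crop, q = 0.10) {
  stopifnot(inherits(panel, "yield_panel"), q >= 0, q < 1)
  sub <- panel[panel$crop == crop & !is.na(panel$area_ha), , drop = FALSE]
  mean_area <- tapply(sub$area_ha, sub$department_id, mean)
  if (length(mean_area) < 10) {
    yt_warn(sprintf(
      "filter_small_area: only %d departments with area data for %s; skipped",
      length(mean_area), crop))
    attr(panel, "dropped") <- character(0)
    return(panel)
  }
  cut <- quantile(mean_area, probs = q, type = 7, names = FALSE)
  dropped <- names(mean_area)[mean_area < cut]
  keep <- !(panel$crop == crop & panel$department_id %in% dropped)
  out <- yield_panel(as.data.frame(panel)[keep, , drop = FALSE],
                     year_range = attr(panel, "year_range"),
                     check_yield = FALSE)
  attr(out, "dropped") <- dropped
  out
}
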