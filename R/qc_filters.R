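#' Outlier rules for annual yield records
#'
#' Three single-pass rules flag suspect yields, typically annotation errors
#' in the digitized statistics: (a) an *absolute* per-crop upper bound;
#' (b) a *mean-ratio* rule flagging values more than `mean_ratio` times
#' higher or lower (on the ratio scale) than the long-term mean of their own
#' (department, crop, season) series; (c) a *jump* rule flagging more than a
#' `jump_ratio`-fold increase over the immediately preceding calendar year.
#'
#' Default bounds: 10 t/ha for wheat and barley, 100 t/ha for sugar beet,
#' 15 t/ha for maize, 8 t/ha for oats, 60 t/ha for potatoes, 5 t/ha for
#' rapeseed and sunflower, 200 hl/ha for wine.  Default mean ratio 5, with
#' maize at 10 and oats and soft wheat at 6.  Default jump ratio 20,
#' increases only.
#'
#' @param absolute_bound named per-crop numeric vector of upper yield bounds.
#' @param mean_ratio default ratio for rule (b).
#' @param mean_ratio_exceptions named per-crop overrides.
#' @param jump_ratio year-on-year increase multiplier for rule (c).
#' @param flag_jump_decrease also flag `jump_ratio`-fold decreases
#'   (default `FALSE`).
#' @export
outlier_rules <- function(absolute_bound = c(barley = 10, soft_wheat = 10,
                                             durum_wheat = 10,
                                             sugar_beet = 100, maize = 15,
                                             oats = 8, potatoes = 60,
                                             rapeseed = 5, sunflower = 5,
                                             wine = 200),
                          mean_ratio = 5,
                          mean_ratio_exceptions = c(maize = 10, oats = 6,
                                                    soft_wheat = 6),
                          jump_ratio = 20,
                          flag_jump_decrease = FALSE) {
  stopifnot(all(absolute_bound > 0), mean_ratio > 0, jump_ratio > 0,
            all(mean_ratio_exceptions > 0))
  structure(list(absolute_bound = absolute_bound,
                 mean_ratio = mean_ratio,
                 mean_ratio_exceptions = mean_ratio_exceptions,
                 jump_ratio = jump_ratio,
                 flag_jump_decrease = flag_jump_decrease),
            class = "outlier_rules")
}

rule_mean_ratio_for <- function(rules, crop) {
  if (crop %in% names(rules$mean_ratio_exceptions))
    unname(rules$mean_ratio_exceptions[crop])
  else rules$mean_ratio
}

#' Flag outlying yields
#'
#' Applies the three rules of [outlier_rules()] in a single pass over every
#' (department, crop, season) series.  The long-term mean of rule (b) is
#' computed over all non-missing raw values of the series, candidate
#' included; the operation is not iterated.  Flags are reported, not yet
#' applied — see [apply_mask()].
#'
#' @param panel a `yield_panel`.
#' @param rules an [outlier_rules()] object.
#' @param strict error if a crop present in the panel lacks an absolute
#'   bound (default `TRUE`).
#' @return a `qc_report`: list with `flagged` (data frame
#'   `department_id,crop,season_type,year,yield,rule`) and
#'   `fraction_flagged` (overall and per crop, relative to non-missing
#'   yields).  A value violating several rules appears once per rule.
#' @export
flag_outliers <- function(panel, rules = outlier_rules(), strict = TRUE) {
  stopifnot(inherits(panel, "yield_panel"), inherits(rules, "outlier_rules"))
  crops_present <- unique(panel$crop)
  uncovered <- setdiff(crops_present, names(rules$absolute_bound))
  if (length(uncovered) > 0 && strict)
    yt_stop("configuration_error",
            paste("no absolute bound for crop(s):",
                  paste(uncovered, collapse = ", ")))

  df <- as.data.frame(panel)
  flagged <- list()
  grp <- split(df, list(df$department_id, df$crop, df$season_type),
               drop = TRUE)
  for (g in grp) {
    g <- g[order(g$year), ]
    y <- g$yield_t_ha
    obs <- !is.na(y)
    if (!any(obs)) next
    crop <- g$crop[1]

    hit_abs <- rep(FALSE, nrow(g))
    if (crop %in% names(rules$absolute_bound))
      hit_abs <- obs & y > rules$absolute_bound[[crop]]

    k <- rule_mean_ratio_for(rules, crop)
    m <- mean(y[obs])
    hit_mean <- obs & (y > k * m | y < m / k)

    # jump rule: only against the immediately preceding calendar year
    hit_jump <- rep(FALSE, nrow(g))
    if (nrow(g) >= 2) {
      prev_idx <- match(g$year - 1L, g$year)
      prev <- y[prev_idx]
      comparable <- obs & !is.na(prev) & prev > 0
      hit_jump <- comparable & y > rules$jump_ratio * prev
      if (isTRUE(rules$flag_jump_decrease))
        hit_jump <- hit_jump | (comparable & y < prev / rules$jump_ratio)
    }

    for (rule in c("absolute", "mean_ratio", "jump")) {
      hit <- switch(rule, absolute = hit_abs, mean_ratio = hit_mean,
                    jump = hit_jump)
      if (any(hit))
        flagged[[length(flagged) + 1L]] <- data.frame(
          department_id = g$department_id[hit], crop = g$crop[hit],
          season_type = g$season_type[hit], year = g$year[hit],
          yield = y[hit], rule = rule, stringsAsFactors = FALSE)
    }
  }

  flagged <- if (length(flagged) > 0) do.call(rbind, flagged) else
    data.frame(department_id = character(0), crop = character(0),
               season_type = character(0), year = integer(0),
               yield = numeric(0), rule = character(0))
  flagged <- flagged[order(flagged$crop, flagged$department_id,
                           flagged$season_type, flagged$year, flagged$rule), ]
  rownames(flagged) <- NULL

  n_obs_total <- sum(!is.na(df$yield_t_ha))
  uniq <- unique(flagged[, c("department_id", "crop", "season_type", "year")])
  per_crop <- vapply(crops_present, function(cr) {
    n <- sum(!is.na(df$yield_t_ha[df$crop == cr]))
    if (n == 0) return(NA_real_)
    nrow(unique(flagged[flagged$crop == cr,
                        c("department_id", "season_type", "year")])) / n
  }, 0)
  structure(list(
    flagged = flagged,
    fraction_flagged = list(
      overall = if (n_obs_total > 0) nrow(uniq) / n_obs_total else NA_real_,
      per_crop = per_crop)
  ), class = "qc_report")
}

#' Mask flagged yields as missing
#'
#' Flagged yields are set to `NA`; no correction is attempted, and area and
#' production are untouched.  Idempotent.
#'
#' @param panel the `yield_panel` the report was computed from.
#' @param report a `qc_report` from [flag_outliers()].
#' @return the masked `yield_panel`.
#' @export
apply_mask <- function(panel, report) {
  stopifnot(inherits(panel, "yield_panel"), inherits(report, "qc_report"))
  if (nrow(report$flagged) == 0) return(panel)
  keys <- record_key(panel)
  hit_keys <- unique(record_key(report$flagged))
  absent <- setdiff(hit_keys, keys)
  if (length(absent) > 0)
    yt_stop("integrity_error",
            paste("flagged key(s) absent from panel:",
                  paste(head(absent, 5), collapse = "; ")))
  panel$yield_t_ha[keys %in% hit_keys] <- NA_real_
  panel
}
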