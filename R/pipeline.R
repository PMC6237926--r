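#' Combine spring and winter series into aggregate series
#'
#' Where a (department, crop) has spring and/or winter records but no
#' aggregate record for a year, an aggregate record is formed by summing
#' areas and productions over the season types present and recomputing the
#' yield — the combination happens before any trend fitting, so a shift
#' from spring to winter cultivars shows up in the combined series.
#'
#' @param panel a `yield_panel`.
#' @return the panel with aggregate records added.
#' @export
combine_seasons <- function(panel) {
  stopifnot(inherits(panel, "yield_panel"))
  df <- as.data.frame(panel)
  seasonal <- df[df$season_type %in% c("spring", "winter"), , drop = FALSE]
  if (nrow(seasonal) == 0) return(panel)
  have_agg <- unique(df[df$season_type == "aggregate",
                        c("department_id", "crop", "year")])
  combo <- do.call(rbind, lapply(
    split(seasonal,
          list(seasonal$department_id, seasonal$crop, seasonal$year),
          drop = TRUE),
    function(g) {
      area <- if (all(is.na(g$area_ha))) NA_real_ else
        sum(g$area_ha, na.rm = TRUE)
      prod <- if (all(is.na(g$production_t))) NA_real_ else
        sum(g$production_t, na.rm = TRUE)
      data.frame(department_id = g$department_id[1], crop = g$crop[1],
                 season_type = "aggregate", year = g$year[1],
                 area_ha = area, production_t = prod,
                 yield_t_ha = if (!is.na(area) && area > 0 && !is.na(prod))
                   prod / area else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  dup <- paste(combo$department_id, combo$crop, combo$year) %in%
    paste(have_agg$department_id, have_agg$crop, have_agg$year)
  yield_panel(rbind(df, combo[!dup, , drop = FALSE]),
              year_range = attr(panel, "year_range"), check_yield = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end on a panel (or a generated scenario):
#' quality filtering, per-series trend fits (series with fewer than
#' `min_obs` observations are skipped and logged), stagnation scoring,
#' variability statistics, era clustering, driver correlations, national
#' aggregation and growth categories.  A failing series is logged and the
#' pipeline continues with the remaining series.
#'
#' @param panel a `yield_panel`, or `NULL` to generate one from `scenario`.
#' @param scenario a [yield_scenario()] used when `panel` is `NULL`.
#' @param drivers optional driver data frame
#'   (`department_id, driver, year, value`); generated from the scenario
#'   when `NULL` and the scenario is used.
#' @param rules [outlier_rules()] for the QC stage.
#' @param cfg [stagnation_config()] for the stagnation stage.
#' @param stages character subset of
#'   `c("qc", "trend", "stagnation", "variability", "clustering",
#'   "drivers", "aggregation")`.
#' @param min_obs minimum observations per series for trend fitting.
#' @param out_dir optional directory: results are written as CSVs plus a
#'   manifest via [write_results()].
#' @param verbose print per-stage progress.
#' @return list of result tables: `qc_flags`, `stagnation`, `cv`,
#'   `national`, `growth_categories`, `clusters`, `driver_correlations`,
#'   plus `fits` (named list of `trend_fit`s), `panel` (the masked panel),
#'   `skipped` (series skipped for lack of data) and `log`.
#' @export
run_pipeline <- function(panel = NULL, scenario = NULL, drivers = NULL,
                         rules = outlier_rules(),
                         cfg = stagnation_config(),
                         stages = c("qc", "trend", "stagnation",
                                    "variability", "clustering", "drivers",
                                    "aggregation"),
                         min_obs = 30, out_dir = NULL, verbose = FALSE) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (verbose) message(msg)
  }
  truth <- NULL
  if (is.null(panel)) {
    stopifnot(inherits(scenario, "yield_scenario"))
    gen <- generate_panel(scenario)
    panel <- gen$panel
    truth <- gen$truth
    if (is.null(drivers) && "drivers" %in% stages)
      drivers <- generate_drivers(scenario, truth)
    say("generated panel: %d records, seed %d", nrow(panel), scenario$seed)
  }
  panel <- combine_seasons(panel)
  out <- list(log = NULL, truth = truth)

  if ("qc" %in% stages) {
    report <- flag_outliers(panel, rules)
    panel <- apply_mask(panel, report)
    out$qc_flags <- report$flagged
    out$qc_fraction <- report$fraction_flagged$overall
    say("qc: %d flags (%.2f%% of observations)", nrow(report$flagged),
        100 * (out$qc_fraction %||% 0))
  }
  out$panel <- panel

  fits <- list(); skipped <- character(0)
  if (any(c("trend", "stagnation", "variability", "drivers") %in% stages)) {
    combos <- unique(as.data.frame(panel)[panel$season_type == "aggregate",
                                          c("department_id", "crop")])
    for (i in seq_len(nrow(combos))) {
      d <- combos$department_id[i]; cr <- combos$crop[i]
      sub <- panel[panel$department_id == d & panel$crop == cr &
                     panel$season_type == "aggregate", ]
      yrs <- seq(min(sub$year), max(sub$year))
      y <- sub$yield_t_ha[match(yrs, sub$year)]
      key <- series_key(d, cr, "aggregate")
      fit <- tryCatch(fit_dlm(y, years = yrs, min_obs = min_obs),
                      insufficient_data = function(e) NULL,
                      yieldtrends_error = function(e) {
                        say("trend: %s failed: %s", key,
                            conditionMessage(e)); NULL
                      })
      if (is.null(fit)) skipped <- c(skipped, key) else fits[[key]] <- fit
    }
    say("trend: %d series fitted, %d skipped", length(fits), length(skipped))
  }
  out$fits <- fits
  out$skipped <- skipped

  if ("stagnation" %in% stages && length(fits) > 0) {
    rows <- list()
    for (key in names(fits)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      res <- tryCatch(stagnation_score(fits[[key]], cfg),
                      yieldtrends_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        department_id = parts[1], crop = parts[2], season_type = parts[3],
        overall_score = res$overall, likely = res$likely,
        onset_year = res$onset_year, n_years = res$n_years_scored,
        stringsAsFactors = FALSE)
    }
    out$stagnation <- do.call(rbind, rows)
    shares <- list()
    for (cr in unique(out$stagnation$crop)) {
      res_cr <- out$stagnation[out$stagnation$crop == cr, ]
      shares[[cr]] <- data.frame(
        crop = cr,
        area_share = area_share_stagnating(
          res_cr[, c("department_id", "likely")], panel, cr, cfg),
        n_assessed = nrow(res_cr), n_likely = sum(res_cr$likely),
        stringsAsFactors = FALSE)
    }
    out$stagnation_share <- do.call(rbind, shares)
    say("stagnation: %d/%d series likely", sum(out$stagnation$likely),
        nrow(out$stagnation))
  }

  if ("variability" %in% stages && length(fits) > 0) {
    cv_rows <- list()
    for (key in names(fits)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      fit <- fits[[key]]
      res <- trend_residuals(fit$y, fit)
      cv <- tryCatch(decadal_cv(fit$y, res, fit$years),
                     yieldtrends_error = function(e) NULL)
      if (is.null(cv) || nrow(cv) == 0) next
      cv$crop <- parts[2]; cv$department_id <- parts[1]
      cv_rows[[length(cv_rows) + 1L]] <- cv
    }
    out$cv <- do.call(rbind, cv_rows)
    out$taylor <- lapply(split(out$cv, out$cv$crop), function(s)
      tryCatch(taylor_power_fit(s), yieldtrends_error = function(e) NULL))
    say("variability: %d decade records", nrow(out$cv %||% data.frame()))
  }

  if ("aggregation" %in% stages) {
    nat <- list()
    for (cr in unique(panel$crop))
      nat[[cr]] <- national_aggregate(panel, cr)
    out$national <- do.call(rbind, nat)
    if (length(fits) > 0)
      out$growth_categories <- decadal_growth_categories(fits,
                                                         exclude = "wine")
  }

  if ("clustering" %in% stages) {
    cl <- list()
    for (cr in unique(panel$crop))
      cl[[cr]] <- cluster_departments(panel, cr)
    out$clusters <- do.call(rbind, cl)
    say("clustering: %d assignments", nrow(out$clusters))
  }

  if ("drivers" %in% stages && !is.null(drivers) && length(fits) > 0) {
    rows <- list()
    for (key in names(fits)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      fit <- fits[[key]]
      yser <- data.frame(year = fit$years, value = fit$y)
      for (drv in unique(drivers$driver)) {
        dser <- drivers[drivers$department_id == parts[1] &
                          drivers$driver == drv, c("year", "value")]
        if (nrow(dser) == 0) next
        for (mode in c("raw", "detrended")) {
          rc <- tryCatch(driver_correlation(yser, dser, mode),
                         yieldtrends_error = function(e) NULL)
          if (is.null(rc)) next
          rows[[length(rows) + 1L]] <- data.frame(
            crop = parts[2], driver = drv, department_id = parts[1],
            mode = mode, r = rc$r, p = rc$p, n_years = rc$n_years,
            stringsAsFactors = FALSE)
        }
      }
    }
    out$driver_correlations <- do.call(rbind, rows)
    say("drivers: %d correlations", nrow(out$driver_correlations %||%
                                           data.frame()))
  }

  out$log <- log_lines
  if (!is.null(out_dir)) {
    tables <- Filter(is.data.frame,
                     out[c("qc_flags", "stagnation", "stagnation_share",
                           "cv", "national", "growth_categories", "clusters",
                           "driver_correlations")])
    write_results(tables, out_dir,
                  config = list(stages = stages, min_obs = min_obs,
                                rules = unclass(rules), cfg = unclass(cfg)),
                  seed = if (!is.null(scenario)) scenario$seed else NULL)
  }
  out
}
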