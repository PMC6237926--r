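#' Construct and validate a yield panel
#'
#' A yield panel is a long-format data frame of annual records, one per
#' (department, crop, season type, year), holding cropping area (ha),
#' production (t; hl for wine) and yield (t/ha; hl/ha for wine).  Missing
#' values are `NA`, never zero: a zero area is a legal observation, an
#' unknown area is not.
#'
#' @param records data frame with columns `department_id`, `crop`,
#'   `season_type`, `year`, `area_ha`, `production_t`, `yield_t_ha`.
#' @param year_range allowed inclusive year span.
#' @param check_yield if `TRUE`, verify that stored yields equal
#'   production/area (relative tolerance 1e-9) wherever all three are present.
#' @return the validated panel, classed `"yield_panel"`.
#' @export
yield_panel <- function(records, year_range = c(1900L, 2016L),
                        check_yield = TRUE) {
  missing_cols <- setdiff(PANEL_COLS, names(records))
  if (length(missing_cols) > 0)
    yt_stop("schema_error", paste("missing required columns:",
                                  paste(missing_cols, collapse = ", ")))
  records <- as.data.frame(records)[, PANEL_COLS]
  records$department_id <- as.character(records$department_id)
  records$crop <- as.character(records$crop)
  records$season_type <- as.character(records$season_type)
  records$year <- as.integer(records$year)

  bad_crop <- setdiff(unique(records$crop), CROPS)
  if (length(bad_crop) > 0)
    yt_stop("schema_error", paste("unknown crop(s):",
                                  paste(bad_crop, collapse = ", ")))
  bad_season <- setdiff(unique(records$season_type), SEASON_TYPES)
  if (length(bad_season) > 0)
    yt_stop("schema_error", paste("unknown season_type(s):",
                                  paste(bad_season, collapse = ", ")))
  out_of_range <- !is.na(records$year) &
    (records$year < year_range[1] | records$year > year_range[2])
  if (any(out_of_range))
    yt_stop("schema_error",
            sprintf("%d records outside year range %d-%d",
                    sum(out_of_range), year_range[1], year_range[2]))

  for (col in c("area_ha", "production_t", "yield_t_ha")) {
    neg <- !is.na(records[[col]]) & records[[col]] < 0
    if (any(neg))
      yt_stop("validation_error",
              sprintf("negative values in %s (%d records)", col, sum(neg)))
  }

  keys <- record_key(records)
  dup <- duplicated(keys)
  if (any(dup))
    yt_stop("integrity_error",
            paste("duplicate (department, crop, season, year) key(s):",
                  paste(head(unique(keys[dup]), 5), collapse = "; ")))

  if (check_yield) {
    ok <- !is.na(records$area_ha) & records$area_ha > 0 &
      !is.na(records$production_t) & !is.na(records$yield_t_ha)
    if (any(ok)) {
      expect <- records$production_t[ok] / records$area_ha[ok]
      off <- abs(records$yield_t_ha[ok] - expect) >
        1e-9 * pmax(1, abs(expect))
      if (any(off))
        yt_stop("integrity_error",
                sprintf("%d stored yields disagree with production/area",
                        sum(off)))
    }
  }

  rownames(records) <- NULL
  structure(records, class = c("yield_panel", "data.frame"),
            year_range = as.integer(year_range))
}

#' Read a yield panel from CSV
#'
#' Expects the long header
#' `department_id,crop,season_type,year,area_ha,production_t,yield_t_ha`
#' (UTF-8, "." decimal separator, empty field = missing).  A `schema` can
#' rename source columns and rescale yields recorded in other units (the
#' historical statistics print kg/ha; all analyses here use t/ha).
#'
#' @param path CSV file path.
#' @param schema optional list with elements `columns` (named character
#'   vector mapping canonical names to source column names) and
#'   `yield_scale` (named per-crop multiplier applied to the yield column,
#'   e.g. `c(soft_wheat = 0.001)` for kg/ha input).
#' @param year_range passed to [yield_panel()].
#' @return a `yield_panel`.
#' @export
read_panel <- function(path, schema = NULL, year_range = c(1900L, 2016L)) {
  if (!file.exists(path)) yt_stop("io_error", paste("file not found:", path))
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  cols <- schema$columns %||% setNames(PANEL_COLS, PANEL_COLS)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0)
    yt_stop("schema_error", paste("missing required columns:",
                                  paste(missing_cols, collapse = ", ")))
  df <- setNames(raw[, unname(cols[PANEL_COLS]), drop = FALSE], PANEL_COLS)

  n_bad <- 0L
  for (col in c("year", "area_ha", "production_t", "yield_t_ha")) {
    txt <- trimws(df[[col]])
    txt[txt == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(txt))
    n_bad <- n_bad + sum(!is.na(txt) & is.na(num))
    df[[col]] <- num
  }
  if (n_bad > 0)
    message(sprintf("read_panel: %d unparseable numeric cells set to missing",
                    n_bad))

  if (!is.null(schema$yield_scale)) {
    for (crop in names(schema$yield_scale)) {
      sel <- df$crop == crop
      df$yield_t_ha[sel] <- df$yield_t_ha[sel] * schema$yield_scale[[crop]]
    }
  }
  yield_panel(df, year_range = year_range, check_yield = FALSE)
}

#' Derive yields from production and area
#'
#' Recomputes `yield = production / area` for every record, overwriting any
#' stored yield: printed yields in the source statistics are unreliable, so
#' the ratio of the two primary quantities is authoritative.  Yield is
#' missing wherever area is zero or either input is missing.
#'
#' @param panel a `yield_panel`.
#' @return the panel with recomputed yields.
#' @export
derive_yields <- function(panel) {
  stopifnot(inherits(panel, "yield_panel"))
  ok <- !is.na(panel$area_ha) & panel$area_ha > 0 & !is.na(panel$production_t)
  panel$yield_t_ha <- ifelse(ok, panel$production_t / panel$area_ha, NA_real_)
  panel
}

#' Department harmonization rules
#'
#' Historical administrative reshapes are reconciled onto a fixed set of
#' analysis units.  A *split* rule copies pre-split yields of one historical
#' department to each successor (areas shared out per `area_policy`); a
#' *merge* rule pools several historical departments into one counterfactual
#' unit (areas and productions summed, yield recomputed) up to and including
#' `end_year`.
#'
#' @param splits list of rules, each
#'   `list(from =, to = c(...), split_year =, area_policy = "equal"|"copy")`;
#'   years strictly before `split_year` are affected.
#' @param merges list of rules, each `list(parts = c(...), to =, end_year =)`;
#'   years `<= end_year` are affected.
#' @export
department_map <- function(splits = list(), merges = list()) {
  for (s in splits)
    stopifnot(is.character(s$from), length(s$to) >= 2, is.numeric(s$split_year))
  for (m in merges)
    stopifnot(length(m$parts) >= 2, is.character(m$to), is.numeric(m$end_year))
  structure(list(splits = splits, merges = merges), class = "department_map")
}

#' Built-in harmonization map for the French panel
#'
#' Corsica (20) was a single department until 1975, then split into
#' Corse-du-Sud (2A) and Haute-Corse (2B): pre-1976 values are copied to both
#' successors.  Seine (75) and Seine-et-Oise (78) were reorganised into seven
#' departments on 1968-01-01: until 1967 the two old departments are pooled
#' into one counterfactual unit.
#'
#' @export
french_department_map <- function() {
  department_map(
    splits = list(list(from = "20", to = c("2A", "2B"), split_year = 1976,
                       area_policy = "equal")),
    merges = list(list(parts = c("75", "78"), to = "75+78", end_year = 1967))
  )
}

#' Harmonize historical departments
#'
#' @param panel a `yield_panel`.
#' @param map a [department_map()].
#' @param strict error when a rule references a department absent from the
#'   panel (default `FALSE`: such rules are skipped).
#' @return harmonized `yield_panel`.
#' @export
harmonize_departments <- function(panel, map, strict = FALSE) {
  stopifnot(inherits(panel, "yield_panel"), inherits(map, "department_map"))
  df <- as.data.frame(panel)

  for (s in map$splits) {
    sel <- df$department_id == s$from & df$year < s$split_year
    if (!any(df$department_id == s$from)) {
      if (strict) yt_stop("mapping_error",
                          paste("split rule references unknown department:",
                                s$from))
      next
    }
    if (any(sel)) {
      src <- df[sel, , drop = FALSE]
      policy <- s$area_policy %||% "equal"
      copies <- lapply(s$to, function(succ) {
        cp <- src
        cp$department_id <- succ
        if (policy == "equal") {
          cp$area_ha <- cp$area_ha / length(s$to)
          cp$production_t <- cp$production_t / length(s$to)
        }
        cp          # yields copied verbatim under both policies
      })
      df <- rbind(df[!sel, , drop = FALSE], do.call(rbind, copies))
    }
  }

  for (m in map$merges) {
    present <- m$parts %in% df$department_id
    if (!any(present)) {
      if (strict) yt_stop("mapping_error",
                          paste("merge rule references unknown departments:",
                                paste(m$parts, collapse = ", ")))
      next
    }
    sel <- df$department_id %in% m$parts & df$year <= m$end_year
    if (any(sel)) {
      src <- df[sel, , drop = FALSE]
      pooled <- do.call(rbind, lapply(
        split(src, list(src$crop, src$season_type, src$year), drop = TRUE),
        function(g) {
          area <- if (all(is.na(g$area_ha))) NA_real_ else
            sum(g$area_ha, na.rm = TRUE)
          prod <- if (all(is.na(g$production_t))) NA_real_ else
            sum(g$production_t, na.rm = TRUE)
          data.frame(department_id = m$to, crop = g$crop[1],
                     season_type = g$season_type[1], year = g$year[1],
                     area_ha = area, production_t = prod,
                     yield_t_ha = if (!is.na(area) && area > 0 &&
                                      !is.na(prod)) prod / area else NA_real_,
                     stringsAsFactors = FALSE)
        }))
      df <- rbind(df[!sel, , drop = FALSE], pooled)
    }
  }

  df <- df[order(df$crop, df$season_type, df$department_id, df$year), ]
  yield_panel(df, year_range = attr(panel, "year_range"), check_yield = FALSE)
}

#' Write result tables with a run manifest
#'
#' Writes one CSV per named table plus `manifest.json` recording a
#' configuration fingerprint, the seed, and package/R versions.  Rerunning
#' with identical inputs produces byte-identical files.
#'
#' @param tables named list of data frames (may be empty).
#' @param directory output directory, created if needed.
#' @param config optional configuration object folded into the fingerprint.
#' @param seed optional seed recorded in the manifest.
#' @return (invisibly) the manifest as a list.
#' @export
write_results <- function(tables, directory, config = NULL, seed = NULL) {
  stopifnot(is.list(tables))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) yt_stop("io_error", paste("cannot create directory:", directory))
  }
  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    write.csv(tables[[nm]], path, row.names = FALSE, na = "")
    files <- c(files, basename(path))
  }
  cfg_repr <- paste(deparse(config), collapse = "")
  manifest <- list(
    config_hash = fnv1a32(cfg_repr),
    seed = seed,
    tables = as.list(setNames(vapply(tables, nrow, 0L), names(tables))),
    files = as.list(files),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("yieldtrends"))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Write a yield panel to CSV
#'
#' Inverse of [read_panel()]: values round-trip within numeric text
#' formatting (15 significant digits).
#'
#' @param panel a `yield_panel`.
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "yield_panel"))
  df <- as.data.frame(panel)
  for (col in c("area_ha", "production_t", "yield_t_ha"))
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(df[[col]], digits = 15, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
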