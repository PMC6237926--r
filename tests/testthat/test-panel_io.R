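make_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("department_id,crop,season_type,year,area_ha,production_t,yield_t_ha",
               lines), path)
  path
}

test_that("a well-formed CSV round-trips through read and write", {
  path <- make_csv(c("D01,maize,aggregate,1950,100,700,7",
                     "D01,maize,aggregate,1951,110,770,7",
                     "D02,wine,aggregate,1950,50,2500,50"))
  p <- read_panel(path)
  expect_s3_class(p, "yield_panel")
  expect_equal(nrow(p), 3)
  expect_equal(p$yield_t_ha, c(7, 7, 50))

  out <- tempfile(fileext = ".csv")
  write_panel(p, out)
  p2 <- read_panel(out)
  expect_equal(as.data.frame(p), as.data.frame(p2), tolerance = 1e-9)
})

test_that("blank and unparseable cells become missing values", {
  path <- make_csv(c("D01,maize,aggregate,1950,,700,",
                     "D01,maize,aggregate,1951,abc,700,7"))
  expect_message(p <- read_panel(path), "1 unparseable")
  expect_true(is.na(p$area_ha[1]))
  expect_true(is.na(p$yield_t_ha[1]))
  expect_true(is.na(p$area_ha[2]))
})

test_that("schema errors and key integrity are enforced", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("department_id,crop,year", "D01,maize,1950"), path)
  expect_error(read_panel(path), class = "schema_error")

  dup <- make_csv(c("D01,maize,aggregate,1950,100,700,7",
                    "D01,maize,aggregate,1950,100,700,7"))
  expect_error(read_panel(dup), class = "integrity_error")

  expect_error(
    mini_panel(department_id = "D01", crop = "maize", year = 1950,
               area_ha = -1),
    class = "validation_error")
  expect_error(
    mini_panel(department_id = "D01", crop = "triticale", year = 1950),
    class = "schema_error")
})

test_that("a per-crop yield scale converts kg/ha input to t/ha", {
  path <- make_csv("D01,maize,aggregate,1950,100,700,7000")
  p <- read_panel(path, schema = list(yield_scale = c(maize = 0.001)))
  expect_equal(p$yield_t_ha, 7)
})

test_that("derive_yields recomputes from production and area", {
  p <- mini_panel(department_id = c("D01", "D01", "D01"),
                  crop = "maize", year = 1950:1952,
                  area_ha = c(100, 0, 100),
                  production_t = c(700, 50, NA),
                  yield_t_ha = c(99, 99, 99))  # wrong stored yields
  out <- derive_yields(p)
  expect_equal(out$yield_t_ha, c(7, NA, NA))
})

test_that("split rules copy yields to successors; merges pool production", {
  p <- mini_panel(
    department_id = c("20", "20", "75", "78", "75"),
    crop = "wine", year = c(1950, 1980, 1950, 1950, 1970),
    area_ha = c(100, 100, 100, 300, 120),
    production_t = c(300, 400, 500, 2100, 700),
    yield_t_ha = c(3, 4, 5, 7, 700 / 120))
  out <- harmonize_departments(p, french_department_map())

  corsica <- out[out$year == 1950 & out$department_id %in% c("2A", "2B"), ]
  expect_equal(nrow(corsica), 2)
  expect_equal(corsica$yield_t_ha, c(3, 3))      # yields copied
  expect_equal(sum(corsica$area_ha), 100)        # areas shared equally
  expect_false("20" %in% out$department_id[out$year == 1950])
  # post-split year untouched
  expect_true("20" %in% out$department_id[out$year == 1980])

  merged <- out[out$department_id == "75+78" & out$year == 1950, ]
  expect_equal(merged$area_ha, 400)
  expect_equal(merged$production_t, 2600)
  expect_equal(merged$yield_t_ha, 6.5)
  # post-merge year untouched (1970 > 1967)
  expect_true("75" %in% out$department_id[out$year == 1970])
})

test_that("harmonization conserves national production totals", {
  fx <- reference_fixture()$panel
  df <- as.data.frame(fx)
  df$department_id[df$department_id == "D01"] <- "75"
  df$department_id[df$department_id == "D02"] <- "78"
  p <- yield_panel(df, check_yield = FALSE)
  out <- harmonize_departments(p, french_department_map())
  expect_equal(sum(out$production_t, na.rm = TRUE),
               sum(p$production_t, na.rm = TRUE))
  # a panel without mapped departments is unchanged
  p2 <- mini_panel(department_id = "D09", crop = "oats", year = 1950,
                   yield_t_ha = 2)
  out2 <- harmonize_departments(p2, french_department_map())
  expect_equal(as.data.frame(out2), as.data.frame(p2))
  expect_error(harmonize_departments(p2, french_department_map(),
                                     strict = TRUE), class = "mapping_error")
})

test_that("write_results emits one CSV per table plus a stable manifest", {
  dir1 <- tempfile(); dir2 <- tempfile()
  tbl <- data.frame(a = 1:3, b = c("x", "y", "z"))

  m0 <- write_results(list(), dir1, config = list(k = 1), seed = 5)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_length(m0$files, 0)

  write_results(list(tbl = tbl), dir2, config = list(k = 1), seed = 5)
  expect_true(file.exists(file.path(dir2, "tbl.csv")))
  bytes1 <- readBin(file.path(dir2, "manifest.json"), "raw", 1e5)
  csv1 <- readBin(file.path(dir2, "tbl.csv"), "raw", 1e5)
  write_results(list(tbl = tbl), dir2, config = list(k = 1), seed = 5)
  expect_identical(readBin(file.path(dir2, "manifest.json"), "raw", 1e5),
                   bytes1)
  expect_identical(readBin(file.path(dir2, "tbl.csv"), "raw", 1e5), csv1)
})
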