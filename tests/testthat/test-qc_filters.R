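# Panel with one series per call, for direct rule arithmetic.
series_panel <- function(crop, years, yields, dept = "D01") {
  mini_panel(department_id = dept, crop = crop, year = years,
             yield_t_ha = yields)
}

test_that("each rule fires on its textbook case", {
  # (a) absolute bound: soft wheat above 10 t/ha
  p <- series_panel("soft_wheat", 1950:1954, c(4, 4.2, 12, 4.1, 4))
  rep <- flag_outliers(p)
  expect_equal(rep$flagged$rule, "absolute")
  expect_equal(rep$flagged$year, 1952)

  # (b) mean-ratio: 0.7 against a long-term mean of ~3.5 is NOT an outlier
  # at ratio 5 (0.7 >= mean / 5)...
  y <- c(rep(3.6, 19), 0.7); y_mean <- mean(y)
  expect_gt(0.7, y_mean / 5)
  p2 <- series_panel("barley", 1950:1969, y)
  rep2 <- flag_outliers(p2)
  expect_equal(nrow(rep2$flagged), 0)

  # ...but 0.7 after a previous year of 0.03 is a >20-fold jump
  y3 <- c(rep(3.6, 18), 0.03, 0.7)
  p3 <- series_panel("barley", 1950:1969, y3)
  rep3 <- flag_outliers(p3)
  expect_true("jump" %in% rep3$flagged$rule[rep3$flagged$year == 1969])

  # jump rule is disabled across gaps in the series
  y4 <- c(rep(4, 10), 0.03, rep(NA, 3), 0.7, rep(4, 5))
  p4 <- series_panel("barley", 1950:1969, y4)
  expect_false("jump" %in% flag_outliers(p4)$flagged$rule)
})

test_that("crop-specific mean ratios and strict coverage are honoured", {
  # maize tolerates 10-fold deviations: 0.5 vs mean ~5 is within band
  y <- c(rep(5, 30), 0.52)
  p <- series_panel("maize", 1950:1980, y)
  expect_equal(nrow(flag_outliers(p)$flagged), 0)
  # barley (default ratio 5) flags the same relative deviation
  p2 <- series_panel("barley", 1950:1980, y)
  expect_equal(flag_outliers(p2)$flagged$rule, "mean_ratio")

  rules <- outlier_rules(absolute_bound = c(barley = 10))
  expect_error(flag_outliers(p, rules, strict = TRUE),
               class = "configuration_error")
  expect_silent(flag_outliers(p2, rules, strict = TRUE))
})

test_that("flags equal the union of three independently evaluated predicates", {
  set.seed(42)
  # 1000 clean values across 10 series, then inject 20 violations
  panels <- list()
  for (i in 1:10) {
    y <- pmax(stats::rnorm(100, 5, 0.4), 3)
    panels[[i]] <- data.frame(department_id = sprintf("D%02d", i),
                              crop = "barley", season_type = "aggregate",
                              year = 1901:2000, area_ha = NA_real_,
                              production_t = NA_real_, yield_t_ha = y)
  }
  df <- do.call(rbind, panels)
  inject <- data.frame(
    dept = sprintf("D%02d", c(1, 1, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 8, 8,
                              9, 9, 10, 10, 2)),
    year = c(1910, 1950, 1920, 1930, 1990, 1915, 1980, 1925, 1995, 1935,
             1985, 1945, 1975, 1955, 1965, 1905, 1999, 1940, 1970, 1960),
    value = c(rep(11, 7), rep(0.5, 7), rep(11, 3), rep(0.5, 3)))
  for (k in seq_len(nrow(inject)))
    df$yield_t_ha[df$department_id == inject$dept[k] &
                    df$year == inject$year[k]] <- inject$value[k]
  p <- yield_panel(df, check_yield = FALSE)
  rep <- flag_outliers(p)

  # oracle: evaluate the three predicates by brute-force scan
  oracle <- list()
  for (d in unique(df$department_id)) {
    s <- df[df$department_id == d, ]
    s <- s[order(s$year), ]
    m <- mean(s$yield_t_ha, na.rm = TRUE)
    for (i in seq_len(nrow(s))) {
      v <- s$yield_t_ha[i]
      if (is.na(v)) next
      rules_hit <- character(0)
      if (v > 10) rules_hit <- c(rules_hit, "absolute")
      if (v > 5 * m || v < m / 5) rules_hit <- c(rules_hit, "mean_ratio")
      j <- which(s$year == s$year[i] - 1)
      if (length(j) == 1 && !is.na(s$yield_t_ha[j]) &&
          v > 20 * s$yield_t_ha[j])
        rules_hit <- c(rules_hit, "jump")
      for (r in rules_hit)
        oracle[[length(oracle) + 1]] <- data.frame(
          department_id = d, year = s$year[i], rule = r)
    }
  }
  oracle <- do.call(rbind, oracle)
  got <- rep$flagged[, c("department_id", "year", "rule")]
  o <- oracle[order(oracle$department_id, oracle$year, oracle$rule), ]
  g <- got[order(got$department_id, got$year, got$rule), ]
  rownames(o) <- rownames(g) <- NULL
  expect_equal(g, o)
  # exactly the 20 injected keys are flagged
  flagged_keys <- unique(paste(got$department_id, got$year))
  expect_setequal(flagged_keys, paste(inject$dept, inject$year))
})

test_that("masking sets exactly the flagged yields to missing, idempotently", {
  fx <- reference_fixture()
  rep <- flag_outliers(fx$panel)
  n_before <- sum(is.na(fx$panel$yield_t_ha))
  masked <- apply_mask(fx$panel, rep)
  expect_equal(sum(is.na(masked$yield_t_ha)) - n_before,
               nrow(unique(rep$flagged[, 1:4])))
  expect_equal(as.data.frame(apply_mask(masked, rep)),
               as.data.frame(masked))
  # areas and productions untouched
  expect_identical(masked$area_ha, fx$panel$area_ha)
  expect_identical(masked$production_t, fx$panel$production_t)

  empty <- flag_outliers(mini_panel(department_id = "D01", crop = "oats",
                                    year = 1950:1960, yield_t_ha = rep(2, 11)))
  expect_equal(as.data.frame(apply_mask(fx$panel, empty)),
               as.data.frame(fx$panel))

  bogus <- rep
  bogus$flagged$year <- 1899L
  expect_error(apply_mask(fx$panel, bogus), class = "integrity_error")
})

test_that("flagged fraction is relative to non-missing yields", {
  p <- series_panel("soft_wheat", 1950:1959,
                    c(4, 4, 12, 4, NA, 4, 4, 4, 4, 4))
  rep <- flag_outliers(p)
  expect_equal(rep$fraction_flagged$overall, 1 / 9)
})
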