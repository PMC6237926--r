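test_that("interval positions: disjoint cases and exhaustive enumeration", {
  expect_equal(classify_position(c(-0.01, -0.002), -0.005, c(0, 0.005)), "P1")
  expect_equal(classify_position(c(0.006, 0.02), 0.01, c(0, 0.005)), "P10")
  expect_error(classify_position(c(0.01, -0.01), 0, c(0, 0.005)),
               class = "interval_error")

  # brute force: one representative value per cell (below/in/above), all
  # (low, point, high) combinations with low <= point <= high
  L <- 0; U <- 0.005
  vals <- c(below = -0.01, "in" = 0.002, above = 0.01)
  labels <- character(0)
  for (lo in vals) for (pt in vals) for (hi in vals) {
    if (lo <= pt && pt <= hi)
      labels <- c(labels, classify_position(c(lo, hi), pt, c(L, U)))
  }
  expect_setequal(unique(labels), paste0("P", 1:10))
  expect_length(unique(labels), 10)
})

test_that("scores are monotone under downward shifts of interval and point", {
  tab <- default_score_table()
  set.seed(31)
  for (i in 1:200) {
    lo <- runif(1, -0.02, 0.02)
    hi <- lo + runif(1, 0, 0.02)
    pt <- runif(1, lo, hi)
    shift <- runif(1, 0, 0.02)
    s1 <- tab[classify_position(c(lo, hi), pt, c(0, 0.005))]
    s2 <- tab[classify_position(c(lo, hi) - shift, pt - shift, c(0, 0.005))]
    expect_gte(unname(s2), unname(s1))
  }
})

test_that("overall score is the mean of per-year scores with inclusive cutoff", {
  yrs <- 1990:2016
  # growth well below the band: every window year scores 1
  low <- make_fit(yrs, a = rep(5, 27), b = rep(-0.02, 27), var_b = 1e-6)
  res <- stagnation_score(low)
  expect_equal(res$overall, 1)
  expect_true(res$likely)
  expect_equal(res$n_years_scored, 20)

  # strong growth: every window year scores 0
  high <- make_fit(yrs, a = rep(5, 27), b = rep(0.15, 27), var_b = 1e-6)
  res2 <- stagnation_score(high)
  expect_equal(res2$overall, 0)
  expect_false(res2$likely)

  # half the window stagnating: overall exactly 0.5, likely (inclusive)
  b_half <- c(rep(0.15, length(1990:2006)), rep(-0.02, length(2007:2016)))
  half <- make_fit(yrs, a = rep(5, 27), b = b_half, var_b = 1e-6)
  res3 <- stagnation_score(half)
  expect_equal(res3$overall, 0.5)
  expect_true(res3$likely)

  expect_equal(res$per_year$score, rep(1, 20))
  expect_error(stagnation_score(make_fit(1950:1960, a = rep(5, 11),
                                         b = rep(0, 11))),
               class = "not_assessable")
})

test_that("degenerate intervals score on the point estimate alone", {
  yrs <- 1995:2016
  g_below <- make_fit(yrs, a = rep(5, 22), b = rep(0.004 * 5, 22), var_b = 0)
  expect_equal(stagnation_score(g_below)$overall, 1)
  g_above <- make_fit(yrs, a = rep(5, 22), b = rep(0.006 * 5, 22), var_b = 0)
  expect_equal(stagnation_score(g_above)$overall, 0)
})

test_that("onset year is the first window year with growth below the bound", {
  yrs <- 1990:2016
  # already below at the window start
  f1 <- make_fit(yrs, a = rep(5, 27), b = rep(0.004 * 5, 27), var_b = 1e-8)
  expect_equal(onset_year(f1), 1997)

  # crosses in 2002
  b <- ifelse(yrs <= 2001, 0.006 * 5, 0.003 * 5)
  # make it likely by keeping most years low: use 0.003 for 2002+ (15 years)
  f2 <- make_fit(yrs, a = rep(5, 27), b = b, var_b = 1e-8)
  res2 <- stagnation_score(f2)
  expect_true(res2$likely)   # 15/20 years score 1
  expect_equal(res2$onset_year, 2002)

  # exactly at the bound every year: strict inequality, no onset
  f3 <- make_fit(yrs, a = rep(5, 27), b = rep(0.005 * 5, 27), var_b = 0)
  res3 <- stagnation_score(f3)
  expect_true(res3$likely)   # 0.005 is inside the inclusive band
  expect_true(is.na(res3$onset_year))

  # onset is a contract violation for clearly growing series
  f4 <- make_fit(yrs, a = rep(5, 27), b = rep(0.1, 27), var_b = 1e-8)
  expect_error(onset_year(f4), class = "contract_violation")
})

test_that("area share weights likely departments by window mean area", {
  p <- mini_panel(department_id = rep(c("A", "B"), each = 20),
                  crop = "maize", year = rep(1997:2016, 2),
                  area_ha = rep(c(100, 300), each = 20),
                  yield_t_ha = 5)
  res <- data.frame(department_id = c("A", "B"), likely = c(FALSE, TRUE))
  expect_equal(area_share_stagnating(res, p, "maize"), 0.75)
  res$likely <- c(FALSE, FALSE)
  expect_equal(area_share_stagnating(res, p, "maize"), 0)
  res_bad <- data.frame(department_id = "C", likely = TRUE)
  expect_error(area_share_stagnating(res_bad, p, "maize"),
               class = "undefined_share_error")
})

test_that("group comparison reproduces the Welch statistic", {
  # identical non-constant groups: zero difference, p = 1
  g <- c(5, 6, 7)
  out <- compare_group_yields(g, g)
  expect_equal(out$difference, 0)
  expect_equal(out$p_value, 1)

  # clearly separated groups with tiny jitter
  out2 <- compare_group_yields(c(7.001, 7, 6.999), c(5.001, 5, 4.999))
  expect_equal(out2$difference, 2, tolerance = 1e-3)
  expect_lt(out2$p_value, 0.05)

  # hand-computed Welch t on a 5+5 fixture
  x <- c(6.1, 5.8, 6.4, 6.0, 5.9); y <- c(5.2, 5.5, 5.1, 5.4, 5.0)
  out3 <- compare_group_yields(x, y)
  se <- sqrt(var(x) / 5 + var(y) / 5)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(out3$p_value, p_hand, tolerance = 1e-12)

  expect_error(compare_group_yields(c(1), c(2, 3)),
               class = "insufficient_group")
})

test_that("sensitivity sweep recovers the default run and scales with grid", {
  p <- mini_panel(department_id = rep(c("A", "B"), each = 20),
                  crop = "maize", year = rep(1997:2016, 2),
                  area_ha = rep(c(100, 300), each = 20),
                  yield_t_ha = 5)
  fits <- list(
    A = make_fit(1990:2016, a = rep(5, 27), b = rep(0.1, 27), var_b = 1e-8),
    B = make_fit(1990:2016, a = rep(5, 27), b = rep(0.001, 27), var_b = 1e-8))

  single <- sensitivity_sweep(fits, p, "maize", upper_bounds = 0.005,
                              window_starts = 1997L)
  expect_equal(nrow(single), 1)
  res_default <- data.frame(
    department_id = c("A", "B"),
    likely = c(stagnation_score(fits$A)$likely,
               stagnation_score(fits$B)$likely))
  expect_equal(single$area_share,
               area_share_stagnating(res_default, p, "maize"))
  expect_equal(single$area_share, 0.75)

  grid <- sensitivity_sweep(fits, p, "maize",
                            upper_bounds = c(0.0025, 0.005, 0.0075),
                            window_starts = c(1992L, 1997L, 2002L))
  expect_equal(nrow(grid), 9)

  # raising the upper bound never decreases a department's score
  set.seed(53)
  for (i in 1:30) {
    b <- rnorm(27, 0.02, 0.03)
    f <- make_fit(1990:2016, a = rep(5, 27), b = b, var_b = 1e-4)
    s1 <- stagnation_score(f, stagnation_config())$overall
    s2 <- stagnation_score(
      f, stagnation_config(interval = c(0, 0.01), threshold = 0.005))$overall
    expect_gte(s2, s1)
  }
})
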