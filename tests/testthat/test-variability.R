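test_that("residuals are observation minus smoothed level at observed years", {
  fit <- make_fit(2000:2009, a = seq(5, 6.8, by = 0.2), b = rep(0.2, 10))
  y <- fit$a
  expect_equal(trend_residuals(y, fit)$residual, rep(0, 10))
  expect_equal(trend_residuals(y + 0.5, fit)$residual, rep(0.5, 10))
  y2 <- y; y2[c(3, 7)] <- NA
  r <- trend_residuals(y2 + 0.5, fit)
  expect_equal(nrow(r), 8)
  expect_false(any(r$year %in% c(2002, 2006)))
  expect_error(trend_residuals(y[1:5], fit), class = "alignment_error")
})

test_that("decadal CV is residual SD over raw mean, with anchored categories", {
  years <- 1950:1959
  y <- rep(5, 10)
  res0 <- data.frame(year = years, residual = rep(0, 10))
  out0 <- decadal_cv(y, res0, years)
  expect_equal(out0$cv, 0)
  expect_equal(out0$category, 1L)

  # mean 5.0 and residual SD 1.25 -> CV 0.25, category 3 (20-30% band)
  resid <- scale(rnorm(10))[, 1] * 1.25
  res1 <- data.frame(year = years, residual = resid)
  out1 <- decadal_cv(y, res1, years)
  expect_equal(out1$mean_yield, 5)
  expect_equal(out1$sd_resid, 1.25, tolerance = 1e-12)
  expect_equal(out1$cv, 0.25, tolerance = 1e-12)
  expect_equal(out1$category, 3L)

  # unit change leaves the CV unchanged
  res1_kg <- data.frame(year = years, residual = resid * 1000)
  out2 <- decadal_cv(y * 1000, res1_kg, years)
  expect_equal(out2$cv, out1$cv)

  # sparse decades are suppressed; non-positive means are an error
  out3 <- decadal_cv(y[1:4], res1[1:4, ], years[1:4])
  expect_equal(nrow(out3), 0)
  expect_error(decadal_cv(rep(0, 10), res1, years),
               class = "undefined_cv_error")
})

test_that("Taylor fit recovers an exact power law and rejects degenerate sets", {
  m <- c(2, 4, 6, 8, 10)
  stats <- data.frame(mean_yield = m, sd_resid = 0.2 * m^0.7)
  fit <- taylor_power_fit(stats)
  expect_equal(fit$slope, 0.7, tolerance = 1e-10)
  expect_equal(fit$intercept, log10(0.2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  set.seed(61)
  noisy <- data.frame(mean_yield = rep(m, 20),
                      sd_resid = 0.2 * rep(m, 20)^0.7 *
                        exp(rnorm(100, 0, 0.1)))
  nf <- taylor_power_fit(noisy)
  expect_equal(nf$slope, 0.7, tolerance = 0.1)

  expect_error(taylor_power_fit(data.frame(mean_yield = rep(5, 5),
                                           sd_resid = 1:5)),
               class = "insufficient_data")
})

test_that("skewness uses the adjusted Fisher-Pearson estimator", {
  expect_equal(residual_skewness(c(-1, 0, 1)), 0)
  expect_lt(residual_skewness(c(-3, rep(0.5, 6))), 0)
  expect_error(residual_skewness(rep(2, 10)), class = "undefined_skewness")
  expect_error(residual_skewness(c(1, 2)), class = "insufficient_data")

  # generator noise hits its skewness target at large n
  set.seed(67)
  x <- rskewnorm(2e4, sd = 1, skewness = -0.2)
  expect_equal(residual_skewness(x), -0.2, tolerance = 0.1)
  expect_equal(sd(x), 1, tolerance = 0.05)
  expect_equal(mean(x), 0, tolerance = 0.05)
})

test_that("quantile trends use linear interpolation across departments", {
  p <- mini_panel(department_id = sprintf("D%02d", 1:5), crop = "maize",
                  year = 1950, yield_t_ha = c(2, 4, 6, 8, 10))
  qt <- quantile_trends(p, "maize")
  expect_equal(qt$q50, 6)
  expect_equal(qt$min, 2)
  expect_equal(qt$max, 10)

  p2 <- mini_panel(department_id = sprintf("D%02d", 1:100), crop = "maize",
                   year = 1950, yield_t_ha = as.numeric(1:100))
  qt2 <- quantile_trends(p2, "maize")
  expect_equal(qt2$q05, 5.95)

  p3 <- mini_panel(department_id = c("A", "B", "C"), crop = "maize",
                   year = 1950, yield_t_ha = rep(7, 3))
  qt3 <- quantile_trends(p3, "maize")
  expect_true(all(qt3[, grep("^q", names(qt3))] == 7))

  p4 <- mini_panel(department_id = "A", crop = "maize", year = 1950,
                   yield_t_ha = 3)
  expect_true(quantile_trends(p4, "maize")$degenerate)
})

test_that("cross-crop residual correlations are symmetric and honest to nulls", {
  set.seed(71)
  yrs <- 1950:2016
  a <- data.frame(year = yrs, residual = rnorm(length(yrs)))
  series <- list(barley = a, barley_copy = a,
                 maize = data.frame(year = yrs,
                                    residual = rnorm(length(yrs))))
  out <- cross_crop_residual_correlation(series)
  expect_equal(out$r["barley", "barley_copy"], 1)
  expect_lt(out$p["barley", "barley_copy"], 1e-10)
  expect_equal(out$r, t(out$r))
  expect_equal(diag(out$r), setNames(rep(1, 3), names(series)))
  expect_true(all(abs(out$r) <= 1, na.rm = TRUE))

  # independent series: p > 0.05 in at least 90% of seeds
  hits <- replicate(40, {
    s <- list(a = data.frame(year = 1:100, residual = rnorm(100)),
              b = data.frame(year = 1:100, residual = rnorm(100)))
    cross_crop_residual_correlation(s)$p["a", "b"] > 0.05
  })
  expect_gte(mean(hits), 0.9)

  # shared-shock construction: corr = lambda^2 / (lambda^2 + sigma2)
  lambda <- 0.8; sigma2 <- 1 - lambda^2
  rho <- lambda^2 / (lambda^2 + sigma2)
  f <- rnorm(500)
  s <- list(a = data.frame(year = 1:500,
                           residual = lambda * f + rnorm(500, 0, sqrt(sigma2))),
            b = data.frame(year = 1:500,
                           residual = lambda * f + rnorm(500, 0, sqrt(sigma2))))
  r_hat <- cross_crop_residual_correlation(s)$r["a", "b"]
  expect_equal(r_hat, rho, tolerance = 3 * (1 - rho^2) / sqrt(500) / rho)

  # short overlap is not assessable
  s2 <- list(a = data.frame(year = 1:5, residual = rnorm(5)),
             b = data.frame(year = 1:5, residual = rnorm(5)))
  out2 <- cross_crop_residual_correlation(s2)
  expect_true(is.na(out2$r["a", "b"]))
  expect_equal(out2$n_years["a", "b"], 5L)
})
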