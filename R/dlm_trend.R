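#' Variance parameters of the local linear trend model
#'
#' The model is the local linear trend dynamic linear model: observed yield
#' `Y_t = a_t + eps_t` with `eps_t ~ N(0, sigma2_eps)`, and state
#' `Z_t = (a_t, b_t)'` evolving as `Z_t = G Z_{t-1} + tau_{t-1}` with
#' `G = [[1,1],[0,1]]` and `tau ~ N(0, diag(sigma2_a, sigma2_b))`.  `a_t` is
#' the underlying yield level and `b_t` the annual absolute growth rate.
#'
#' @param sigma2_eps observation noise variance (yield units squared).
#' @param sigma2_a level disturbance variance.
#' @param sigma2_b slope disturbance variance.
#' @export
dlm_params <- function(sigma2_eps, sigma2_a, sigma2_b) {
  v <- c(sigma2_eps, sigma2_a, sigma2_b)
  if (any(!is.finite(v)) || any(v < 0))
    yt_stop("validation_error", "variance parameters must be finite and >= 0")
  if (all(v == 0))
    yt_stop("validation_error", "at least one variance must be positive")
  structure(list(sigma2_eps = sigma2_eps, sigma2_a = sigma2_a,
                 sigma2_b = sigma2_b), class = "dlm_params")
}

#' Prior for the state at the first year
#'
#' A weakly informative proper normal standing in for a diffuse prior:
#' mean `(first non-missing observation, 0)`, independent variances
#' `variance` (default 1e7 in squared yield units) on both level and slope.
#'
#' @param y the observation series (used for the level mean).
#' @param variance prior variance on each state component.
#' @export
dlm_init <- function(y, variance = 1e7) {
  obs <- y[!is.na(y)]
  if (length(obs) == 0) yt_stop("estimation_error", "all-missing series")
  list(mean = c(obs[1], 0), variance = c(variance, variance))
}

check_series <- function(y) {
  if (length(y) < 2) yt_stop("estimation_error", "series length must be >= 2")
  if (all(is.na(y))) yt_stop("estimation_error", "all-missing series")
}

#' Kalman filter for the local linear trend model
#'
#' Runs the forward linear-Gaussian recursion.  Missing years perform the
#' time update only; the log-likelihood is the sum of log one-step
#' predictive densities over non-missing years.
#'
#' @param y numeric series (NA = missing), one value per consecutive year.
#' @param params a [dlm_params()] object.
#' @param init prior from [dlm_init()] (default: built from `y`).
#' @return list with `loglik`, `n_obs`, filtered means `m_filt` (T x 2,
#'   columns level and slope), filtered covariances `P_filt` (T x 3:
#'   var(a), cov(a,b), var(b)), and one-step predicted `m_pred`, `P_pred`.
#' @export
kalman_filter <- function(y, params, init = dlm_init(y)) {
  stopifnot(inherits(params, "dlm_params"))
  check_series(y)
  .kalman_cpp(as.numeric(y), params$sigma2_eps, params$sigma2_a,
              params$sigma2_b, init$mean, init$variance, FALSE)
}

#' Kalman smoother (fixed-interval) for the local linear trend model
#'
#' Runs the filter and the Rauch-Tung-Striebel backward pass, then assembles
#' a `trend_fit`: smoothed level and growth with their variances at every
#' year (including missing ones) and the relative growth rate with its 90%
#' confidence interval (see [relative_growth()]).
#'
#' @inheritParams kalman_filter
#' @param years optional integer years labelling the series.
#' @param level confidence level for the relative-growth interval.
#' @return a `trend_fit`: data-frame-like list with `years`, `a`, `var_a`,
#'   `b`, `var_b`, `g`, `g_lo`, `g_hi` plus attributes `params`, `loglik`,
#'   `n_obs`.
#' @export
kalman_smooth <- function(y, params, init = dlm_init(y),
                          years = seq_along(y), level = 0.90) {
  stopifnot(inherits(params, "dlm_params"), length(years) == length(y))
  check_series(y)
  res <- .kalman_cpp(as.numeric(y), params$sigma2_eps, params$sigma2_a,
                     params$sigma2_b, init$mean, init$variance, TRUE)
  fit <- list(years = as.integer(years),
              y = as.numeric(y),
              a = res$m_smooth[, 1], var_a = pmax(res$P_smooth[, 1], 0),
              b = res$m_smooth[, 2], var_b = pmax(res$P_smooth[, 3], 0),
              filter = res)
  fit$n_obs <- res$n_obs
  fit$loglik <- res$loglik
  fit$params <- params
  class(fit) <- "trend_fit"
  rg <- relative_growth(fit, level = level)
  fit$g <- rg$g; fit$g_lo <- rg$lo; fit$g_hi <- rg$hi
  fit
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Local linear trend fit: %d years (%d observed), loglik %.3f\n",
              length(x$years), x$n_obs, x$loglik))
  cat(sprintf("  sigma2_eps=%.4g sigma2_a=%.4g sigma2_b=%.4g\n",
              x$params$sigma2_eps, x$params$sigma2_a, x$params$sigma2_b))
  invisible(x)
}

#' @export
as.data.frame.trend_fit <- function(x, ...) {
  data.frame(year = x$years, a = x$a, var_a = x$var_a, b = x$b,
             var_b = x$var_b, g = x$g, g_lo = x$g_lo, g_hi = x$g_hi)
}

#' Relative growth rate with confidence interval
#'
#' Converts absolute growth to relative growth `g_t = b_t / a_t`
#' (fraction per year).  The interval divides the absolute-growth normal
#' interval `b_t +/- z * sqrt(var_b_t)` by the level point estimate; the
#' 90% two-sided quantile is fixed at `z = 1.6449`.
#'
#' @param fit a `trend_fit`.
#' @param level two-sided confidence level (default 0.90).
#' @return list with `g`, `lo`, `hi`.
#' @export
relative_growth <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "trend_fit"))
  if (any(fit$a <= 0))
    yt_stop("undefined_rate_error",
            sprintf("non-positive smoothed level in year(s) %s",
                    paste(head(fit$years[fit$a <= 0], 5), collapse = ", ")))
  z <- if (identical(level, 0.90)) 1.6449 else qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(fit$var_b)
  list(g = fit$b / fit$a,
       lo = (fit$b - half) / fit$a,
       hi = (fit$b + half) / fit$a)
}

# Negative log-likelihood on the log-variance scale.
dlm_negloglik <- function(theta, y, init) {
  v <- exp(theta)
  ll <- .kalman_cpp(y, v[1], v[2], v[3], init$mean, init$variance,
                    FALSE)$loglik
  if (!is.finite(ll)) return(1e12)
  -ll
}

#' Fit the local linear trend model by maximum likelihood
#'
#' Maximizes the filter log-likelihood over `(sigma2_eps, sigma2_a,
#' sigma2_b)`, parameterized as log-variances (unconstrained), with BFGS
#' from five deterministic starts spanning state-to-observation variance
#' ratios 1e-2, 1e-1, 1, 10 and 1e2; the best converged likelihood wins.
#' Series with fewer than `min_obs` non-missing observations are refused:
#' a century-scale trend cannot be estimated reliably from less.
#'
#' @param y numeric series with NA for missing years.
#' @param years optional year labels.
#' @param min_obs minimum non-missing observations (default 30).
#' @param init_variance prior variance for [dlm_init()].
#' @param level confidence level for relative growth.
#' @return a `trend_fit` evaluated at the ML parameters; the fitted
#'   [dlm_params()] are in `$params` and the maximized log-likelihood in
#'   `$loglik`.
#' @export
fit_dlm <- function(y, years = seq_along(y), min_obs = 30,
                    init_variance = 1e7, level = 0.90) {
  check_series(y)
  y <- as.numeric(y)
  n_obs <- sum(!is.na(y))
  if (n_obs < min_obs)
    yt_stop("insufficient_data",
            sprintf("only %d non-missing observations (need >= %d)",
                    n_obs, min_obs))
  init <- dlm_init(y, variance = init_variance)

  v0 <- var(y, na.rm = TRUE)
  if (!is.finite(v0) || v0 <= 0) v0 <- 1
  ratios <- c(1e-2, 1e-1, 1, 10, 1e2)
  best <- NULL
  for (r in ratios) {
    theta0 <- log(c(v0 / 2, r * v0 / 4, r * v0 / 4))
    opt <- tryCatch(
      optim(theta0, dlm_negloglik, y = y, init = init, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    yt_stop("estimation_error", "optimizer failed from every start")
  v <- exp(best$par)
  params <- dlm_params(v[1], v[2], v[3])
  fit <- kalman_smooth(y, params, init = init, years = years, level = level)
  fit$convergence <- best$convergence
  fit
}
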