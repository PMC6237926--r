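# Independent oracles used to check the package's algorithms from first
# principles.  These deliberately use brute-force linear algebra and O(n^3)
# scans rather than the package's own code paths.

# Joint multivariate-normal oracle for the local linear trend model.
# Builds the exact joint distribution of the stacked states Z_1..Z_T (2T
# dims) under Z_1 ~ N(m0, diag(P0)), Z_t = G Z_{t-1} + w, then conditions
# on the observed y directly.  Returns smoothed means/covariances per time
# point, filtered moments (conditioning on y_1..t only), and the marginal
# log-likelihood of the observed vector.
gauss_oracle <- function(y, s2eps, s2a, s2b, m0, P0) {
  T <- length(y)
  G <- matrix(c(1, 0, 1, 1), 2, 2)  # [[1,1],[0,1]]
  W <- diag(c(s2a, s2b))
  mu <- matrix(0, 2 * T, 1)
  C <- matrix(0, 2 * T, 2 * T)
  idx <- function(t) (2 * t - 1):(2 * t)
  mu[idx(1)] <- m0
  C[idx(1), idx(1)] <- diag(P0)
  for (t in 2:T) {
    mu[idx(t)] <- G %*% mu[idx(t - 1)]
    C[idx(t), idx(t)] <- G %*% C[idx(t - 1), idx(t - 1)] %*% t(G) + W
    for (s in 1:(t - 1)) {
      C[idx(s), idx(t)] <- C[idx(s), idx(t - 1)] %*% t(G)
      C[idx(t), idx(s)] <- t(C[idx(s), idx(t)])
    }
  }
  obs <- which(!is.na(y))
  H <- matrix(0, length(obs), 2 * T)
  for (i in seq_along(obs)) H[i, 2 * obs[i] - 1] <- 1
  Syy <- H %*% C %*% t(H) + diag(s2eps, length(obs))
  Szy <- C %*% t(H)
  yv <- y[obs]
  resid <- yv - H %*% mu
  Si <- solve(Syy)
  cond_mean <- mu + Szy %*% Si %*% resid
  cond_cov <- C - Szy %*% Si %*% t(Szy)
  loglik <- -0.5 * (length(obs) * log(2 * pi) +
                      determinant(Syy, logarithm = TRUE)$modulus +
                      t(resid) %*% Si %*% resid)
  # filtered moments: condition on y_1..t for each t
  filt_mean <- matrix(NA_real_, T, 2)
  filt_var <- matrix(NA_real_, T, 3)
  for (t in 1:T) {
    upto <- which(obs <= t)
    if (length(upto) == 0) {
      fm <- mu[idx(t)]; fc <- C[idx(t), idx(t)]
    } else {
      Ht <- H[upto, , drop = FALSE]
      Syyt <- Ht %*% C %*% t(Ht) + diag(s2eps, length(upto))
      Szyt <- C[idx(t), , drop = FALSE] %*% t(Ht)
      K <- Szyt %*% solve(Syyt)
      fm <- mu[idx(t)] + K %*% (yv[upto] - Ht %*% mu)
      fc <- C[idx(t), idx(t)] - K %*% t(Szyt)
    }
    filt_mean[t, ] <- fm
    filt_var[t, ] <- c(fc[1, 1], fc[1, 2], fc[2, 2])
  }
  sm <- matrix(NA_real_, T, 2); sv <- matrix(NA_real_, T, 3)
  for (t in 1:T) {
    sm[t, ] <- cond_mean[idx(t)]
    cc <- cond_cov[idx(t), idx(t)]
    sv[t, ] <- c(cc[1, 1], cc[1, 2], cc[2, 2])
  }
  list(smooth_mean = sm, smooth_var = sv, filt_mean = filt_mean,
       filt_var = filt_var, loglik = as.numeric(loglik))
}

# Simulate a series from the local linear trend model itself.
sim_dlm_series <- function(T, s2eps, s2a, s2b, a0 = 5, b0 = 0.05) {
  a <- numeric(T); b <- numeric(T)
  a[1] <- a0; b[1] <- b0
  for (t in 2:T) {
    b[t] <- b[t - 1] + rnorm(1, 0, sqrt(s2b))
    a[t] <- a[t - 1] + b[t - 1] + rnorm(1, 0, sqrt(s2a))
  }
  list(y = a + rnorm(T, 0, sqrt(s2eps)), a = a, b = b)
}

# Naive O(n^3) average-linkage agglomeration from the definition: the
# distance between two clusters is the mean of all pairwise point
# distances.  Returns merge heights and the partition after each merge.
naive_upgma <- function(x) {
  n <- length(x)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  d <- function(ci, cj) mean(abs(outer(x[ci], x[cj], "-")))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    m <- length(clusters)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- d(clusters[[i]], clusters[[j]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    lab <- integer(n)
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition label vector (for comparing clusterings
# regardless of label permutation).
canon_partition <- function(lab) as.integer(factor(lab, levels = unique(lab)))

# Build a trend_fit object directly from given growth paths; used to test
# the stagnation scorer in isolation from the Kalman machinery.
make_fit <- function(years, a, b, var_b = 0, var_a = 0) {
  z <- 1.6449
  fit <- list(years = as.integer(years), y = a, a = a, var_a = rep(var_a,
              length(years)), b = b, var_b = rep(var_b, length(years)),
              n_obs = length(years), loglik = NA_real_,
              params = dlm_params(1, 0, 0))
  class(fit) <- "trend_fit"
  fit$g <- b / a
  fit$g_lo <- (b - z * sqrt(fit$var_b)) / a
  fit$g_hi <- (b + z * sqrt(fit$var_b)) / a
  fit
}

# Minimal panel builder for unit tests.
mini_panel <- function(...) {
  df <- data.frame(...)
  defaults <- list(season_type = "aggregate", area_ha = NA_real_,
                   production_t = NA_real_, yield_t_ha = NA_real_)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  yield_panel(df[, c("department_id", "crop", "season_type", "year",
                     "area_ha", "production_t", "yield_t_ha")],
              check_yield = FALSE)
}
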