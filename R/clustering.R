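#' Default analysis eras
#'
#' Four consecutive periods of about 30 years used for the era-wise
#' clustering of departmental mean yields.
#'
#' @export
default_eras <- function() {
  list(c(1900L, 1929L), c(1930L, 1959L), c(1960L, 1989L), c(1990L, 2016L))
}

#' Departmental mean yields within an era
#'
#' Per-department mean of non-missing yields over the era; departments with
#' fewer than `min_years` observed years are excluded.
#'
#' @param panel a `yield_panel`.
#' @param crop crop name.
#' @param era inclusive `(first, last)` years.
#' @param season_type season type (default `"aggregate"`).
#' @param min_years minimum observed years (default 5).
#' @return named numeric vector, names = department IDs.
#' @export
era_mean_yields <- function(panel, crop, era, season_type = "aggregate",
                            min_years = 5L) {
  stopifnot(inherits(panel, "yield_panel"), length(era) == 2)
  sub <- panel[panel$crop == crop & panel$season_type == season_type &
                 panel$year >= era[1] & panel$year <= era[2] &
                 !is.na(panel$yield_t_ha), , drop = FALSE]
  if (nrow(sub) == 0) return(setNames(numeric(0), character(0)))
  n <- tapply(sub$yield_t_ha, sub$department_id, length)
  m <- tapply(sub$yield_t_ha, sub$department_id, mean)
  out <- m[n >= min_years]
  setNames(as.numeric(out), names(out))
}

#' Trim extreme values before clustering
#'
#' Removes the `ceiling(fraction * n)` smallest and largest values so that
#' isolated outliers cannot dominate the dendrogram.  Ties are broken by
#' department ID order (names of `values`).
#'
#' @param values named numeric vector.
#' @param fraction trimming fraction per tail, in `[0, 0.5)` (default 0.01).
#' @return the reduced named vector; trimmed names in attribute
#'   `"trimmed"`.
#' @export
trim_extremes <- function(values, fraction = 0.01) {
  stopifnot(fraction >= 0, fraction < 0.5)
  n <- length(values)
  if (fraction == 0 || n == 0) {
    attr(values, "trimmed") <- character(0)
    return(values)
  }
  k <- ceiling(fraction * n)
  ord <- order(values, names(values))
  drop_idx <- c(ord[seq_len(k)], ord[n + 1 - seq_len(k)])
  if (n - 2 * k < 3)
    yt_stop("insufficient_data",
            sprintf("only %d values left after trimming", n - 2 * k))
  out <- values[-drop_idx]
  attr(out, "trimmed") <- names(values)[drop_idx]
  out
}

# Calinski-Harabasz index for a 1-d clustering.
ch_index <- function(values, labels) {
  n <- length(values)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  gm <- mean(values)
  W <- 0; B <- 0
  for (lab in unique(labels)) {
    v <- values[labels == lab]
    W <- W + sum((v - mean(v))^2)
    B <- B + length(v) * (mean(v) - gm)^2
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' UPGMA clustering of departmental mean yields
#'
#' Hierarchical agglomeration with unweighted average linkage (UPGMA) on
#' Euclidean distances between scalar mean yields; the tree is cut at every
#' candidate `k` and the Calinski-Harabasz index
#' `CH(k) = [B/(k-1)] / [W/(n-k)]` selects the cluster count (ties go to
#' the smallest `k`).  Cluster labels are relabelled 1..k by ascending
#' cluster mean yield, making the assignment deterministic.
#'
#' @param values named numeric vector (department ID -> mean yield).
#' @param k_range candidate cluster counts (default `2:min(10, n - 1)`).
#' @return a `cluster_result`: list with `assignment` (data frame
#'   `department_id, cluster, cluster_mean_yield`), `k`, `ch_curve`
#'   (named by k), `cluster_means`, and the `hclust` tree.  With all
#'   values identical, `k = 1` is reported and the CH curve is `NA`.
#' @export
upgma_cluster <- function(values, k_range = NULL) {
  n <- length(values)
  if (n < 3) yt_stop("insufficient_data", "need >= 3 values to cluster")
  if (length(unique(values)) == 1) {
    return(structure(list(
      assignment = data.frame(department_id = names(values), cluster = 1L,
                              cluster_mean_yield = unname(values)),
      k = 1L, ch_curve = NA_real_, cluster_means = unname(values[1]),
      tree = NULL, degenerate = TRUE), class = "cluster_result"))
  }
  k_range <- k_range %||% (2:min(10L, n - 1L))
  stopifnot(all(k_range >= 2), all(k_range <= n - 1))
  tree <- hclust(dist(values), method = "average")
  ch <- vapply(k_range, function(k)
    ch_index(values, cutree(tree, k = k)), 0)
  names(ch) <- k_range
  k_best <- k_range[which.max(ch)]
  labels <- cutree(tree, k = k_best)
  means <- tapply(values, labels, mean)
  relabel <- match(names(means)[order(means)], names(means))
  new_lab <- setNames(seq_along(relabel),
                      names(means)[order(means)])[as.character(labels)]
  assignment <- data.frame(department_id = names(values),
                           cluster = as.integer(new_lab),
                           cluster_mean_yield =
                             as.numeric(sort(means)[new_lab]),
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment, k = k_best, ch_curve = ch,
                 cluster_means = as.numeric(sort(means)), tree = tree,
                 degenerate = FALSE),
            class = "cluster_result")
}

#' Era-wise clustering for one crop
#'
#' Convenience wrapper: era means, 1% tail trimming, UPGMA with CH
#' selection, one result per era.  Trimmed departments are reported as
#' unclustered (cluster `NA`), not silently dropped.
#'
#' @param panel a `yield_panel`.
#' @param crop crop name.
#' @param eras list of `(first, last)` year pairs (default
#'   [default_eras()]).
#' @param trim_fraction per-tail trimming fraction.
#' @param ... passed to [era_mean_yields()].
#' @return data frame
#'   `crop, era_start, era_end, department_id, cluster, cluster_mean_yield,
#'   k, ch_at_k`.
#' @export
cluster_departments <- function(panel, crop, eras = default_eras(),
                                trim_fraction = 0.01, ...) {
  rows <- list()
  for (era in eras) {
    vals <- era_mean_yields(panel, crop, era, ...)
    if (length(vals) < 3) next
    trimmed <- tryCatch(trim_extremes(vals, trim_fraction),
                        yieldtrends_error = function(e) NULL)
    if (is.null(trimmed)) next
    res <- upgma_cluster(trimmed)
    ch_at_k <- if (res$degenerate) NA_real_ else
      unname(res$ch_curve[as.character(res$k)])
    df <- data.frame(crop = crop, era_start = era[1], era_end = era[2],
                     department_id = res$assignment$department_id,
                     cluster = res$assignment$cluster,
                     cluster_mean_yield = res$assignment$cluster_mean_yield,
                     k = res$k, ch_at_k = ch_at_k, stringsAsFactors = FALSE)
    unclustered <- attr(trimmed, "trimmed")
    if (length(unclustered) > 0)
      df <- rbind(df, data.frame(
        crop = crop, era_start = era[1], era_end = era[2],
        department_id = unclustered, cluster = NA_integer_,
        cluster_mean_yield = NA_real_, k = res$k, ch_at_k = ch_at_k,
        stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(crop = character(0), era_start = integer(0),
                      era_end = integer(0), department_id = character(0),
                      cluster = integer(0), cluster_mean_yield = numeric(0),
                      k = integer(0), ch_at_k = numeric(0))
  rownames(out) <- NULL
  out
}
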