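#' Hartigan-Wong k-means on principal component scores
#'
#' Thin, seed-deterministic wrapper around the Hartigan-Wong algorithm
#' ([stats::kmeans()]): the best of `n_starts` random initializations by total
#' within-cluster sum of squares is returned. Scores are clustered as they
#' are, without standardization, preserving the variance ranking of the
#' components.
#'
#' @param points numeric matrix, n x m (conditions x score dimensions).
#' @param k number of clusters, 1 <= k <= n.
#' @param seed integer seed.
#' @param n_starts random initializations.
#' @param iter_max maximum Hartigan-Wong iterations.
#' @return list of class `kmeans_solution`: `assignments`, `centers`, `wcss`,
#'   `k`, `m`, `seed`.
#' @export
kmeans_hw <- function(points, k, seed, n_starts = 1, iter_max = 100) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k cannot exceed the number of points", call. = FALSE)
  if (k == n) {
    # trivial optimum: every point its own centre
    return(structure(list(assignments = seq_len(n), centers = points,
                          wcss = 0, k = k, m = ncol(points), seed = seed),
                     class = "kmeans_solution"))
  }
  fit <- with_seed(seed, {
    best <- NULL
    attempts <- 0L
    starts <- 0L
    while (starts < n_starts && attempts < n_starts * 10L) {
      attempts <- attempts + 1L
      km <- tryCatch(
        suppressWarnings(stats::kmeans(points, centers = k, nstart = 1,
                                       iter.max = iter_max,
                                       algorithm = "Hartigan-Wong")),
        error = function(e) NULL)
      if (is.null(km)) next
      starts <- starts + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for every initialization",
                            call. = FALSE)
    best
  })
  structure(list(assignments = fit$cluster, centers = fit$centers,
                 wcss = fit$tot.withinss, k = k, m = ncol(points), seed = seed),
            class = "kmeans_solution")
}

#' AIC of a k-means solution
#'
#' The information criterion used for cluster-number selection: the k-means
#' distortion plus twice the number of fitted parameters,
#' `AIC = WCSS + 2 * m * k` (m = score dimensions, k = clusters). Lower is
#' better.
#'
#' @param wcss total within-cluster sum of squares (or a `kmeans_solution`).
#' @param m score dimensionality.
#' @param k cluster count.
#' @return AIC value.
#' @export
aic_kmeans <- function(wcss, m, k) {
  if (inherits(wcss, "kmeans_solution")) {
    k <- wcss$k; m <- wcss$m; wcss <- wcss$wcss
  }
  stopifnot(m >= 1, k >= 1, wcss >= 0)
  wcss + 2 * m * k
}

#' Monte-Carlo AIC selection of the cluster count
#'
#' Because k-means is stochastic in its initialization, the AIC at each
#' candidate cluster count is estimated by Monte-Carlo simulation:
#' `n_iterations` independent single-start Hartigan-Wong runs per candidate k,
#' each contributing one AIC value. The chosen k follows the tie rule: with
#' `"within_sd_largest"` (default), all k whose mean AIC lies within one SD
#' (of the minimizing k's AIC distribution) of the minimum are candidates and
#' the largest is chosen; `"strict_min"` takes the minimizer.
#'
#' @param points n x m score matrix.
#' @param k_range candidate cluster counts (default 1..m).
#' @param n_iterations Monte-Carlo iterations per k (default 10000).
#' @param seed integer seed.
#' @param tie_rule `"within_sd_largest"` or `"strict_min"`.
#' @return list of class `cluster_selection`: `table` (data frame `k`,
#'   `mean_aic`, `sd_aic`), `chosen_k`, `n_iterations`, `k_range`.
#' @export
select_k_monte_carlo <- function(points, k_range = seq_len(ncol(points)),
                                 n_iterations = 10000, seed,
                                 tie_rule = c("within_sd_largest", "strict_min")) {
  tie_rule <- match.arg(tie_rule)
  points <- as.matrix(points)
  stopifnot(length(k_range) >= 1, all(k_range >= 1), all(k_range <= nrow(points)))
  m <- ncol(points)
  tab <- with_seed(seed, {
    res <- lapply(k_range, function(k) {
      if (k == nrow(points)) {
        return(c(mean_aic = aic_kmeans(0, m, k), sd_aic = 0))
      }
      aics <- vapply(seq_len(n_iterations), function(i) {
        km <- tryCatch(
          suppressWarnings(stats::kmeans(points, centers = k, nstart = 1,
                                         iter.max = 100,
                                         algorithm = "Hartigan-Wong")),
          error = function(e) NULL)
        if (is.null(km)) return(NA_real_)
        aic_kmeans(km$tot.withinss, m, k)
      }, numeric(1))
      aics <- aics[is.finite(aics)]
      c(mean_aic = mean(aics), sd_aic = stats::sd(aics))
    })
    data.frame(k = k_range, do.call(rbind, res))
  })
  i_min <- which.min(tab$mean_aic)
  chosen <- if (tie_rule == "strict_min") {
    tab$k[i_min]
  } else {
    band <- tab$mean_aic[i_min] + max(tab$sd_aic[i_min], 0, na.rm = TRUE)
    max(tab$k[tab$mean_aic <= band])
  }
  structure(list(table = tab, chosen_k = chosen, n_iterations = n_iterations,
                 k_range = k_range, tie_rule = tie_rule),
            class = "cluster_selection")
}

#' Final clustering with progression ordering
#'
#' Runs best-of-`n_starts` Hartigan-Wong k-means at the chosen cluster count,
#' then orders the clusters into a morphology progression by their mean score
#' on the first principal component. The direction is normalized using the
#' cluster mean curves when available: rank 1 is the end of the progression
#' whose mean curve correlates best with the ventilation-dependent reference
#' template (PaO2 peaking at end-inspiration), rank K the inverted end.
#'
#' @param points n x m score matrix (column 1 = PC1).
#' @param k cluster count.
#' @param seed integer seed.
#' @param n_starts initializations for the final fit.
#' @param curves optional n x p matrix of the normalized breaths, used for
#'   mean curves and direction normalization.
#' @param insp_fraction inspiratory fraction (for the reference template).
#' @return list of class `ordered_clustering`: `assignments` (cluster ids),
#'   `progression_rank` (per condition), `rank_of_cluster` (map), `centers`,
#'   `wcss`, `k`, `cluster_means` (p x k matrix or NULL), `sizes`.
#' @export
finalize_clustering <- function(points, k, seed, n_starts = 100, curves = NULL,
                                insp_fraction = 1 / 3) {
  points <- as.matrix(points)
  km <- kmeans_hw(points, k, seed = seed, n_starts = n_starts)
  mean_pc1 <- vapply(seq_len(k), function(c) mean(points[km$assignments == c, 1]),
                     numeric(1))
  ord <- order(mean_pc1)            # ascending PC1
  rank_of_cluster <- integer(k)
  rank_of_cluster[ord] <- seq_len(k)

  cluster_means <- NULL
  if (!is.null(curves) && k >= 2) {
    curves <- as.matrix(curves)
    cluster_means <- vapply(seq_len(k), function(c) {
      colMeans(curves[km$assignments == c, , drop = FALSE])
    }, numeric(ncol(curves)))
    ref <- breath_template(morphology_params(0), n_samples = ncol(curves),
                           insp_fraction = insp_fraction)
    first <- which(rank_of_cluster == 1)
    last <- which(rank_of_cluster == k)
    if (stats::cor(cluster_means[, first], ref) < stats::cor(cluster_means[, last], ref)) {
      rank_of_cluster <- (k + 1L) - rank_of_cluster
    }
  }
  rank_of_cluster <- as.integer(rank_of_cluster)
  structure(list(
    assignments = km$assignments,
    progression_rank = rank_of_cluster[km$assignments],
    rank_of_cluster = rank_of_cluster,
    centers = km$centers, wcss = km$wcss, k = k,
    cluster_means = cluster_means,
    sizes = tabulate(km$assignments, k)
  ), class = "ordered_clustering")
}
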