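#' Functional principal component analysis on the canonical breath grid
#'
#' Decomposes a sample of normalized breaths \eqn{x_i(t)} on the dense regular
#' grid into a mean function \eqn{\mu(t)} and orthonormal eigenfunctions
#' \eqn{\phi_k(t)} of the sample covariance operator, with per-curve scores
#' \eqn{\xi_{ik} = \sum_j (x_i(t_j) - \mu(t_j))\,\phi_k(t_j)\,\Delta t}.
#' Because the grid is dense and regular the decomposition is computed exactly
#' as the singular value decomposition of the centred curve matrix with
#' rectangle-rule quadrature weight \eqn{\Delta t}; no smoothing is applied
#' (an optional pre-smoother can be supplied). Eigenfunctions are unit-norm in
#' \eqn{L^2(\Delta t)} and their sign is fixed so that the element of largest
#' absolute value is positive, making fits reproducible. The covariance uses
#' the 1/(n-1) normalization, so eigenvalues are score variances.
#'
#' @param curves numeric matrix, one curve per row (n x 600 at the defaults),
#'   all on the same grid; or a list of [normalize_breath()] results.
#' @param grid_dt grid spacing, seconds.
#' @param smoother optional function applied to each curve before fitting.
#' @return object of class `fpca_model`: `mu`, `phi` (grid x K matrix),
#'   `lambda` (descending eigenvalues), `var_frac`, `scores` (n x K),
#'   `grid_dt`, `n`.
#' @export
fit_fpca <- function(curves, grid_dt = 0.1, smoother = NULL) {
  if (is.list(curves) && !is.matrix(curves)) {
    ids <- vapply(curves, function(b) as.character(b$condition_id), "")
    curves <- do.call(rbind, lapply(curves, `[[`, "values"))
    rownames(curves) <- ids
  }
  if (!is.matrix(curves) || nrow(curves) < 2) {
    stop("need a matrix with at least 2 curves", call. = FALSE)
  }
  if (anyNA(curves)) stop("curves contain NA", call. = FALSE)
  if (!is.null(smoother)) curves <- t(apply(curves, 1, smoother))

  n <- nrow(curves)
  mu <- colMeans(curves)
  xc <- sweep(curves, 2, mu)
  sv <- svd(xc)
  lambda <- sv$d^2 / (n - 1) * grid_dt
  keep <- lambda > max(lambda[1], 0) * 1e-10
  if (!any(keep)) keep[1] <- TRUE
  lambda <- lambda[keep]
  phi <- sv$v[, keep, drop = FALSE] / sqrt(grid_dt)
  # sign convention: largest-|element| of each eigenfunction is positive
  for (k in seq_len(ncol(phi))) {
    j <- which.max(abs(phi[, k]))
    if (phi[j, k] < 0) phi[, k] <- -phi[, k]
  }
  scores <- xc %*% phi * grid_dt
  rownames(scores) <- rownames(curves)
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))
  total <- sum(lambda)
  structure(list(mu = mu, phi = phi, lambda = lambda,
                 var_frac = if (total > 0) lambda / total else rep(0, length(lambda)),
                 scores = scores, grid_dt = grid_dt, n = n),
            class = "fpca_model")
}

#' Number of components needed to reach a variance threshold
#'
#' @param model an `fpca_model`.
#' @param threshold fraction of total variance, in (0, 1\].
#' @return smallest K whose cumulative variance fraction reaches the
#'   threshold.
#' @export
n_components_for_threshold <- function(model, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  if (sum(model$lambda) <= 0) stop("model has no variance", call. = FALSE)
  cum <- cumsum(model$var_frac)
  which(cum >= threshold - 1e-12)[1]
}

#' Project a curve onto the eigenfunctions
#'
#' Inner products of the centred curve against each eigenfunction with
#' rectangle-rule weight; projecting the mean curve gives the zero vector.
#'
#' @param model an `fpca_model`.
#' @param curve numeric vector on the model grid.
#' @return named numeric score vector.
#' @export
fpca_project <- function(model, curve) {
  if (length(curve) != length(model$mu)) {
    stop("curve is not on the model grid", call. = FALSE)
  }
  drop((curve - model$mu) %*% model$phi) * model$grid_dt
}

#' Reconstruct a curve from scores
#'
#' @param model an `fpca_model`.
#' @param scores numeric score vector (length >= K).
#' @param K number of components to use (default all).
#' @return reconstructed curve `mu + sum_k scores[k] * phi_k`.
#' @export
fpca_reconstruct <- function(model, scores, K = ncol(model$phi)) {
  stopifnot(K >= 0, K <= ncol(model$phi), length(scores) >= K)
  if (K == 0) return(model$mu)
  model$mu + drop(model$phi[, seq_len(K), drop = FALSE] %*% scores[seq_len(K)])
}
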