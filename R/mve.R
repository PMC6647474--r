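#' Fit a PCA score-space model on in-vitro analysis spectra
#'
#' In-vitro spectra are acquired with reliable probe contact, so their first
#' principal-component scores define the reference region for contact quality
#' control. The model is mean-centered (no scaling); loadings follow a fixed
#' sign convention (largest-magnitude element positive) for reproducibility.
#'
#' @param x Matrix of preprocessed spectra (rows = measurements) or an
#'   `analysis_set`.
#' @param n_components Number of components retained (default 3).
#' @return An object of class `spectra_pca` with elements `center`,
#'   `loadings` (features x components, orthonormal) and `explained`
#'   (variance fractions).
#' @export
fit_pca <- function(x, n_components = 3L) {
  m <- if (inherits(x, "analysis_set")) x$values else as.matrix(x)
  if (nrow(m) < 4L) {
    stop("at least 4 spectra are required to fit the score space",
         call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, numeric(1L))
  load <- sweep(load, 2L, flip, `*`)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(center = p$center, loadings = load,
                 explained = expl[seq_len(k)]),
            class = "spectra_pca")
}

#' Project spectra into a fitted PCA score space
#'
#' @param pca A `spectra_pca` model.
#' @param x Matrix of spectra (or `analysis_set`) with the same features the
#'   model was fitted on.
#' @return Score matrix (rows x components).
#' @export
project_scores <- function(pca, x) {
  m <- if (inherits(x, "analysis_set")) x$values else
    if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(m) != length(pca$center)) {
    stop("spectrum length does not match the fitted score space",
         call. = FALSE)
  }
  sweep(m, 2L, pca$center, `-`) %*% pca$loadings
}

#' Minimum volume enclosing ellipsoid (Khachiyan's algorithm)
#'
#' Computes the smallest-volume ellipsoid `{x : (x - c)' A (x - c) <= 1}`
#' containing every row of `scores`, via Khachiyan's barycentric coordinate
#' ascent on the dual problem. After convergence the shape matrix is rescaled
#' so that the farthest fitting point lies exactly on the unit boundary,
#' making the enclosure exact (the rescaling changes the volume by at most a
#' factor `(1 + tolerance)^(d/2)`).
#'
#' @param scores Point matrix (rows = points, columns = dimensions); at least
#'   `d + 1` affinely independent points are required.
#' @param tolerance Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1e4).
#' @return An object of class `mvee` with elements `center`, `shape`
#'   (symmetric positive-definite), `tolerance` and `n_points`.
#' @export
fit_mvee <- function(scores, tolerance = 1e-6, max_iter = 1e4) {
  x <- as.matrix(scores)
  n <- nrow(x)
  d <- ncol(x)
  if (n < d + 1L) {
    stop("need at least ", d + 1L, " points to fit an ellipsoid",
         call. = FALSE)
  }
  q <- t(cbind(x, 1))                       # (d+1) x n lifted points
  u <- rep(1 / n, n)
  it <- 0L
  repeat {
    xu <- q %*% (u * t(q))                  # (d+1) x (d+1)
    minv <- tryCatch(solve(xu), error = function(e) NULL)
    if (is.null(minv)) {
      stop(paste("points are affinely dependent (flat set); add a small",
                 "jitter or reduce the dimension"), call. = FALSE)
    }
    m_dist <- colSums(q * (minv %*% q))     # Mahalanobis distances
    j <- which.max(m_dist)
    maximum <- m_dist[j]
    step <- (maximum - d - 1) / ((d + 1) * (maximum - 1))
    if (maximum <= (1 + tolerance) * (d + 1) || it >= max_iter) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
    it <- it + 1L
  }
  center <- drop(crossprod(x, u))
  cov_u <- crossprod(x, u * x) - tcrossprod(center)
  shape <- solve(cov_u) / d
  shape <- (shape + t(shape)) / 2
  # rescale so every fitting point is enclosed exactly (boundary at the
  # farthest point)
  dev <- sweep(x, 2L, center, `-`)
  r2max <- max(rowSums((dev %*% shape) * dev))
  shape <- shape / r2max
  structure(list(center = center, shape = shape, tolerance = tolerance,
                 n_points = n, iterations = it),
            class = "mvee")
}

#' Squared ellipsoid distance of points from an ellipsoid center
#'
#' @param ellipsoid An `mvee`.
#' @param scores Point matrix.
#' @return Numeric vector `(x - c)' A (x - c)` per row; a point is inside the
#'   fitted ellipsoid iff this is `<= 1`.
#' @export
mvee_distance2 <- function(ellipsoid, scores) {
  x <- matrix(scores, ncol = length(ellipsoid$center))
  dev <- sweep(x, 2L, ellipsoid$center, `-`)
  rowSums((dev %*% ellipsoid$shape) * dev)
}

#' Classify points as inliers at a relative ellipsoid radius
#'
#' The fitted ellipsoid's radii are scaled uniformly by `radius_pct / 100`
#' (100 = fitted boundary; 105 is the pipeline's operating default, which
#' gave the smallest average test error in the source analysis).
#'
#' @param ellipsoid An `mvee`.
#' @param scores Point matrix.
#' @param radius_pct Relative radius in percent (> 0).
#' @return Logical vector, `TRUE` for inliers.
#' @export
classify_inliers <- function(ellipsoid, scores, radius_pct = 105) {
  if (radius_pct <= 0) stop("radius_pct must be positive", call. = FALSE)
  mvee_distance2(ellipsoid, scores) <= (radius_pct / 100)^2
}

#' Outlier counts over a sweep of relative ellipsoid radii
#'
#' @param ellipsoid An `mvee`.
#' @param scores Point matrix of in-vivo scores.
#' @param radii_pct Non-empty vector of relative radii (percent).
#' @param chosen_pct Radius at which per-spectrum flags are reported
#'   (default 105).
#' @return An object of class `outlier_report`: `counts` (data.frame of
#'   radius and outlier count), `inlier` (flags at `chosen_pct`),
#'   `chosen_pct`.
#' @export
radius_sweep <- function(ellipsoid, scores, radii_pct = c(75, 100, 105, 125, 150),
                         chosen_pct = 105) {
  if (length(radii_pct) < 1L) stop("radii_pct must be non-empty", call. = FALSE)
  d2 <- mvee_distance2(ellipsoid, scores)
  counts <- data.frame(
    radius_pct = radii_pct,
    n_outliers = vapply(radii_pct, function(r) sum(d2 > (r / 100)^2),
                        integer(1L))
  )
  structure(list(counts = counts,
                 inlier = d2 <= (chosen_pct / 100)^2,
                 chosen_pct = chosen_pct),
            class = "outlier_report")
}

#' Ellipsoid volume
#' @param ellipsoid An `mvee`.
#' @return Volume of the fitted (radius 100%) ellipsoid.
#' @export
mvee_volume <- function(ellipsoid) {
  d <- length(ellipsoid$center)
  unit <- pi^(d / 2) / gamma(d / 2 + 1)
  unit / sqrt(det(ellipsoid$shape))
}
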