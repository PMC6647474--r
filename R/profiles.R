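#' @useDynLib nirscart, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

N_PROFILE_POINTS <- 500L

#' Construct a depth profile
#'
#' A depth profile holds a tissue property sampled at 500 equally spaced
#' depth fractions on \[0, 1\], where 0 is the articular surface and 1 the
#' cartilage-bone interface. Proteoglycan (PG) content is expressed as
#' safranin-O optical density (OD, dimensionless, non-negative); collagen
#' orientation angle in degrees (0 = parallel to the surface, 90 =
#' perpendicular).
#'
#' @param values Numeric vector of length 500.
#' @param kind `"od"` or `"angle"`; used for range validation.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(values, kind = c("od", "angle")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != N_PROFILE_POINTS) {
    stop("a depth profile must have exactly ", N_PROFILE_POINTS, " points",
         call. = FALSE)
  }
  if (anyNA(values)) stop("depth profile contains missing values", call. = FALSE)
  if (kind == "od" && any(values < -1e-9)) {
    stop("optical density values must be non-negative", call. = FALSE)
  }
  if (kind == "angle" && (any(values < -1e-9) || any(values > 90 + 1e-9))) {
    stop("orientation angles must lie in [0, 90] degrees", call. = FALSE)
  }
  structure(list(depth = seq(0, 1, length.out = N_PROFILE_POINTS),
                 values = values, kind = kind),
            class = "depth_profile")
}

#' Resample an irregular depth profile to the standard 500-point grid
#'
#' Raw microscopy profiles are measured on arbitrary depth grids. They are
#' linearly interpolated onto 500 equally spaced points spanning the measured
#' depth range, which is rescaled to the \[0, 1\] depth-fraction convention.
#'
#' @param raw_depths Strictly increasing numeric vector (>= 2 samples).
#' @param raw_values Numeric vector of the same length.
#' @param kind Passed to [depth_profile()].
#' @return A `depth_profile`.
#' @export
#' @examples
#' p <- resample_profile(c(0, 1), c(0, 1))
#' p$values[100]  # == 99/499, linear interpolation
resample_profile <- function(raw_depths, raw_values, kind = "od") {
  if (length(raw_depths) < 2L) {
    stop("at least 2 depth samples are required", call. = FALSE)
  }
  if (length(raw_depths) != length(raw_values)) {
    stop("depths and values must have equal length", call. = FALSE)
  }
  if (any(diff(raw_depths) <= 0)) {
    stop("depths must be strictly increasing", call. = FALSE)
  }
  span <- range(raw_depths)
  frac <- (raw_depths - span[1L]) / (span[2L] - span[1L])
  grid <- seq(0, 1, length.out = N_PROFILE_POINTS)
  vals <- stats::approx(frac, raw_values, xout = grid, method = "linear")$y
  depth_profile(vals, kind = kind)
}

#' Mean of a depth profile over its first fraction
#'
#' The full-thickness value of a property is the mean over the whole profile
#' (`fraction = 1`); the superficial value is the mean over the first 25% of
#' depth (`fraction = 0.25`), i.e. the first `ceiling(0.25 * 500) = 125` grid
#' points.
#'
#' @param profile A `depth_profile`.
#' @param fraction Depth fraction in (0, 1].
#' @return Scalar mean value.
#' @export
profile_mean <- function(profile, fraction = 1) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * N_PROFILE_POINTS)
  mean(profile$values[seq_len(k)])
}

#' Pointwise average of depth profiles
#'
#' @param profiles A list of `depth_profile` objects on the common grid.
#' @return A `depth_profile` with the elementwise mean values.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) < 1L) stop("no profiles to average", call. = FALSE)
  if (!all(vapply(profiles, inherits, logical(1L), "depth_profile"))) {
    stop("all elements must be depth_profile objects", call. = FALSE)
  }
  kinds <- unique(vapply(profiles, `[[`, character(1L), "kind"))
  if (length(kinds) != 1L) {
    stop("cannot average profiles of different kinds", call. = FALSE)
  }
  m <- vapply(profiles, `[[`, numeric(N_PROFILE_POINTS), "values")
  depth_profile(rowMeans(as.matrix(m)), kind = kinds)
}

#' Extract the five regression targets from reference profiles
#'
#' Assembles cartilage thickness, full-thickness and superficial (first 25%)
#' PG content, and full-thickness and superficial collagen orientation angle
#' from a PG depth profile, an orientation-angle depth profile and a thickness
#' measurement.
#'
#' @param pg_profile `depth_profile` of optical density.
#' @param angle_profile `depth_profile` of orientation angle.
#' @param thickness Cartilage thickness in mm (> 0).
#' @return A one-row `data.frame` with columns `thickness`, `pg_full`,
#'   `pg_sup`, `angle_full`, `angle_sup`.
#' @export
extract_references <- function(pg_profile, angle_profile, thickness) {
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0) {
    stop("thickness must be a positive scalar (mm)", call. = FALSE)
  }
  data.frame(
    thickness  = thickness,
    pg_full    = profile_mean(pg_profile, 1),
    pg_sup     = profile_mean(pg_profile, 0.25),
    angle_full = profile_mean(angle_profile, 1),
    angle_sup  = profile_mean(angle_profile, 0.25)
  )
}

#' Names of the five regression targets
#' @return Character vector of target column names.
#' @export
target_names <- function() {
  c("thickness", "pg_full", "pg_sup", "angle_full", "angle_sup")
}
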