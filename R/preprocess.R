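#' Preprocessing configuration
#'
#' The two detector segments are filtered separately with a Savitzky-Golay
#' polynomial filter whose window matches each detector's sampling (139
#' points = 0.08 um on detector A; 41 points = 0.26 um on detector B), then
#' cropped to the analysis region and concatenated. The first derivative is
#' computed in a single filter pass and scaled by the per-segment wavelength
#' spacing so both segments share d/dlambda units.
#'
#' @param window_a,window_b Filter window lengths in points (odd, larger than
#'   the polynomial degree).
#' @param poly_degree Local polynomial degree (default 3).
#' @param derivative_order Derivative order (default 1; must not exceed
#'   `poly_degree`).
#' @param crop Analysis wavelength interval in um (default `c(0.80, 1.90)`;
#'   the visible region below 0.80 um is contaminated by the arthroscopic
#'   light source and discarded).
#' @param boundary Detector A is used below this wavelength and detector B
#'   from it upward (default 1.0 um, the middle of the physical overlap).
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(window_a = 139L, window_b = 41L,
                              poly_degree = 3L, derivative_order = 1L,
                              crop = c(0.80, 1.90), boundary = 1.0) {
  for (w in c(window_a, window_b)) {
    if (w %% 2L == 0L || w <= poly_degree) {
      stop("filter windows must be odd and larger than the polynomial degree",
           call. = FALSE)
    }
  }
  if (derivative_order > poly_degree || derivative_order < 0L) {
    stop("derivative_order must lie in [0, poly_degree]", call. = FALSE)
  }
  if (length(crop) != 2L || crop[1L] >= crop[2L]) {
    stop("crop must be an increasing wavelength interval", call. = FALSE)
  }
  structure(list(window_a = as.integer(window_a),
                 window_b = as.integer(window_b),
                 poly_degree = as.integer(poly_degree),
                 derivative_order = as.integer(derivative_order),
                 crop = crop, boundary = boundary),
            class = "preprocess_config")
}

# convolution kernel of the Savitzky-Golay filter: value (or derivative) of
# the local least-squares polynomial at the window center
sg_kernel <- function(window, degree, deriv = 0L, spacing = 1) {
  h <- (window - 1L) %/% 2L
  x <- (-h:h) * spacing
  v <- outer(x, 0:degree, `^`)
  proj <- solve(crossprod(v), t(v))        # (degree+1) x window
  factorial(deriv) * proj[deriv + 1L, ]
}

#' Savitzky-Golay filtering / differentiation of a uniformly sampled series
#'
#' Replaces each point having a full centered window by the value (or
#' `deriv`-th derivative, scaled by `spacing^-deriv`) of the local
#' least-squares polynomial of the given degree. Only interior positions are
#' returned: no padded extrapolation is performed at the edges, so the output
#' has `length(values) - window + 1` elements, aligned with input positions
#' `(window-1)/2 + 1` through `length(values) - (window-1)/2`.
#'
#' @param values Numeric series sampled at uniform spacing.
#' @param window Odd window length in points, greater than `degree`.
#' @param degree Polynomial degree.
#' @param deriv Derivative order (0 = smoothing).
#' @param spacing Sample spacing used to scale derivatives.
#' @return Numeric vector of filtered interior values.
#' @export
#' @examples
#' savgol(seq(0, 1, length.out = 21)^3, window = 7, degree = 3)  # exact
savgol <- function(values, window, degree = 3L, deriv = 0L, spacing = 1) {
  if (window %% 2L == 0L || window <= degree) {
    stop("window must be odd and larger than degree", call. = FALSE)
  }
  if (deriv > degree) stop("deriv must not exceed degree", call. = FALSE)
  if (length(values) < window) {
    stop("series is shorter than the filter window", call. = FALSE)
  }
  k <- sg_kernel(window, degree, deriv, spacing)
  # embed() lists each window in reverse order
  drop(stats::embed(values, window) %*% rev(k))
}

# per-segment output description: input indices kept and the sparse filter
# operator (input length x output length) so whole cohorts are preprocessed
# with one matrix product per segment
sg_operator <- function(wavelengths, window, degree, deriv, keep_idx) {
  spacing <- grid_spacing(wavelengths)
  k <- sg_kernel(window, degree, deriv, spacing)
  h <- (window - 1L) %/% 2L
  n <- length(wavelengths)
  op <- matrix(0, nrow = n, ncol = length(keep_idx))
  for (j in seq_along(keep_idx)) {
    op[(keep_idx[j] - h):(keep_idx[j] + h), j] <- k
  }
  op
}

# which input indices of each segment survive interior filtering, the
# crop interval and the detector boundary rule
analysis_indices <- function(grids, config) {
  eps <- 1e-9
  h_a <- (config$window_a - 1L) %/% 2L
  h_b <- (config$window_b - 1L) %/% 2L
  if (length(grids$A) < config$window_a || length(grids$B) < config$window_b) {
    stop("detector grid shorter than its filter window", call. = FALSE)
  }
  interior_a <- seq(h_a + 1L, length(grids$A) - h_a)
  interior_b <- seq(h_b + 1L, length(grids$B) - h_b)
  idx_a <- interior_a[grids$A[interior_a] >= config$crop[1L] - eps &
                        grids$A[interior_a] < config$boundary - eps]
  idx_b <- interior_b[grids$B[interior_b] >= config$boundary - eps &
                        grids$B[interior_b] <= config$crop[2L] + eps]
  if (length(idx_a) + length(idx_b) == 0L) {
    stop("crop interval lies outside the filterable wavelength range",
         call. = FALSE)
  }
  list(A = idx_a, B = idx_b)
}

new_analysis_set <- function(wavelengths, segment, values, meta, config) {
  colnames(values) <- sprintf("%s_%.6f", segment, wavelengths)
  structure(list(wavelengths = wavelengths, segment = segment,
                 values = values, meta = meta, config = config),
            class = "analysis_set")
}

#' Preprocess raw spectra into derivative analysis spectra
#'
#' Applies Savitzky-Golay derivative filtering per detector segment, crops to
#' the analysis interval, resolves the detector overlap (A below `boundary`,
#' B from `boundary` upward) and concatenates the segments. Because only
#' interior filter positions are kept, detector B contributes from its first
#' interior wavelength (1.128 um under the defaults) upward.
#'
#' @param x A `nirs_cohort`, a `raw_spectrum`, or a plain list with intensity
#'   vectors `A` and `B`.
#' @param config A [preprocess_config()].
#' @param grids Detector grids (taken from the cohort or spectrum when
#'   available).
#' @param ... Unused.
#' @return An `analysis_set`: `wavelengths` (um, increasing within each
#'   segment block), `segment` labels, `values` (rows = spectra), `meta`
#'   (carried over from the cohort, `NULL` for single spectra), `config`.
#' @export
preprocess <- function(x, config = preprocess_config(), ...) {
  UseMethod("preprocess")
}

#' @rdname preprocess
#' @export
preprocess.nirs_cohort <- function(x, config = preprocess_config(), ...) {
  res <- preprocess_matrices(x$intensity, x$grids, config)
  new_analysis_set(res$wavelengths, res$segment, res$values, x$meta, config)
}

#' @rdname preprocess
#' @export
preprocess.raw_spectrum <- function(x, config = preprocess_config(),
                                    grids = attr(x, "grids"), ...) {
  if (is.null(grids)) grids <- default_grids()
  res <- preprocess_matrices(list(A = matrix(x$A, nrow = 1L),
                                  B = matrix(x$B, nrow = 1L)),
                             grids, config)
  new_analysis_set(res$wavelengths, res$segment, res$values, NULL, config)
}

#' @rdname preprocess
#' @export
preprocess.list <- function(x, config = preprocess_config(),
                            grids = default_grids(), ...) {
  preprocess.raw_spectrum(x, config, grids)
}

preprocess_matrices <- function(intensity, grids, config) {
  idx <- analysis_indices(grids, config)
  parts <- list()
  for (seg in c("A", "B")) {
    if (length(idx[[seg]]) == 0L) next
    w <- if (seg == "A") config$window_a else config$window_b
    op <- sg_operator(grids[[seg]], w, config$poly_degree,
                      config$derivative_order, idx[[seg]])
    parts[[seg]] <- list(wavelengths = grids[[seg]][idx[[seg]]],
                         values = intensity[[seg]] %*% op)
  }
  list(wavelengths = unlist(lapply(parts, `[[`, "wavelengths"),
                            use.names = FALSE),
       segment = rep(names(parts),
                     vapply(parts, function(p) length(p$wavelengths),
                            integer(1L))),
       values = do.call(cbind, lapply(parts, `[[`, "values")))
}

#' Average repeat spectra
#'
#' Pointwise arithmetic mean of analysis spectra sharing a wavelength grid.
#'
#' @param x A list of single-spectrum `analysis_set` objects, or one
#'   `analysis_set` whose rows are averaged within groups.
#' @param by For the `analysis_set` method: metadata columns defining the
#'   groups (default location and modality, so the repeat index is averaged
#'   out).
#' @param ... Unused.
#' @return An `analysis_set` with one row (list method) or one row per group.
#' @export
average_repeats <- function(x, ...) UseMethod("average_repeats")

#' @rdname average_repeats
#' @export
average_repeats.list <- function(x, ...) {
  if (length(x) < 1L) stop("no spectra to average", call. = FALSE)
  wl <- x[[1L]]$wavelengths
  for (s in x) {
    if (length(s$wavelengths) != length(wl) ||
        any(abs(s$wavelengths - wl) > 1e-12)) {
      stop("spectra are on different analysis grids", call. = FALSE)
    }
  }
  vals <- do.call(rbind, lapply(x, function(s) s$values))
  out <- x[[1L]]
  out$values <- matrix(colMeans(vals), nrow = 1L,
                       dimnames = list(NULL, colnames(x[[1L]]$values)))
  out$meta <- NULL
  out
}

#' @rdname average_repeats
#' @export
average_repeats.analysis_set <- function(x, by = c("loc_id", "modality"),
                                         ...) {
  if (is.null(x$meta)) stop("analysis set has no metadata to group by",
                            call. = FALSE)
  key <- interaction(x$meta[by], drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(x$values)), key)
  vals <- do.call(rbind, lapply(groups, function(i) {
    colMeans(x$values[i, , drop = FALSE])
  }))
  meta <- x$meta[vapply(groups, `[`, integer(1L), 1L), , drop = FALSE]
  meta$rep <- NA_integer_
  rownames(meta) <- NULL
  out <- x
  out$values <- vals
  out$meta <- meta
  out
}
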