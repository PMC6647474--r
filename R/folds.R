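#' Rank-paired animal-level cross-validation folds
#'
#' Fold assignment is done at the animal level so that calibration and
#' validation never share a pony. For each reference property, ponies are
#' sorted in ascending order of their pony-specific mean value; fold k
#' validates the ponies of rank k and rank `k + ceiling(n/2)` (ranks 1-6,
#' 2-7, ... for the 10-pony design), which keeps both sets representative of
#' the full value range. Ties in the mean are broken by pony identifier so
#' the plan is invariant to input order.
#'
#' @param pony_means Named numeric vector: mean target value per pony.
#' @param target Optional target name carried for provenance.
#' @return An object of class `fold_plan`: a list with `target`, `ranking`
#'   (ponies in ascending order) and `folds`, each fold a list with
#'   `validation` and `calibration` pony identifiers.
#' @export
#' @examples
#' means <- setNames(1:10, LETTERS[1:10])
#' make_folds(means)$folds[[1]]$validation  # "A" "F"
make_folds <- function(pony_means, target = NA_character_) {
  ids <- names(pony_means)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("pony_means must be a named vector", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate pony identifiers", call. = FALSE)
  n <- length(ids)
  if (n < 4L) stop("need at least 4 ponies for cross-validation", call. = FALSE)
  ord <- order(pony_means, ids)
  ranking <- ids[ord]
  half <- ceiling(n / 2)
  n_folds <- half
  folds <- lapply(seq_len(n_folds), function(k) {
    val_ranks <- c(k, k + half)
    val_ranks <- val_ranks[val_ranks <= n]
    validation <- ranking[val_ranks]
    list(validation = validation,
         calibration = setdiff(ranking, validation))
  })
  structure(list(target = target, ranking = ranking, folds = folds),
            class = "fold_plan")
}

#' Fit target and feature scalers on calibration data
#'
#' Reference targets are range-scaled to \[0, 1\] using the calibration
#' minimum and maximum; spectra are standardized per feature by the
#' calibration mean and standard deviation. Constant features (zero standard
#' deviation) are given unit scale so they map to exactly zero after
#' centering.
#'
#' @param y_cal Calibration target values.
#' @param x_cal Calibration spectra (rows = measurements).
#' @return An object of class `scaler_params`.
#' @export
fit_scalers <- function(y_cal, x_cal) {
  if (length(y_cal) < 1L || nrow(x_cal) < 1L) {
    stop("calibration set is empty", call. = FALSE)
  }
  rng <- range(y_cal)
  if (diff(rng) <= 0) {
    stop("calibration target is constant; range scaling is degenerate",
         call. = FALSE)
  }
  mu <- colMeans(x_cal)
  sd_ <- apply(x_cal, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  structure(list(target_min = rng[1L], target_max = rng[2L],
                 feat_mean = mu, feat_sd = sd_),
            class = "scaler_params")
}

#' @rdname fit_scalers
#' @param scalers A `scaler_params` object.
#' @param y Target values to scale to \[0, 1\] (calibration range).
#' @export
scale_targets <- function(scalers, y) {
  (y - scalers$target_min) / (scalers$target_max - scalers$target_min)
}

#' @rdname fit_scalers
#' @param y_scaled Scaled target values to map back to physical units.
#' @export
unscale_targets <- function(scalers, y_scaled) {
  y_scaled * (scalers$target_max - scalers$target_min) + scalers$target_min
}

#' @rdname fit_scalers
#' @param x Spectra to standardize with the calibration statistics.
#' @export
scale_features <- function(scalers, x) {
  sweep(sweep(x, 2L, scalers$feat_mean, `-`), 2L, scalers$feat_sd, `/`)
}
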