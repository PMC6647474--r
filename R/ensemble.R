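#' Train the six-member ensemble for one fold and one target
#'
#' Trains both architectures (convolutional and dense), each initialized with
#' the three fixed seeds, on the calibration spectra of one cross-validation
#' fold. Calibration rows are the individual in-vitro repeat spectra (three
#' per location), which acts as data augmentation. Scalers are fitted on the
#' calibration set only; targets are range-scaled to \[0, 1\] and spectra
#' standardized per feature before training.
#'
#' @param x_cal,y_cal Calibration spectra (rows = repeat measurements) and
#'   their reference target values in physical units.
#' @param x_val,y_val Validation spectra and targets (held-out ponies).
#' @param config A [train_config()].
#' @param fold Fold index carried for provenance.
#' @param target Target name carried for provenance.
#' @return An object of class `nirs_ensemble` with the six trained members,
#'   the fitted `scaler_params`, fold id and target name.
#' @export
train_ensemble <- function(x_cal, y_cal, x_val, y_val,
                           config = train_config(),
                           fold = NA_integer_, target = NA_character_) {
  scalers <- fit_scalers(y_cal, x_cal)
  xs_cal <- scale_features(scalers, x_cal)
  xs_val <- scale_features(scalers, x_val)
  ys_cal <- scale_targets(scalers, y_cal)
  ys_val <- scale_targets(scalers, y_val)
  members <- list()
  for (arch in list(architecture_conv(), architecture_dense())) {
    for (seed in config$seeds) {
      model <- build_model(arch, ncol(x_cal), seed)
      model <- train_member(model, xs_cal, ys_cal, xs_val, ys_val, config)
      members[[paste(arch$variant, seed, sep = "_")]] <- model
    }
  }
  structure(list(members = members, scalers = scalers,
                 fold = fold, target = target,
                 input_length = ncol(x_cal)),
            class = "nirs_ensemble")
}

#' Predict reference values with a trained ensemble
#'
#' The ensemble prediction is the arithmetic mean of the six member outputs,
#' mapped back to physical units with the fold's target scaler.
#'
#' @param object A `nirs_ensemble`.
#' @param newdata Spectra in raw (unscaled) analysis space, rows = spectra.
#' @param members If `TRUE`, also return the per-member predictions.
#' @param ... Unused.
#' @return Numeric vector of predictions (or a list with `ensemble` and
#'   `members` when `members = TRUE`).
#' @export
predict.nirs_ensemble <- function(object, newdata, members = FALSE, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$input_length) {
    stop("spectrum length does not match the ensemble's analysis grid",
         call. = FALSE)
  }
  xs <- scale_features(object$scalers, x)
  per_member <- vapply(object$members, function(m) nn_predict(m, xs),
                       numeric(nrow(x)))
  per_member <- matrix(per_member, nrow = nrow(x),
                       dimnames = list(NULL, names(object$members)))
  ens <- unscale_targets(object$scalers, rowMeans(per_member))
  if (members) {
    list(ensemble = ens,
         members = unscale_targets(object$scalers, per_member))
  } else {
    ens
  }
}
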