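#' Aggregate repeat predictions to a location-level prediction
#'
#' In-vitro repeat predictions are plain averages; in-vivo repeat predictions
#' are averaged over the non-outlier repeats only. If every repeat at a
#' location is flagged as an outlier the location-level prediction is
#' missing (`NA`) and a warning is issued; such locations are excluded from
#' metrics downstream.
#'
#' @param predictions Numeric vector of per-repeat predictions.
#' @param inlier Logical vector of inlier flags (default all `TRUE`).
#' @return Scalar mean over inlier repeats, or `NA`.
#' @export
aggregate_by_location <- function(predictions,
                                  inlier = rep(TRUE, length(predictions))) {
  if (length(predictions) < 1L) {
    stop("at least one repeat prediction is required", call. = FALSE)
  }
  if (!any(inlier)) {
    warning("all repeats flagged as outliers; location prediction is missing",
            call. = FALSE)
    return(NA_real_)
  }
  mean(predictions[inlier])
}

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties). Pairs with
#' missing values are dropped; at least 3 complete pairs are required and an
#' all-constant input is an error (the correlation is undefined).
#'
#' @param x,y Paired numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs for a rank correlation",
         call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho)) {
    stop("rank correlation undefined (constant input)", call. = FALSE)
  }
  rho
}

#' Root mean square error and normalized RMSE
#'
#' `nrmse_pct` normalizes an RMSE by the overall range of the reference
#' values and expresses it in percent (reported to one decimal in tables).
#'
#' @param pred,ref Paired predictions and reference values (missing pairs
#'   dropped).
#' @return `rmse_value`: RMSE in target units.
#' @export
rmse_value <- function(pred, ref) {
  ok <- is.finite(pred) & is.finite(ref)
  if (!any(ok)) stop("no complete pairs", call. = FALSE)
  sqrt(mean((pred[ok] - ref[ok])^2))
}

#' @rdname rmse_value
#' @param rmse An RMSE in target units.
#' @param ref_min,ref_max Reference value range (`ref_max > ref_min`).
#' @return `nrmse_pct`: normalized RMSE in percent.
#' @export
nrmse_pct <- function(rmse, ref_min, ref_max) {
  if (ref_max <= ref_min) {
    stop("reference range is degenerate (max <= min)", call. = FALSE)
  }
  100 * rmse / (ref_max - ref_min)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration over all group assignments for combined sample sizes up
#' to 20 (ties handled via mid-ranks; the two-sided p-value is the
#' probability of a U at least as far from its null mean as observed, so two
#' identical groups give p = 1); the normal approximation with tie
#' correction is used for larger samples.
#'
#' @param x,y Numeric samples from the two groups (each non-empty, total
#'   size >= 3 recommended).
#' @return A list with `statistic` (U for group `x`), `p.value` and `method`.
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 20L) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
    list(statistic = u_obs, p.value = p,
         method = "Mann-Whitney U (exact enumeration)")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(statistic = u_obs, p.value = wt$p.value,
         method = "Mann-Whitney U (normal approximation)")
  }
}

#' Paired Wilcoxon signed-rank test
#'
#' Used to compare measured and predicted reference values. Zero differences
#' are dropped (standard convention); if every difference is zero the test
#' is degenerate and p = 1 is reported with a warning. The exact distribution
#' is used for up to 25 non-zero differences without ties, otherwise the
#' normal approximation.
#'
#' @param measured,predicted Paired numeric vectors.
#' @return A list with `statistic` (V), `p.value` and `method`.
#' @export
compare_paired <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 1L) {
    stop("measured and predicted must be non-empty and paired", call. = FALSE)
  }
  d <- predicted - measured
  if (all(d == 0)) {
    warning("all paired differences are zero; signed-rank test degenerate",
            call. = FALSE)
    return(list(statistic = 0, p.value = 1,
                method = "Wilcoxon signed rank (degenerate: all ties)"))
  }
  nz <- sum(d != 0)
  use_exact <- nz <= 25L && !anyDuplicated(abs(d[d != 0]))
  wt <- suppressWarnings(stats::wilcox.test(predicted, measured,
                                            paired = TRUE,
                                            exact = use_exact))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}

#' Per-target, per-set performance metrics
#'
#' Computes Spearman's rho, RMSE and normalized RMSE for each combination of
#' target and evaluation set from a long table of location-level prediction
#' records. Validation records are pooled across folds (each location
#' predicted exactly once, by the fold holding out its pony) and an error is
#' raised if pooling finds a location predicted more than once.
#'
#' @param records Data frame with columns `target`, `set` (calibration /
#'   validation / test), `loc_id`, `fold`, `prediction`, `reference`.
#' @param ref_ranges Named list (per target) of `c(min, max)` reference
#'   ranges used for NRMSE normalization.
#' @return Data frame with one row per target x set: `rho`, `rmse`,
#'   `nrmse_pct`, `n` (missing predictions excluded, counted in
#'   `n_missing`).
#' @export
evaluate_sets <- function(records, ref_ranges) {
  stopifnot(all(c("target", "set", "loc_id", "prediction", "reference") %in%
                  names(records)))
  val <- records[records$set == "validation", ]
  dup <- duplicated(val[, c("target", "loc_id")])
  if (any(dup)) {
    stop("validation pooling error: location predicted by more than one fold",
         call. = FALSE)
  }
  combos <- unique(records[, c("target", "set")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    r <- records[records$target == combos$target[i] &
                   records$set == combos$set[i], ]
    ok <- is.finite(r$prediction)
    rng <- ref_ranges[[combos$target[i]]]
    rm_ <- rmse_value(r$prediction[ok], r$reference[ok])
    data.frame(target = combos$target[i], set = combos$set[i],
               rho = spearman_rho(r$prediction[ok], r$reference[ok]),
               rmse = rm_,
               nrmse_pct = nrmse_pct(rm_, rng[1L], rng[2L]),
               n = sum(ok), n_missing = sum(!ok))
  }))
  rownames(out) <- NULL
  out
}

#' Outlier-radius sweep of test-set performance
#'
#' Re-aggregates the cached per-repeat in-vivo predictions at each relative
#' ellipsoid radius and recomputes test metrics: the average (over targets)
#' RMSE on range-scaled values, the average Spearman correlation, and the
#' number of outlier spectra. Locations whose repeats are all rejected at a
#' radius are excluded from the metrics at that radius.
#'
#' @param repeat_predictions Data frame with columns `target`, `loc_id`,
#'   `prediction`, `reference` and `d2` (squared ellipsoid distance of the
#'   repeat's score).
#' @param ref_ranges Named list of reference ranges per target.
#' @param radii_pct Vector of relative radii in percent.
#' @return Data frame with one row per radius: `radius_pct`,
#'   `avg_scaled_rmse`, `avg_rho`, `n_outliers`.
#' @export
sweep_performance <- function(repeat_predictions, ref_ranges,
                              radii_pct = c(75, 100, 105, 125, 150)) {
  stopifnot(length(radii_pct) >= 1L)
  rp <- repeat_predictions
  targets <- unique(rp$target)
  # outlier counts are per spectrum, so count within a single target's rows
  one_target <- rp[rp$target == targets[1L], ]
  out <- do.call(rbind, lapply(radii_pct, function(r) {
    thr <- (r / 100)^2
    per_target <- vapply(targets, function(tg) {
      tr <- rp[rp$target == tg, ]
      agg <- tapply(seq_len(nrow(tr)), tr$loc_id, function(i) {
        keep <- tr$d2[i] <= thr
        c(pred = if (any(keep)) mean(tr$prediction[i][keep]) else NA_real_,
          ref = tr$reference[i][1L])
      })
      agg <- do.call(rbind, agg)
      ok <- is.finite(agg[, "pred"])
      rng <- ref_ranges[[tg]]
      sc <- function(v) (v - rng[1L]) / (rng[2L] - rng[1L])
      c(rmse = rmse_value(sc(agg[ok, "pred"]), sc(agg[ok, "ref"])),
        rho = spearman_rho(agg[ok, "pred"], agg[ok, "ref"]))
    }, numeric(2L))
    data.frame(radius_pct = r,
               avg_scaled_rmse = mean(per_target["rmse", ]),
               avg_rho = mean(per_target["rho", ]),
               n_outliers = sum(one_target$d2 > thr))
  }))
  rownames(out) <- NULL
  out
}
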