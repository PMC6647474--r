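#' Pipeline configuration
#'
#' Bundles the per-stage configurations with the orchestration-level choices:
#' which reference targets to model, the number of score components, the
#' outlier operating radius, the radius sweep, and an optional output
#' directory for run artifacts. A `seed` given here overrides the cohort
#' seed, so all randomness flows from one global seed plus the fixed member
#' initialization seeds of [train_config()].
#'
#' @param cohort A [cohort_config()].
#' @param forward A [forward_params()].
#' @param preprocessing A [preprocess_config()].
#' @param training A [train_config()].
#' @param targets Reference targets to model (subset of [target_names()]).
#' @param n_components Score-space dimension for outlier detection.
#' @param radius_pct Operating relative ellipsoid radius in percent.
#' @param sweep_radii Radii (percent) for the performance/count sweep.
#' @param predict_calibration Also predict the calibration spectra of every
#'   fold (the most expensive and least informative evaluation set; disable
#'   for reduced-budget runs).
#' @param seed Optional global seed overriding `cohort$seed`.
#' @param out_dir Optional run directory; when set, every stage's outputs are
#'   persisted as CSV/JSON as the run progresses (partial outputs are
#'   retained if a later stage fails).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            forward = forward_params(),
                            preprocessing = preprocess_config(),
                            training = train_config(),
                            targets = target_names(),
                            n_components = 3L,
                            radius_pct = 105,
                            sweep_radii = c(75, 100, 105, 125, 150),
                            predict_calibration = TRUE,
                            seed = NULL,
                            out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(forward, "forward_params"),
            inherits(preprocessing, "preprocess_config"),
            inherits(training, "train_config"))
  if (length(targets) < 1L || !all(targets %in% target_names())) {
    stop("targets must be a non-empty subset of target_names()",
         call. = FALSE)
  }
  if (radius_pct <= 0) stop("radius_pct must be positive", call. = FALSE)
  if (length(sweep_radii) < 1L || any(sweep_radii <= 0)) {
    stop("sweep_radii must be positive", call. = FALSE)
  }
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, forward = forward,
                 preprocessing = preprocessing, training = training,
                 targets = targets,
                 n_components = as.integer(n_components),
                 radius_pct = radius_pct, sweep_radii = sweep_radii,
                 predict_calibration = isTRUE(predict_calibration),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes cohort generation, preprocessing, outlier-model fitting,
#' reference extraction, fold planning, ensemble training and evaluation in
#' order. Any stage failure aborts the run with the failing stage named;
#' artifacts of completed stages are retained when `out_dir` is set. Runs are
#' deterministic: the same configuration always yields the same result.
#'
#' Calibration models are trained on the individual in-vitro repeat spectra
#' of the calibration ponies; validation pools the held-out ponies of every
#' fold (each location predicted exactly once) on in-vitro data, and the test
#' set is the arthroscopic (in-vivo) spectra of the held-out ponies, with
#' per-location averaging restricted to non-outlier repeats.
#'
#' @param config A [pipeline_config()].
#' @param keep_models Keep the trained ensembles in the result (large).
#' @return An object of class `nirs_pipeline_result` with the cohort, the
#'   analysis set, the outlier report (including detector
#'   sensitivity/specificity against the known artifact flags), fold plans,
#'   location-level prediction `records`, per-repeat test predictions
#'   (`repeat_records`), the `metrics` table (target x set), group and paired
#'   test tables, the radius `sweep`, reference ranges and the run log.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_models = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  run_log <- character()
  note <- function(fmt, ...) {
    run_log <<- c(run_log, sprintf(fmt, ...))
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config_echo(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  persist <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    note("stage %-22s %7.1f s", name, (proc.time() - t0)[["elapsed"]])
    res
  }
  note("global seed %d | member seeds %s | R %s",
       config$cohort$seed, paste(config$training$seeds, collapse = "/"),
       as.character(getRversion()))

  cohort <- stage("generate", generate_cohort(config$cohort, config$forward))
  persist("spectra.csv", function(p) save_spectra(cohort, p))

  aset <- stage("preprocess", preprocess(cohort, config$preprocessing))
  persist("analysis.csv", function(p) save_analysis(aset, p))

  meta <- aset$meta
  vitro <- which(meta$modality == "in_vitro")
  vivo <- which(meta$modality == "in_vivo")

  od <- stage("outliers", {
    pca <- fit_pca(aset$values[vitro, , drop = FALSE], config$n_components)
    scores_vitro <- project_scores(pca, aset$values[vitro, , drop = FALSE])
    scores_vivo <- project_scores(pca, aset$values[vivo, , drop = FALSE])
    ell <- fit_mvee(scores_vitro)
    report <- radius_sweep(ell, scores_vivo, config$sweep_radii,
                           config$radius_pct)
    art <- meta$artifact[vivo]
    list(pca = pca, ellipsoid = ell, report = report,
         d2 = mvee_distance2(ell, scores_vivo),
         sensitivity = if (any(art)) mean(!report$inlier[art]) else NA_real_,
         specificity = if (any(!art)) mean(report$inlier[!art]) else NA_real_)
  })
  note("outliers at %g%%: %d flagged | sensitivity %.3f | specificity %.3f",
       config$radius_pct, sum(!od$report$inlier), od$sensitivity,
       od$specificity)
  persist("outlier_counts.csv", function(p)
    data.table::fwrite(od$report$counts, p))

  latent <- cohort$latent
  ref_ranges <- lapply(stats::setNames(config$targets, config$targets),
                       function(tg) range(latent[[tg]]))
  inlier_all <- rep(TRUE, nrow(meta))
  inlier_all[vivo] <- od$report$inlier
  d2_all <- rep(NA_real_, nrow(meta))
  d2_all[vivo] <- od$d2

  # location-level aggregation of one fold's predictions on a row subset
  predict_set <- function(ens, rows, set, target, fold,
                          pred = stats::predict(ens,
                                                aset$values[rows, ,
                                                            drop = FALSE])) {
    groups <- split(seq_along(rows), meta$loc_id[rows])
    first <- vapply(groups, `[`, integer(1L), 1L)
    loc_ids <- names(groups)
    agg <- vapply(groups, function(i)
      aggregate_by_location(pred[i], inlier_all[rows][i]), numeric(1L))
    data.frame(target = target, set = set, fold = fold, loc_id = loc_ids,
               pony = meta$pony[rows][first],
               prediction = unname(agg),
               reference = stats::setNames(latent[[target]],
                                           latent$loc_id)[loc_ids],
               row.names = NULL)
  }

  records <- list()
  repeat_records <- list()
  plans <- list()
  models <- list()
  for (tg in config$targets) {
    ref_by_loc <- stats::setNames(latent[[tg]], latent$loc_id)
    pony_means <- tapply(latent[[tg]], latent$pony, mean)
    plan <- make_folds(stats::setNames(as.numeric(pony_means),
                                       names(pony_means)), tg)
    plans[[tg]] <- plan
    for (k in seq_along(plan$folds)) {
      fold <- plan$folds[[k]]
      cal_rows <- vitro[meta$pony[vitro] %in% fold$calibration]
      val_rows <- vitro[meta$pony[vitro] %in% fold$validation]
      test_rows <- vivo[meta$pony[vivo] %in% fold$validation]
      ens <- stage(sprintf("train %s fold %d", tg, k),
                   train_ensemble(aset$values[cal_rows, , drop = FALSE],
                                  ref_by_loc[meta$loc_id[cal_rows]],
                                  aset$values[val_rows, , drop = FALSE],
                                  ref_by_loc[meta$loc_id[val_rows]],
                                  config$training, fold = k, target = tg))
      if (keep_models) models[[tg]][[k]] <- ens
      pred_test <- stats::predict(ens, aset$values[test_rows, , drop = FALSE])
      sets <- list(predict_set(ens, val_rows, "validation", tg, k),
                   predict_set(ens, test_rows, "test", tg, k,
                               pred = pred_test))
      if (config$predict_calibration) {
        sets <- c(sets, list(predict_set(ens, cal_rows, "calibration",
                                         tg, k)))
      }
      records[[length(records) + 1L]] <- do.call(rbind, sets)
      repeat_records[[length(repeat_records) + 1L]] <- data.frame(
        target = tg, fold = k, loc_id = meta$loc_id[test_rows],
        prediction = pred_test,
        reference = unname(ref_by_loc[meta$loc_id[test_rows]]),
        d2 = d2_all[test_rows], row.names = NULL)
    }
  }
  records <- do.call(rbind, records)
  repeat_records <- do.call(rbind, repeat_records)
  persist("records.csv", function(p) data.table::fwrite(records, p))
  persist("repeat_records.csv", function(p)
    data.table::fwrite(repeat_records, p))

  metrics <- stage("evaluate", evaluate_sets(records, ref_ranges))
  persist("metrics.csv", function(p) data.table::fwrite(metrics, p))

  group_tests <- stage("group tests", do.call(rbind, lapply(
    config$targets, function(tg) {
      pm <- tapply(latent[[tg]], latent$pony, mean)
      grp <- latent$group[match(names(pm), latent$pony)]
      gt <- compare_groups(pm[grp == "experimental"], pm[grp == "control"])
      data.frame(target = tg, statistic = gt$statistic,
                 p_value = gt$p.value, method = gt$method)
    })))
  paired_tests <- stage("paired tests", do.call(rbind, lapply(
    config$targets, function(tg) {
      r <- records[records$target == tg & records$set == "test", ]
      ok <- is.finite(r$prediction)
      pt <- compare_paired(r$reference[ok], r$prediction[ok])
      data.frame(target = tg, statistic = pt$statistic,
                 p_value = pt$p.value, method = pt$method)
    })))
  persist("group_tests.csv", function(p) data.table::fwrite(group_tests, p))
  persist("paired_tests.csv", function(p) data.table::fwrite(paired_tests, p))

  sweep <- stage("sweep", sweep_performance(repeat_records, ref_ranges,
                                            config$sweep_radii))
  persist("sweep.csv", function(p) data.table::fwrite(sweep, p))
  persist("log.txt", function(p) writeLines(run_log, p))

  structure(list(config = config, cohort = cohort, analysis = aset,
                 outliers = od[c("report", "sensitivity", "specificity",
                                 "pca", "ellipsoid")],
                 fold_plans = plans, records = records,
                 repeat_records = repeat_records, metrics = metrics,
                 group_tests = group_tests, paired_tests = paired_tests,
                 sweep = sweep, ref_ranges = ref_ranges,
                 models = if (keep_models) models, log = run_log),
            class = "nirs_pipeline_result")
}

# configuration echo with plain types only (for the JSON artifact)
config_echo <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), config_echo)
  } else if (is.matrix(x)) {
    lapply(seq_len(nrow(x)), function(i) unname(x[i, ]))
  } else {
    x
  }
}

#' @export
print.nirs_pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$fold_plans), "target(s),",
      nrow(x$cohort$latent), "locations\n")
  cat(sprintf("Outliers at %g%%: %d | sensitivity %.3f | specificity %.3f\n",
              x$config$radius_pct, sum(!x$outliers$report$inlier),
              x$outliers$sensitivity, x$outliers$specificity))
  cat("\nMetrics (per target and evaluation set):\n")
  print(x$metrics, digits = 3)
  invisible(x)
}
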