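#' Save and load a cohort's spectra
#'
#' `save_spectra()` writes the per-spectrum metadata and both detector
#' intensity blocks to a single CSV (one row per spectrum, intensity columns
#' named `A_<wavelength>` / `B_<wavelength>`) plus a JSON sidecar
#' (`<path>.json`) holding the wavelength grids, the generating
#' configuration, the forward-model parameters and the per-location latent
#' table. `load_spectra()` reconstructs the `nirs_cohort`; the round trip is
#' lossless to well below 1e-12.
#'
#' @param cohort A `nirs_cohort`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `save_spectra()`: `path`, invisibly. `load_spectra()`: a
#'   `nirs_cohort`.
#' @export
save_spectra <- function(cohort, path) {
  stopifnot(inherits(cohort, "nirs_cohort"))
  dt <- data.table::as.data.table(
    cbind(cohort$meta, cohort$intensity$A, cohort$intensity$B))
  data.table::fwrite(dt, path)
  cfg <- cohort$config
  cfg$grids <- NULL
  sidecar <- list(grids = cohort$grids,
                  config = unclass(cfg),
                  params = unclass(cohort$params),
                  latent = cohort$latent)
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

meta_columns <- function() {
  c("pony", "group", "leg", "site", "location", "loc_id", "rep",
    "modality", "artifact")
}

#' @rdname save_spectra
#' @export
load_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar_path(path))) {
    stop("sidecar not found: ", sidecar_path(path), call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 2L) stop("parse error: file has no data rows", call. = FALSE)
  bad <- which(nf != nf[1L])
  if (length(bad) > 0L) {
    stop(sprintf("parse error: row %d has %d fields, expected %d",
                 bad[1L], nf[bad[1L]], nf[1L]), call. = FALSE)
  }
  dt <- data.table::fread(path, data.table = FALSE)
  missing_meta <- setdiff(meta_columns(), names(dt))
  if (length(missing_meta) > 0L) {
    stop("parse error: missing metadata columns: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  side <- jsonlite::fromJSON(sidecar_path(path))
  grids <- lapply(side$grids, as.numeric)
  a_cols <- grep("^A_", names(dt))
  b_cols <- grep("^B_", names(dt))
  if (length(a_cols) != length(grids$A) || length(b_cols) != length(grids$B)) {
    stop("parse error: intensity column count does not match the sidecar grids",
         call. = FALSE)
  }
  cfg_args <- side$config
  cfg_args$grids <- grids
  config <- do.call(cohort_config, cfg_args)
  params <- do.call(forward_params, side$params)
  intensity <- list(A = as.matrix(dt[, a_cols, drop = FALSE]),
                    B = as.matrix(dt[, b_cols, drop = FALSE]))
  colnames(intensity$A) <- sprintf("A_%.6f", grids$A)
  colnames(intensity$B) <- sprintf("B_%.6f", grids$B)
  meta <- dt[, meta_columns(), drop = FALSE]
  structure(list(meta = meta, intensity = intensity,
                 latent = as.data.frame(side$latent),
                 grids = grids, config = config, params = params),
            class = "nirs_cohort")
}

#' Save an analysis set (preprocessed spectra)
#'
#' One row per spectrum: the metadata columns followed by the derivative
#' values, with columns named `<segment>_<wavelength>`.
#'
#' @param aset An `analysis_set`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
save_analysis <- function(aset, path) {
  stopifnot(inherits(aset, "analysis_set"))
  vals <- as.data.frame(aset$values)
  dt <- if (is.null(aset$meta)) vals else cbind(aset$meta, vals)
  data.table::fwrite(data.table::as.data.table(dt), path)
  invisible(path)
}
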