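#' Default dual-detector wavelength grids
#'
#' The acquisition system combines two spectrometers: detector A covering the
#' visible / short NIR range (0.35--1.1 um at 0.6 nm resolution) and detector B
#' covering the NIR range (1.0--2.5 um at 6.4 nm resolution). Wavelengths are
#' expressed in micrometres throughout the package.
#'
#' @param from_a,to_a,by_a Detector A span and spacing (um).
#' @param from_b,to_b,by_b Detector B span and spacing (um).
#' @return A named list with numeric wavelength vectors `A` and `B`, each
#'   strictly increasing with uniform spacing.
#' @export
#' @examples
#' g <- default_grids()
#' length(g$A)  # 1251 samples on detector A
default_grids <- function(from_a = 0.35, to_a = 1.1, by_a = 0.0006,
                          from_b = 1.0, to_b = 2.5, by_b = 0.0064) {
  list(A = seq(from_a, to_a, by = by_a),
       B = seq(from_b, to_b, by = by_b))
}

grid_spacing <- function(wavelengths) {
  d <- diff(wavelengths)
  if (length(d) < 1L || any(d <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (max(d) - min(d) > 1e-9) {
    stop("wavelength grid must have uniform spacing", call. = FALSE)
  }
  mean(d)
}
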