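#' Configuration of a synthetic study cohort
#'
#' Defines the size and structure of a virtual cohort emulating the equine
#' study design: experimental animals carrying surgically created chondral
#' lesions plus healthy controls, measured on both hind legs along three
#' anatomical lines (proximal, central, distal) at four locations of
#' increasing distance from the lesion. Each location is measured three times
#' in vitro under controlled probe contact and fifteen times in vivo during
#' arthroscopy, where a small fraction of spectra suffer from poor probe
#' contact (artifacts).
#'
#' @param n_experimental Number of experimental ponies (default 7).
#' @param n_control Number of healthy control ponies (default 3).
#' @param legs Leg labels (default left/right).
#' @param sites Anatomical measurement lines (default proximal/central/distal).
#' @param n_locations Locations per line, numbered 1 (closest to the lesion)
#'   to `n_locations` (farthest; default 4).
#' @param in_vitro_repeats In-vitro repeats per location (default 3).
#' @param in_vivo_repeats In-vivo repeats per location (default 15).
#' @param contamination_rate Probability that an in-vivo repeat is an artifact
#'   spectrum (default 0.031, the in-vivo outlier rate reported for
#'   arthroscopic acquisition).
#' @param noise_sd Additive Gaussian intensity noise (default 0.005, about
#'   0.5% of the reflectance baseline, plausible for 10-scan averages).
#' @param degeneration_max Degeneration factor at location 1 of experimental
#'   ponies; decays linearly to 0 at location `n_locations` (default 0.7).
#' @param seed RNG seed; identical config + seed gives a bit-identical cohort.
#' @param grids Detector wavelength grids, see [default_grids()].
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_experimental = 7L, n_control = 3L,
                          legs = c("left", "right"),
                          sites = c("proximal", "central", "distal"),
                          n_locations = 4L,
                          in_vitro_repeats = 3L, in_vivo_repeats = 15L,
                          contamination_rate = 0.031,
                          noise_sd = 0.005,
                          degeneration_max = 0.7,
                          seed = 42L,
                          grids = default_grids()) {
  counts <- c(n_experimental = n_experimental, n_control = n_control,
              n_locations = n_locations,
              in_vitro_repeats = in_vitro_repeats,
              in_vivo_repeats = in_vivo_repeats)
  if (any(counts < 1L) || any(counts != round(counts))) {
    stop("all cohort counts must be positive integers", call. = FALSE)
  }
  if (contamination_rate < 0 || contamination_rate > 1) {
    stop("contamination_rate must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_experimental = as.integer(n_experimental),
                 n_control = as.integer(n_control),
                 legs = legs, sites = sites,
                 n_locations = as.integer(n_locations),
                 in_vitro_repeats = as.integer(in_vitro_repeats),
                 in_vivo_repeats = as.integer(in_vivo_repeats),
                 contamination_rate = contamination_rate,
                 noise_sd = noise_sd,
                 degeneration_max = degeneration_max,
                 seed = as.integer(seed),
                 grids = grids),
            class = "cohort_config")
}

#' Parameters of the spectral forward model
#'
#' The forward model is a deliberately simple stand-in for tissue optics: a
#' power-law scattering baseline minus a sum of Gaussian absorption bands
#' whose depths are affine in the tissue targets (full-thickness PG,
#' superficial PG, normalized mean collagen angle, thickness). Band centers
#' mimic the water/CH overtone regions near 0.97, 1.21, 1.45 and 1.73 um so
#' that the cropped 0.8--1.9 um analysis region stays informative. Artifact
#' spectra additionally receive a visible-region light-source leak, a
#' multiplicative contact-loss factor and a baseline tilt.
#'
#' @param band_centers,band_widths Gaussian band centers and widths (um).
#' @param band_base Baseline band depth at zero target values.
#' @param band_links Bands x 4 matrix of affine coefficients linking band
#'   depth to `(pg_full, pg_sup, angle_full / 90, thickness)`.
#' @param scatter_amplitude,scatter_exponent Power-law baseline
#'   `amplitude * lambda^-exponent`.
#' @param leak_center,leak_width,leak_amplitude Visible-region light-source
#'   leak (center must lie within 0.40--0.75 um).
#' @param contact_loss_range Range of the multiplicative contact-loss factor
#'   applied to artifact spectra.
#' @param tilt_range Range of the additive baseline tilt slope (per um).
#' @return A validated list of class `forward_params`.
#' @export
forward_params <- function(band_centers = c(0.97, 1.21, 1.45, 1.73),
                           band_widths = c(0.05, 0.06, 0.09, 0.08),
                           band_base = c(0.030, 0.020, 0.060, 0.025),
                           band_links = rbind(
                             c(0.012, 0.000, 0.000, 0.120),
                             c(0.132, 0.060, 0.000, 0.000),
                             c(0.000, 0.000, 0.072, 0.108),
                             c(0.060, 0.108, 0.048, 0.000)),
                           scatter_amplitude = 1.2,
                           scatter_exponent = 1.3,
                           leak_center = 0.55,
                           leak_width = 0.05,
                           leak_amplitude = 12,
                           contact_loss_range = c(0.25, 0.70),
                           tilt_range = c(-0.3, 0.3)) {
  nb <- length(band_centers)
  stopifnot(length(band_widths) == nb, length(band_base) == nb,
            nrow(band_links) == nb, ncol(band_links) == 4L)
  if (leak_center < 0.40 || leak_center > 0.75) {
    stop("leak_center must lie within 0.40-0.75 um (visible light source)",
         call. = FALSE)
  }
  structure(list(band_centers = band_centers, band_widths = band_widths,
                 band_base = band_base, band_links = band_links,
                 scatter_amplitude = scatter_amplitude,
                 scatter_exponent = scatter_exponent,
                 leak_center = leak_center, leak_width = leak_width,
                 leak_amplitude = leak_amplitude,
                 contact_loss_range = contact_loss_range,
                 tilt_range = tilt_range),
            class = "forward_params")
}

# truncated-normal draws by inversion: one uniform per draw, so the RNG
# stream length does not depend on the values drawn
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Map latent cartilage state to reference depth profiles
#'
#' The latent state of a measurement location is summarized by four numbers:
#' `thickness` (mm), `pg_amplitude` (overall PG optical-density scale),
#' `degeneration` (0--1; 0 in controls) and `angle_steepness` (sharpness of
#' the depth-wise collagen reorientation; an optional `angle_mid` gives the
#' transition midpoint as a depth fraction). The PG profile is a monotone
#' increasing baseline curve `pg_amplitude * (0.35 + 0.65 d^1.4)` with a
#' superficial depletion factor `1 - 0.9 * degeneration * exp(-d / 0.25)`.
#' The orientation angle rises from 2 deg at the surface to a deep-zone value
#' `88 - 7.5 * degeneration` deg through a normalized logistic sigmoid.
#'
#' @param latent A list or one-row data.frame with fields `thickness`,
#'   `pg_amplitude`, `degeneration`, `angle_steepness` and optionally
#'   `angle_mid` (default 0.4).
#' @return A list with `depth_profile` elements `pg` and `angle`.
#' @export
latent_to_profiles <- function(latent) {
  latent <- as.list(latent)
  deg <- latent$degeneration
  if (is.null(latent$angle_mid)) latent$angle_mid <- 0.4
  stopifnot(deg >= 0, deg <= 1, latent$thickness > 0, latent$pg_amplitude >= 0)
  d <- seq(0, 1, length.out = N_PROFILE_POINTS)
  pg <- latent$pg_amplitude * (0.35 + 0.65 * d^1.4) *
    (1 - 0.9 * deg * exp(-d / 0.25))
  s <- latent$angle_steepness
  m <- latent$angle_mid
  sig <- stats::plogis(s * (d - m))
  signorm <- (sig - sig[1L]) / (sig[N_PROFILE_POINTS] - sig[1L])
  a_deep <- 88 - 7.5 * deg
  angle <- 2 + (a_deep - 2) * signorm
  list(pg = depth_profile(pg, "od"), angle = depth_profile(angle, "angle"))
}

# band depths for a matrix of reference targets (rows = locations);
# returns locations x bands matrix
band_depths <- function(refs, params) {
  x <- cbind(refs$pg_full, refs$pg_sup, refs$angle_full / 90, refs$thickness)
  sweep(x %*% t(params$band_links), 2L, params$band_base, `+`)
}

# noiseless intensity matrix on one wavelength grid: wavelengths x locations
clean_intensity <- function(wavelengths, depths, params) {
  baseline <- params$scatter_amplitude * wavelengths^(-params$scatter_exponent)
  g <- vapply(seq_along(params$band_centers), function(j) {
    exp(-(wavelengths - params$band_centers[j])^2 /
          (2 * params$band_widths[j]^2))
  }, numeric(length(wavelengths)))
  baseline - g %*% t(depths)
}

#' Simulate one diffuse-reflectance spectrum from reference targets
#'
#' Evaluates the forward model (scattering baseline minus affine-linked
#' Gaussian absorption bands) on both detector grids and adds Gaussian noise
#' drawn from the current R random number stream.
#'
#' @param refs A list or one-row data.frame with the five reference targets
#'   (see [target_names()]).
#' @param params A [forward_params()] object.
#' @param grids Detector grids, see [default_grids()].
#' @param noise_sd Additive noise standard deviation (>= 0).
#' @return A list of class `raw_spectrum` with numeric intensity vectors `A`
#'   and `B` and the grids as attribute.
#' @export
forward_spectrum <- function(refs, params = forward_params(),
                             grids = default_grids(), noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  refs <- as.data.frame(as.list(refs))
  depths <- band_depths(refs, params)
  out <- lapply(grids, function(wl) {
    v <- drop(clean_intensity(wl, depths, params))
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    v
  })
  structure(out, grids = grids, class = "raw_spectrum")
}

#' Inject an acquisition artifact into a spectrum
#'
#' Emulates poor probe-tissue contact during arthroscopy: the collected
#' signal drops by a multiplicative contact-loss factor, stray light from the
#' arthroscope adds a Gaussian leak in the visible region (0.40--0.75 um),
#' and the baseline acquires a linear tilt. The contact-loss factor, leak
#' scale and tilt slope are drawn from the current R random number stream.
#'
#' @param spectrum A `raw_spectrum` (list with elements `A` and `B`).
#' @param params A [forward_params()] object.
#' @param grids Detector grids matching the spectrum.
#' @return The modified `raw_spectrum`.
#' @export
inject_artifact <- function(spectrum, params = forward_params(),
                            grids = default_grids()) {
  m <- stats::runif(1L, params$contact_loss_range[1L],
                    params$contact_loss_range[2L])
  leak_scale <- stats::runif(1L, 0.7, 1.3)
  tilt <- stats::runif(1L, params$tilt_range[1L], params$tilt_range[2L])
  mid <- mean(range(unlist(grids)))
  leak <- params$leak_amplitude * leak_scale *
    exp(-(grids$A - params$leak_center)^2 / (2 * params$leak_width^2))
  out <- spectrum
  out$A <- m * spectrum$A + leak + tilt * (grids$A - mid)
  out$B <- m * spectrum$B + tilt * (grids$B - mid)
  out
}

#' Generate a synthetic study cohort
#'
#' Draws latent cartilage properties for every measurement location
#' (pony x leg x site x location), converts them to reference depth profiles
#' and targets, and forward-models the configured numbers of in-vitro and
#' in-vivo repeat spectra on both detector grids. In experimental ponies a
#' degeneration factor decays linearly with distance from the lesion
#' (location 1 closest), depleting superficial PG and lowering the deep-zone
#' collagen angle; control ponies have zero degeneration. A configurable
#' fraction of in-vivo repeats is replaced by artifact spectra
#' ([inject_artifact()]); the true artifact flags are stored so that outlier
#' detector performance can be measured.
#'
#' @param config A [cohort_config()].
#' @param params A [forward_params()].
#' @return A list of class `nirs_cohort` with elements `meta` (one row per
#'   spectrum: pony, group, leg, site, location, rep, modality, artifact,
#'   loc_id), `intensity` (matrices `A`, `B`; rows match `meta`), `latent`
#'   (one row per location: latent state plus the five reference targets),
#'   `grids`, `config`, `params`.
#' @export
#' @examples
#' cfg <- cohort_config(n_experimental = 2, n_control = 1,
#'                      in_vivo_repeats = 2, seed = 1)
#' coh <- generate_cohort(cfg)
#' table(coh$meta$modality)
generate_cohort <- function(config = cohort_config(),
                            params = forward_params()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  ponies <- c(sprintf("E%02d", seq_len(config$n_experimental)),
              sprintf("C%02d", seq_len(config$n_control)))
  groups <- rep(c("experimental", "control"),
                c(config$n_experimental, config$n_control))

  loc <- expand.grid(location = seq_len(config$n_locations),
                     site = config$sites, leg = config$legs,
                     pony = ponies, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  loc <- loc[, c("pony", "leg", "site", "location")]
  loc$group <- groups[match(loc$pony, ponies)]
  loc$loc_id <- paste(loc$pony, loc$leg, loc$site, loc$location, sep = "|")
  n_loc <- nrow(loc)

  # latent state: pony-level random effects plus location-level variation
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  pony_eff <- function(sd) stats::rnorm(length(ponies), 0, sd)[
    match(loc$pony, ponies)]
  loc$thickness <- clamp(0.82 + pony_eff(0.15) + stats::rnorm(n_loc, 0, 0.18),
                         0.14, 1.36)
  loc$pg_amplitude <- clamp(1.05 + pony_eff(0.35) +
                              stats::rnorm(n_loc, 0, 0.18), 0.06, 2.2)
  loc$angle_steepness <- clamp(9 + pony_eff(0.8) + stats::rnorm(n_loc, 0, 1.0),
                               5, 14)
  loc$angle_mid <- clamp(0.40 + pony_eff(0.06) + stats::rnorm(n_loc, 0, 0.09),
                         0.12, 0.80)
  grad <- (config$n_locations - loc$location) /
    max(1L, config$n_locations - 1L)
  deg_noise <- stats::rnorm(n_loc, 0, 0.08)
  loc$degeneration <- ifelse(loc$group == "experimental",
                             clamp(config$degeneration_max * grad + deg_noise,
                                   0, 1), 0)

  # reference profiles and targets (deterministic given the latent state)
  refs <- do.call(rbind, lapply(seq_len(n_loc), function(i) {
    p <- latent_to_profiles(loc[i, ])
    extract_references(p$pg, p$angle, loc$thickness[i])
  }))
  latent <- cbind(loc[, c("loc_id", "pony", "group", "leg", "site", "location",
                          "pg_amplitude", "degeneration", "angle_steepness",
                          "angle_mid")],
                  refs)

  # spectra: noiseless location spectra, then per-repeat noise realizations
  depths <- band_depths(refs, params)
  clean <- lapply(config$grids, clean_intensity, depths = depths,
                  params = params)

  build_rows <- function(n_rep, modality) {
    idx <- rep(seq_len(n_loc), each = n_rep)
    meta <- loc[idx, c("pony", "group", "leg", "site", "location", "loc_id")]
    meta$rep <- rep(seq_len(n_rep), times = n_loc)
    meta$modality <- modality
    rownames(meta) <- NULL
    intensity <- lapply(clean, function(cl) {
      m <- t(cl)[idx, , drop = FALSE]
      m + matrix(stats::rnorm(length(m), 0, config$noise_sd),
                 nrow = nrow(m))
    })
    list(meta = meta, intensity = intensity)
  }

  vitro <- build_rows(config$in_vitro_repeats, "in_vitro")
  vivo <- build_rows(config$in_vivo_repeats, "in_vivo")
  vitro$meta$artifact <- FALSE
  vivo$meta$artifact <- stats::runif(nrow(vivo$meta)) <
    config$contamination_rate
  for (i in which(vivo$meta$artifact)) {
    s <- inject_artifact(list(A = vivo$intensity$A[i, ],
                              B = vivo$intensity$B[i, ]),
                         params, config$grids)
    vivo$intensity$A[i, ] <- s$A
    vivo$intensity$B[i, ] <- s$B
  }

  meta <- rbind(vitro$meta, vivo$meta)
  intensity <- list(A = rbind(vitro$intensity$A, vivo$intensity$A),
                    B = rbind(vitro$intensity$B, vivo$intensity$B))
  colnames(intensity$A) <- sprintf("A_%.6f", config$grids$A)
  colnames(intensity$B) <- sprintf("B_%.6f", config$grids$B)
  rownames(meta) <- NULL

  structure(list(meta = meta, intensity = intensity, latent = latent,
                 grids = config$grids, config = config, params = params),
            class = "nirs_cohort")
}
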