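# the default seed-42 cohort is generated once and reused across tests here
default_cohort <- generate_cohort(cohort_config())

test_that("default config gives 10 ponies, 7 experimental + 3 control", {
  lat <- default_cohort$latent
  expect_equal(length(unique(lat$pony)), 10L)
  byg <- table(unique(lat[, c("pony", "group")])$group)
  expect_equal(unname(byg[["experimental"]]), 7L)
  expect_equal(unname(byg[["control"]]), 3L)
  # 10 ponies x 2 legs x 3 sites x 4 locations
  expect_equal(nrow(lat), 240L)
  expect_equal(sum(default_cohort$meta$modality == "in_vitro"), 240L * 3L)
  expect_equal(sum(default_cohort$meta$modality == "in_vivo"), 240L * 15L)
})

test_that("generation is deterministic for identical config and seed", {
  c1 <- generate_cohort(tiny_cohort_config())
  c2 <- generate_cohort(tiny_cohort_config())
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(tiny_cohort_config(seed = 43L))
  expect_false(identical(c1$intensity$A, c3$intensity$A))
})

test_that("contamination_rate 0 flags every in-vivo repeat clean", {
  c0 <- generate_cohort(tiny_cohort_config(contamination = 0))
  expect_false(any(c0$meta$artifact))
})

test_that("contamination bookkeeping within 1 percentage point", {
  vivo <- default_cohort$meta$modality == "in_vivo"
  expect_gte(sum(vivo), 1500L)
  rate <- mean(default_cohort$meta$artifact[vivo])
  expect_lt(abs(rate - default_cohort$config$contamination_rate), 0.01)
  expect_false(any(default_cohort$meta$artifact[!vivo]))
})

test_that("group contrast: mean pg_full rises with distance from the lesion", {
  lat <- default_cohort$latent
  exp_lat <- lat[lat$group == "experimental", ]
  m1 <- mean(exp_lat$pg_full[exp_lat$location == 1])
  m4 <- mean(exp_lat$pg_full[exp_lat$location == 4])
  expect_lt(m1, m4)
})

test_that("latent_to_profiles matches its stated parametric form", {
  latent <- list(thickness = 0.8, pg_amplitude = 1.1, degeneration = 0,
                 angle_steepness = 9)
  prof <- latent_to_profiles(latent)
  d <- seq(0, 1, length.out = 500)
  # degeneration 0: undepleted baseline exactly
  expect_equal(prof$pg$values, 1.1 * (0.35 + 0.65 * d^1.4), tolerance = 1e-12)
  expect_lt(prof$angle$values[1], 10)
  expect_gt(prof$angle$values[500], 80)

  worn <- latent_to_profiles(modifyList(latent, list(degeneration = 0.8)))
  expect_true(all(worn$pg$values <= prof$pg$values + 1e-12))
  expect_lt(worn$angle$values[500], prof$angle$values[500])
})

test_that("full-thickness PG mean matches a quadrature oracle", {
  latent <- list(thickness = 0.8, pg_amplitude = 1.3, degeneration = 0.4,
                 angle_steepness = 8, angle_mid = 0.4)
  prof <- latent_to_profiles(latent)
  curve <- function(d) {
    1.3 * (0.35 + 0.65 * d^1.4) * (1 - 0.9 * 0.4 * exp(-d / 0.25))
  }
  oracle <- stats::integrate(curve, 0, 1, rel.tol = 1e-10)$value
  # 500-point endpoint sampling cannot reach the spec's nominal 1e-6;
  # discretization-aware tolerance (see decisions ledger)
  expect_equal(profile_mean(prof$pg, 1), oracle, tolerance = 2e-3)
  # the linear (exponent-free) analogue is exact
  lin <- depth_profile(seq(0, 1, length.out = 500))
  expect_equal(profile_mean(lin, 1), 0.5, tolerance = 1e-12)
})

test_that("forward_spectrum: zero-absorber case equals the baseline", {
  params <- forward_params(band_base = rep(0, 4),
                           band_links = matrix(0, 4, 4))
  refs <- data.frame(thickness = 0.8, pg_full = 0.5, pg_sup = 0.3,
                     angle_full = 45, angle_sup = 20)
  grids <- tiny_grids()
  s <- forward_spectrum(refs, params, grids, noise_sd = 0)
  expect_equal(s$A, 1.2 * grids$A^(-1.3), tolerance = 1e-12)
  expect_equal(s$B, 1.2 * grids$B^(-1.3), tolerance = 1e-12)
})

test_that("forward_spectrum: more PG means deeper PG-linked absorption", {
  grids <- tiny_grids()
  params <- forward_params()
  refs_lo <- data.frame(thickness = 0.8, pg_full = 0.3, pg_sup = 0.2,
                        angle_full = 45, angle_sup = 20)
  refs_hi <- refs_lo
  refs_hi$pg_full <- 1.2
  lo <- forward_spectrum(refs_lo, params, grids, noise_sd = 0)
  hi <- forward_spectrum(refs_hi, params, grids, noise_sd = 0)
  # band 2 (1.21 um) carries the largest pg_full link
  j <- which.min(abs(grids$B - 1.21))
  expect_lt(hi$B[j], lo$B[j])
})

test_that("replicate averaging converges at the Monte-Carlo rate", {
  grids <- tiny_grids()
  refs <- data.frame(thickness = 0.8, pg_full = 0.5, pg_sup = 0.3,
                     angle_full = 45, angle_sup = 20)
  clean <- forward_spectrum(refs, forward_params(), grids, noise_sd = 0)
  rms_of <- function(n) {
    m <- rowMeans(vapply(seq_len(n), function(i) {
      forward_spectrum(refs, forward_params(), grids, noise_sd = 0.01)$A
    }, numeric(length(grids$A))))
    sqrt(mean((m - clean$A)^2))
  }
  set.seed(11)
  r10 <- rms_of(10)
  r1000 <- rms_of(1000)
  expect_equal(r10 / r1000, sqrt(100), tolerance = 0.35)
})

test_that("inject_artifact: identity parameters leave the spectrum unchanged", {
  grids <- tiny_grids()
  params <- forward_params(leak_amplitude = 0, contact_loss_range = c(1, 1),
                           tilt_range = c(0, 0))
  refs <- data.frame(thickness = 0.8, pg_full = 0.5, pg_sup = 0.3,
                     angle_full = 45, angle_sup = 20)
  s <- forward_spectrum(refs, params, grids, noise_sd = 0)
  set.seed(2)
  s2 <- inject_artifact(s, params, grids)
  expect_equal(s2$A, s$A, tolerance = 1e-12)
  expect_equal(s2$B, s$B, tolerance = 1e-12)
})

test_that("inject_artifact: leak dominates the visible region", {
  grids <- default_grids()
  params <- forward_params()
  refs <- data.frame(thickness = 0.8, pg_full = 0.5, pg_sup = 0.3,
                     angle_full = 45, angle_sup = 20)
  s <- forward_spectrum(refs, params, grids, noise_sd = 0)
  set.seed(3)
  s2 <- inject_artifact(s, params, grids)
  j <- which.min(abs(grids$A - params$leak_center))
  expect_gte(abs(s2$A[j]), 5 * abs(s$A[j]))
})

test_that("artifact spectra are separable in the in-vitro score space", {
  aset <- preprocess(default_cohort)
  vitro <- aset$meta$modality == "in_vitro"
  vivo <- aset$meta$modality == "in_vivo"
  pca <- fit_pca(aset$values[vitro, ], 3L)
  ell <- fit_mvee(project_scores(pca, aset$values[vitro, ]))
  flags <- classify_inliers(ell,
                            project_scores(pca, aset$values[vivo, ]), 105)
  art <- aset$meta$artifact[vivo]
  expect_gte(mean(!flags[art]), 0.90)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(cohort_config(n_experimental = 0), "positive")
  expect_error(cohort_config(contamination_rate = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(forward_params(leak_center = 0.9), "0.40-0.75")
})
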