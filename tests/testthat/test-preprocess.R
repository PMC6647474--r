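test_that("savgol reproduces polynomials up to its degree", {
  x <- seq(0, 1, length.out = 101)
  y <- 2 - 3 * x + 0.5 * x^2 + 4 * x^3
  sm <- savgol(y, window = 7, degree = 3, deriv = 0)
  h <- 3
  expect_lt(max(abs(sm - y[(h + 1):(101 - h)])), 1e-9)
})

test_that("savgol first derivative of a line is the slope", {
  x <- seq(0, 2, length.out = 81)
  y <- 1.5 + 2.25 * x
  d <- savgol(y, window = 9, degree = 3, deriv = 1, spacing = x[2] - x[1])
  expect_equal(d, rep(2.25, 81 - 8), tolerance = 1e-9)
})

test_that("savgol matches a brute-force local least-squares oracle", {
  set.seed(21)
  y <- rnorm(60)
  out <- savgol(y, window = 7, degree = 3, deriv = 0)
  oracle <- vapply(4:57, function(i) {
    w <- y[(i - 3):(i + 3)]
    fit <- stats::lm(w ~ poly(-3:3, 3, raw = TRUE))
    unname(stats::predict(fit)[4])
  }, numeric(1))
  expect_equal(out, oracle, tolerance = 1e-10)

  d1 <- savgol(y, window = 7, degree = 3, deriv = 1, spacing = 0.5)
  oracle1 <- vapply(4:57, function(i) {
    w <- y[(i - 3):(i + 3)]
    unname(coef(stats::lm(w ~ poly(seq(-1.5, 1.5, by = 0.5), 3,
                                   raw = TRUE)))[2])
  }, numeric(1))
  expect_equal(d1, oracle1, tolerance = 1e-10)
})

test_that("savgol interior agrees with signal::sgolayfilt", {
  set.seed(22)
  y <- rnorm(80)
  ours <- savgol(y, window = 11, degree = 3, deriv = 0)
  ref <- signal::sgolayfilt(y, p = 3, n = 11)
  expect_equal(ours, ref[6:75], tolerance = 1e-9)
})

test_that("savgol rejects invalid windows and short series", {
  expect_error(savgol(rnorm(50), window = 8), "odd")
  expect_error(savgol(rnorm(50), window = 3, degree = 3), "odd|degree")
  expect_error(savgol(rnorm(5), window = 7), "shorter")
  expect_error(savgol(rnorm(50), window = 7, degree = 3, deriv = 4), "deriv")
})

test_that("analysis grid respects interior filtering, crop and boundary", {
  grids <- default_grids()
  aset <- preprocess(generate_cohort(
    cohort_config(n_experimental = 1L, n_control = 1L, legs = "left",
                  sites = "central", n_locations = 1L,
                  in_vivo_repeats = 1L, seed = 1L)))
  wl <- aset$wavelengths
  seg <- aset$segment
  expect_equal(length(wl), 455L)
  expect_equal(sum(seg == "A"), 334L)
  expect_equal(sum(seg == "B"), 121L)
  expect_true(all(wl[seg == "A"] >= 0.80 - 1e-9))
  expect_true(all(wl[seg == "A"] < 1.0))
  expect_true(all(wl[seg == "B"] >= 1.0))
  expect_true(all(wl[seg == "B"] <= 1.90 + 1e-9))
  # interior-only: segment B starts at its first full-window wavelength
  expect_equal(min(wl[seg == "B"]), grids$B[21], tolerance = 1e-12)
  expect_true(all(diff(wl[seg == "A"]) > 0) && all(diff(wl[seg == "B"]) > 0))
})

test_that("preprocessing a cohort equals preprocessing spectra one by one", {
  coh <- generate_cohort(tiny_cohort_config())
  cfg <- tiny_preprocess_config()
  aset <- preprocess(coh, cfg)
  i <- 7L
  single <- preprocess(list(A = coh$intensity$A[i, ],
                            B = coh$intensity$B[i, ]),
                       cfg, grids = coh$grids)
  expect_equal(drop(single$values), unname(aset$values[i, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(single$wavelengths, aset$wavelengths)
})

test_that("derivative output is invariant to constant offsets", {
  coh <- generate_cohort(tiny_cohort_config())
  cfg <- tiny_preprocess_config()
  s <- list(A = coh$intensity$A[1, ], B = coh$intensity$B[1, ])
  s_off <- list(A = s$A + 5, B = s$B + 5)
  expect_equal(preprocess(s, cfg, grids = coh$grids)$values,
               preprocess(s_off, cfg, grids = coh$grids)$values,
               tolerance = 1e-9)
})

test_that("average_repeats averages within location and modality", {
  coh <- generate_cohort(tiny_cohort_config())
  aset <- preprocess(coh, tiny_preprocess_config())
  avg <- average_repeats(aset)
  expect_equal(nrow(avg$values),
               length(unique(paste(aset$meta$loc_id, aset$meta$modality))))
  one <- aset$meta$loc_id == aset$meta$loc_id[1] &
    aset$meta$modality == "in_vitro"
  manual <- colMeans(aset$values[one, , drop = FALSE])
  row <- which(avg$meta$loc_id == aset$meta$loc_id[1] &
                 avg$meta$modality == "in_vitro")
  expect_equal(unname(avg$values[row, ]), unname(manual), tolerance = 1e-14)
})

test_that("average_repeats on a list demands a common grid", {
  coh <- generate_cohort(tiny_cohort_config())
  cfg <- tiny_preprocess_config()
  s1 <- preprocess(list(A = coh$intensity$A[1, ], B = coh$intensity$B[1, ]),
                   cfg, grids = coh$grids)
  s2 <- preprocess(list(A = coh$intensity$A[2, ], B = coh$intensity$B[2, ]),
                   cfg, grids = coh$grids)
  avg <- average_repeats(list(s1, s2))
  expect_equal(drop(avg$values), drop((s1$values + s2$values) / 2),
               tolerance = 1e-14)
  s3 <- s2
  s3$wavelengths <- s3$wavelengths + 0.01
  expect_error(average_repeats(list(s1, s3)), "different analysis grids")
})

test_that("preprocess_config validation", {
  expect_error(preprocess_config(window_a = 10L), "odd")
  expect_error(preprocess_config(derivative_order = 4L), "derivative_order")
  expect_error(preprocess_config(crop = c(2, 1)), "increasing")
  expect_error(preprocess(generate_cohort(tiny_cohort_config()),
                          preprocess_config(window_a = 2001L)),
               "shorter than its filter window")
})
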