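test_that("aggregate_by_location averages inlier repeats only", {
  expect_equal(aggregate_by_location(c(1, 2, 3)), 2)
  expect_equal(aggregate_by_location(c(1, 2, 9), c(TRUE, TRUE, FALSE)), 1.5)
  expect_warning(res <- aggregate_by_location(c(1, 2), c(FALSE, FALSE)),
                 "outliers")
  expect_true(is.na(res))
  expect_error(aggregate_by_location(numeric(0)), "at least one")
})

test_that("spearman_rho agrees exactly with a brute-force mid-rank oracle", {
  midranks <- function(v) {
    # independent mid-rank computation via pairwise comparisons
    vapply(seq_along(v), function(i) {
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2
    }, numeric(1))
  }
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  set.seed(61)
  for (i in 1:5) {
    x <- sample(1:8, 15, replace = TRUE)  # guarantees ties
    y <- rnorm(15)
    expect_equal(spearman_rho(x, y), pearson(midranks(x), midranks(y)),
                 tolerance = 1e-14)
  }
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(62)
  x <- rnorm(20)
  y <- rnorm(20)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r, tolerance = 1e-14)
  expect_equal(spearman_rho(x, y^3 + 5 * y), r, tolerance = 1e-14)
})

test_that("spearman_rho rejects degenerate input", {
  expect_error(spearman_rho(1:2, 2:1), "3 complete pairs")
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
})

test_that("rmse and nrmse definitions", {
  expect_equal(rmse_value(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_value(c(2, 4), c(1, 3)), 1)
  expect_equal(nrmse_pct(0.5, 0, 2), 25)
  expect_error(nrmse_pct(0.5, 2, 2), "degenerate")
})

test_that("printed report NRMSE cells reconstruct from RMSE and range", {
  # reference ranges: superficial PG 0.04-1.17 OD, full-thickness angle
  # 10.1-77.2 degrees; printed values carry one decimal
  expect_lt(abs(nrmse_pct(0.174, 0.04, 1.17) - 15.4), 0.05)
  expect_lt(abs(nrmse_pct(0.220, 0.04, 1.17) - 19.5), 0.05)
  expect_lt(abs(nrmse_pct(13.439, 10.1, 77.2) - 20.0), 0.05)
})

test_that("Mann-Whitney exact enumeration agrees with wilcox.test", {
  set.seed(63)
  for (i in 1:5) {
    x <- rnorm(5)
    y <- rnorm(4)
    ours <- compare_groups(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("Mann-Whitney edge cases and large-sample branch", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  big <- compare_groups(rnorm(15), rnorm(15))
  expect_match(big$method, "normal approximation")
  expect_true(big$p.value > 0 && big$p.value <= 1)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("paired Wilcoxon handles ties and degenerate input", {
  set.seed(64)
  m <- rnorm(12)
  p <- m + rnorm(12, sd = 0.3)
  ours <- compare_paired(m, p)
  ref <- stats::wilcox.test(p, m, paired = TRUE, exact = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  expect_warning(deg <- compare_paired(c(1, 2), c(1, 2)), "zero")
  expect_equal(deg$p.value, 1)
  expect_error(compare_paired(1:3, 1:2), "paired")
})

test_that("evaluate_sets computes per-target, per-set metrics and pools folds", {
  set.seed(65)
  ref <- runif(20, 1, 2)
  records <- rbind(
    data.frame(target = "thickness", set = "validation",
               fold = rep(1:2, each = 10), loc_id = sprintf("L%02d", 1:20),
               prediction = ref + rnorm(20, sd = 0.1), reference = ref),
    data.frame(target = "thickness", set = "test", fold = 1L,
               loc_id = sprintf("L%02d", 1:20),
               prediction = ref + rnorm(20, sd = 0.2), reference = ref))
  rr <- list(thickness = range(ref))
  m <- evaluate_sets(records, rr)
  expect_equal(nrow(m), 2L)
  v <- m[m$set == "validation", ]
  keep <- records$set == "validation"
  expect_equal(v$rmse, rmse_value(records$prediction[keep],
                                  records$reference[keep]))
  expect_equal(v$nrmse_pct, 100 * v$rmse / diff(range(ref)))
  expect_equal(v$n, 20L)

  dup <- records
  dup$loc_id[11:20] <- dup$loc_id[1:10]
  expect_error(evaluate_sets(dup, rr), "validation pooling error")
})

test_that("missing location predictions are excluded and counted", {
  records <- data.frame(target = "thickness", set = "test", fold = 1L,
                        loc_id = sprintf("L%d", 1:6),
                        prediction = c(1, 2, NA, 4, 5, 6),
                        reference = c(1.1, 2.2, 3, 4.1, 5.2, 5.9))
  m <- evaluate_sets(records, list(thickness = c(1, 6)))
  expect_equal(m$n, 5L)
  expect_equal(m$n_missing, 1L)
})

test_that("sweep_performance re-aggregates with nested outlier sets", {
  set.seed(66)
  locs <- sprintf("L%02d", 1:10)
  ref <- setNames(runif(10, 1, 2), locs)
  rp <- do.call(rbind, lapply(locs, function(l) {
    data.frame(target = "thickness", loc_id = l,
               prediction = ref[[l]] + rnorm(5, sd = 0.1),
               reference = ref[[l]],
               d2 = runif(5, 0, 2.5))
  }))
  sw <- sweep_performance(rp, list(thickness = range(ref)),
                          radii_pct = c(75, 100, 105, 125, 150))
  expect_equal(nrow(sw), 5L)
  expect_true(all(diff(sw$n_outliers) <= 0))
  # manual recomputation at 100%
  keep <- rp$d2 <= 1
  agg <- tapply(rp$prediction[keep], rp$loc_id[keep], mean)
  sc <- function(v) (v - min(ref)) / diff(range(ref))
  manual <- sqrt(mean((sc(agg) - sc(ref[names(agg)]))^2))
  expect_equal(sw$avg_scaled_rmse[sw$radius_pct == 100], unname(manual),
               tolerance = 1e-12)
})
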