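test_that("Grubbs critical values match published tables", {
  # published two-sided 5% critical values (3 dp)
  expect_equal(grubbs_critical(10, 0.05), 2.290, tolerance = 5e-4)
  expect_equal(grubbs_critical(20, 0.05), 2.708, tolerance = 5e-4)
  expect_equal(grubbs_critical(13, 0.05), 2.462, tolerance = 5e-4)
  expect_equal(grubbs_critical(10, 0.01), 2.482, tolerance = 5e-4)
})

test_that("Grubbs screen flags a single gross outlier and nothing else", {
  rep1 <- grubbs_one_outlier(c(rep(0, 9), 100))
  expect_true(rep1$removed)
  expect_equal(rep1$outlier_index, 10L)
  expect_gt(rep1$g_statistic, rep1$critical_value)

  rep2 <- grubbs_one_outlier(c(-1, 0, 1, 0))
  expect_false(rep2$removed)

  # zero spread: degenerate branch with a note
  rep3 <- grubbs_one_outlier(c(2, 2, 2))
  expect_false(rep3$removed)
  expect_match(rep3$note, "zero spread")

  expect_error(grubbs_one_outlier(c(1, 2)), "at least 3")
})

test_that("Grubbs decisions are location and scale invariant", {
  set.seed(31)
  for (i in 1:20) {
    r <- rnorm(12)
    if (i %% 3 == 0) r[1] <- r[1] + 8   # plant an outlier sometimes
    base <- grubbs_one_outlier(r)
    moved <- grubbs_one_outlier(3.7 * r - 52)
    expect_equal(moved$removed, base$removed)
    expect_equal(moved$outlier_index, base$outlier_index)
    expect_equal(moved$g_statistic, base$g_statistic, tolerance = 1e-10)
  }
})

test_that("outlier policy removes exactly the planted observation", {
  ds <- exact_mariotti_dataset(epsilon = -9, d15n_s0 = -41,
                               conversions = seq(0.2, 0.7, by = 0.05))
  df <- as.data.frame(ds)
  df$d15n_bulk[5] <- df$d15n_bulk[5] + 10   # 10-permil offset row
  spiked <- n2o_dataset(df[c("replicate_id", "time_min", "n2o_nmol",
                             "d15n_bulk", "d15n_alpha", "d18o")],
                        no_initial = attr(ds, "no_initial"))
  out <- apply_outlier_policy(spiked)
  expect_equal(nrow(out), nrow(spiked) - 1L)
  log <- attr(out, "exclusion_log")
  expect_equal(log$time_min, spiked$time_min[5])
  expect_match(log$reason, "Grubbs")

  # well-behaved scatter passes through unchanged (an exact line would
  # leave only numerical noise as residuals, which is not a fair screen)
  df2 <- as.data.frame(ds)
  df2$d15n_bulk <- df2$d15n_bulk + 0.3 * (-1)^seq_len(nrow(df2))
  wobbly <- n2o_dataset(df2[c("replicate_id", "time_min", "n2o_nmol",
                              "d15n_bulk", "d15n_alpha", "d18o")],
                        no_initial = attr(ds, "no_initial"))
  clean <- apply_outlier_policy(wobbly)
  expect_equal(nrow(clean), nrow(wobbly))
  expect_false(attr(clean, "outlier_report")$removed)

  # tied extremes: first index wins
  tied <- grubbs_one_outlier(c(5, rep(0, 8), 5, 0.0))
  expect_true(is.na(tied$outlier_index) || tied$outlier_index == 1L)
})

test_that("bootstrap is reproducible and consistent with point estimates", {
  sim <- generate_study_like(seed = 8)
  ds <- sim$observations
  b1 <- bootstrap_models(ds, n_boot = 60, seed = 123)
  b2 <- bootstrap_models(ds, n_boot = 60, seed = 123)
  expect_identical(b1, b2)
  b3 <- bootstrap_models(ds, n_boot = 60, seed = 124)
  expect_false(identical(b1$mean, b3$mean))

  # on noise-free data the resampling spread collapses well below the
  # measurement noise, and the mean tracks the point estimate
  sim0 <- generate_study_like(seed = 1, noise_sd = 0)
  b0 <- bootstrap_models(sim0$observations, n_boot = 200, seed = 7)
  expect_equal(b0$n_failed, 0)
  expect_lt(b0$sd[["eps_bulk"]], 0.5)
  bulk <- fit_rayleigh_linear(sim0$observations, "d15n_bulk")
  expect_equal(b0$mean[["kie_bulk"]], bulk_kie(bulk)$kie,
               tolerance = 2e-4)
})

test_that("bootstrap rejects tiny datasets", {
  small <- delta_dataset(c(-44, -43, -42), c(-43, -42, -41))
  expect_error(bootstrap_models(small, n_boot = 10, seed = 1),
               "at least 5")
})
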