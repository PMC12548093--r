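test_that("predict_bulk_delta is self-consistent at the symmetric point", {
  # at delta = 0 everywhere, rho = 0.5 puts exactly the standard ratio
  # at the alpha site, so the prediction returns 0
  a <- atom_amounts(0, 0, 1000)
  expect_equal(predict_bulk_delta(0.5, a$n15_bulk, 1000, 0), 0,
               tolerance = 1e-9)

  # generic self-consistency: if rho carries the observed alpha share
  # and beta is the observed beta, the observed bulk is returned
  ds <- delta_dataset(c(-44, -43, -42), c(-42.5, -41.8, -41))
  a <- atom_amounts(ds$d15n_bulk, ds$d15n_alpha, ds$n2o_nmol)
  rho_obs <- a$n15_alpha / a$n15_bulk
  pred <- predict_bulk_delta(rho_obs, a$n15_bulk, ds$n2o_nmol,
                             ds$d15n_beta)
  expect_equal(pred, ds$d15n_bulk, tolerance = 1e-9)

  # pole: rho * n15_bulk reaching the N2O amount is rejected, and the
  # prediction diverges as the denominator shrinks
  expect_error(predict_bulk_delta(0.9, 10, 5, 0), "smaller")
  shrinking <- predict_bulk_delta(c(0.5, 0.9, 0.99), 10, 10, 0)
  expect_true(all(diff(shrinking) > 0) && shrinking[3] > 1e5)
  expect_error(predict_bulk_delta(1.2, 1, 10, 0), "\\(0, 1\\)")
})

test_that("rho estimation matches tau when the sites are indistinguishable", {
  truth <- sim_truth(kie_n_alpha = 1 / epsilon_to_alpha(-8.6),
                     kie_n_beta = 1 / epsilon_to_alpha(-8.6),
                     noise_sd = c(d15n_bulk = 0, d15n_alpha = 0, d18o = 0),
                     seed = 2)
  sim <- simulate_closed_system(truth, n_steps = 4000)
  est <- estimate_rho_tau(sim$observations)
  expect_true(est$converged)
  expect_lt(abs(est$rho - est$tau), max(est$se_rho, 1e-6))
})

test_that("zero-noise rho reproduces the simulator's 15N-alpha share", {
  sim <- generate_study_like(seed = 1, noise_sd = 0)
  ds <- sim$observations
  est <- estimate_rho(ds)
  a <- atom_amounts(ds$d15n_bulk, ds$d15n_alpha, ds$n2o_nmol)
  true_share <- mean(a$n15_alpha / a$n15_bulk)
  expect_lt(abs(est$rho - true_share), 1e-6)
  expect_lt(est$nonlinear_rmse, 0.01)
})

test_that("rho is invariant to row order and joint amount rescaling", {
  sim <- generate_study_like(seed = 9)
  ds <- sim$observations
  est <- estimate_rho(ds)

  set.seed(2)
  perm <- sample(nrow(ds))
  shuffled <- ds
  shuffled[seq_len(nrow(ds)), ] <- as.data.frame(ds)[perm, ]
  expect_equal(estimate_rho(shuffled)$rho, est$rho, tolerance = 1e-9)

  scaled_df <- as.data.frame(ds)
  scaled_df$n2o_nmol <- scaled_df$n2o_nmol * 3
  scaled <- n2o_dataset(scaled_df[c("replicate_id", "time_min", "n2o_nmol",
                                    "d15n_bulk", "d15n_alpha", "d18o")],
                        no_initial = attr(ds, "no_initial") * 3)
  expect_equal(estimate_rho(scaled)$rho, est$rho, tolerance = 1e-8)
})

test_that("tau averaging has the expected magnitude and symmetry", {
  # identical alpha and bulk deltas: tau exactly 0.5
  sym <- delta_dataset(c(-44, -43, -42, -41), c(-44, -43, -42, -41))
  expect_equal(estimate_tau(sym)$tau, 0.5, tolerance = 1e-9)

  # natural-abundance inputs sit within 1e-4 of 0.5
  sim <- generate_study_like(seed = 4)
  est <- estimate_tau(sim$observations)
  expect_lt(abs(est$tau - 0.5), 1e-4)

  # a 5-permil alpha-over-beta asymmetry shifts tau down by the amount
  # an independent isotope-fraction calculation predicts
  bulk <- c(-44, -43, -42)
  asym <- delta_dataset(bulk, bulk + 2.5)
  tau_asym <- estimate_tau(asym)$tau
  oracle <- sapply(bulk, function(b) {
    ra <- (1 + (b + 2.5) / 1000) * R_STD_N
    rb <- (1 + (b - 2.5) / 1000) * R_STD_N
    xa <- ra / (1 + ra); xb <- rb / (1 + rb)
    (1 - xa) / ((1 - xa) + (1 - xb))
  })
  expect_equal(tau_asym, mean(oracle), tolerance = 1e-10)
  expect_lt(tau_asym, 0.5)
  expect_equal(tau_asym - 0.5, -4.58e-6, tolerance = 0.02)
})

test_that("position-specific conversion honours the weighted-mean identity", {
  sim <- generate_study_like(seed = 6)
  ds <- sim$observations
  bulk <- fit_rayleigh_linear(ds, "d15n_bulk")
  rt <- estimate_rho_tau(ds)
  ps <- position_specific(rt, bulk)
  expect_equal(rt$tau * ps$n_alpha$alpha + (1 - rt$tau) * ps$n_beta$alpha,
               ps$bulk$alpha, tolerance = 1e-12)

  # rho = tau collapses both sites onto the bulk factor
  fake <- list(rho = 0.5, se_rho = 0.01, tau = 0.5, se_tau = 0.001)
  ps_eq <- position_specific(fake, bulk)
  expect_equal(ps_eq$n_alpha$alpha, ps_eq$bulk$alpha, tolerance = 1e-12)
  expect_equal(ps_eq$n_beta$alpha, ps_eq$bulk$alpha, tolerance = 1e-12)

  expect_error(position_specific(list(rho = 1.2, se_rho = 0, tau = 0.5,
                                      se_tau = 0), bulk), "\\(0, 1\\)")
})

test_that("p-values against the 0.5 nulls behave sensibly", {
  # strongly asymmetric zero-noise data: rho decisively different from 0.5
  sim <- generate_study_like(seed = 1, noise_sd = 0)
  est <- estimate_rho_tau(sim$observations)
  expect_lt(est$p_rho, 1e-4)
  expect_lt(est$p_tau, 1e-4)
  expect_gt(est$rho, 0.5)  # central N less depleted than terminal N
  expect_lt(est$tau, 0.5)
})
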