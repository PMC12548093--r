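test_that("cumulative N2O adds previously removed aliquots", {
  expect_equal(cumulative_n2o(c(100, 150), removed = c(10)), c(100, 160))
  expect_equal(cumulative_n2o(c(50, 80, 120)), c(50, 80, 120))
  # brute-force prefix sum for a generic case
  in_bottle <- c(110, 170, 240)
  removed <- c(25, 40)
  expect_equal(cumulative_n2o(in_bottle, removed),
               c(110, 170 + 25, 240 + 25 + 40))
  expect_error(cumulative_n2o(c(-1, 2)), "non-negative")
})

test_that("fraction remaining follows the 2 NO : 1 N2O stoichiometry", {
  expect_equal(fraction_remaining(0, 10300), 1)
  expect_equal(fraction_remaining(10300 / 2, 10300), 0)
  # 3 umol N2O from 10.3 umol NO is ~58% conversion
  expect_equal(1 - fraction_remaining(3000, 10300), 0.58, tolerance = 0.005)
  # linear in the product amount
  n2o <- seq(0, 5000, by = 500)
  f <- fraction_remaining(n2o, 10300)
  expect_equal(diff(f), rep(diff(f)[1], length(f) - 1))
  expect_error(fraction_remaining(6000, 10300), "stoichiometry")
})

test_that("Rayleigh abscissa has the right limits and is monotone", {
  expect_equal(rayleigh_abscissa(0.5), log(2))
  expect_equal(rayleigh_abscissa(1), 1)   # L'Hopital limit
  expect_equal(rayleigh_abscissa(0), 0)
  expect_equal(rayleigh_abscissa(1 - 1e-9), 1, tolerance = 1e-6)
  grid <- seq(1e-6, 1 - 1e-6, length.out = 2000)
  x <- rayleigh_abscissa(grid)
  expect_true(all(diff(x) > 0))
  expect_true(all(x > 0 & x < 1))
  expect_error(rayleigh_abscissa(1.2), "\\[0, 1\\]")
  expect_error(rayleigh_abscissa(-0.1), "\\[0, 1\\]")
})

test_that("dataset construction derives beta, SP, f and abscissa", {
  ds <- delta_dataset(d15n_bulk = c(-44, -43, -42),
                      d15n_alpha = c(-43, -42.5, -41))
  expect_s3_class(ds, "n2o_dataset")
  expect_equal(ds$d15n_beta, 2 * ds$d15n_bulk - ds$d15n_alpha)
  expect_equal(ds$sp, ds$d15n_alpha - ds$d15n_beta)
  expect_equal(ds$abscissa, rayleigh_abscissa(ds$f))
  expect_equal(abs(ds$d15n_bulk - (ds$d15n_alpha + ds$d15n_beta) / 2),
               rep(0, 3), tolerance = 1e-9)

  expect_error(
    n2o_dataset(data.frame(replicate_id = "A", time_min = 1,
                           n2o_nmol = 10), no_initial = 100),
    "missing required columns")
  dup <- data.frame(replicate_id = "A", time_min = c(10, 10),
                    n2o_nmol = c(100, 120), d15n_bulk = 0,
                    d15n_alpha = 0, d18o = 0)
  expect_error(n2o_dataset(dup, no_initial = 10300), "duplicated")
})

test_that("observation filters implement the conversion and plateau rules", {
  base <- data.frame(
    replicate_id = "R1",
    time_min = c(40, 80, 120, 160, 200),
    n2o_nmol = c(300, 1200, 2400, 2410, 2412),
    d15n_bulk = -44 + (0:4) / 2, d15n_alpha = -43 + (0:4) / 2,
    d18o = 10 + 0:4)
  ds <- n2o_dataset(base, no_initial = 10300)

  filtered <- filter_observations(ds)
  log <- attr(filtered, "exclusion_log")
  # 300 nmol is (1-f) = 0.058 < 0.1; rows 4 and 5 sit on the plateau
  expect_equal(filtered$time_min, c(80, 120))
  expect_setequal(log$time_min, c(40, 160, 200))
  expect_match(log$reason[log$time_min == 40], "conversion")
  expect_match(log$reason[log$time_min == 160], "plateau")

  # a zero increment counts as plateau even at tolerance 0
  flat <- n2o_dataset(data.frame(
    replicate_id = "A", time_min = 1:4 * 10,
    n2o_nmol = c(1100, 2200, 2200, 2201),
    d15n_bulk = 0, d15n_alpha = 0, d18o = 0), no_initial = 10300)
  f0 <- filter_observations(flat, plateau_fraction = 0)
  expect_equal(f0$n2o_nmol, c(1100, 2200))

  # untouched datasets pass through with an empty log
  clean <- filter_observations(delta_dataset(c(-44, -43, -42),
                                             c(-43, -42, -41)))
  expect_equal(nrow(attr(clean, "exclusion_log")), 0)

  expect_error(filter_observations(ds, min_conversion = 0.9),
               "no observations remain")
})

test_that("filtering is idempotent", {
  sim <- generate_study_like(seed = 11)
  once <- filter_observations(sim$observations)
  twice <- filter_observations(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))

  set.seed(5)
  ds <- n2o_dataset(data.frame(
    replicate_id = rep(c("A", "B"), each = 4),
    time_min = rep(1:4 * 40, 2),
    n2o_nmol = c(500, 1800, 2600, 2620, 700, 1500, 2500, 3300),
    d15n_bulk = rnorm(8, -43), d15n_alpha = rnorm(8, -42),
    d18o = rnorm(8, 12)), no_initial = 10300)
  once <- filter_observations(ds)
  expect_equal(as.data.frame(filter_observations(once)),
               as.data.frame(once))
})
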