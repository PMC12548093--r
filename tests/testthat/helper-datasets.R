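# Shared fixtures, built in code.

# Dataset whose bulk deltas follow the Mariotti line exactly:
# delta = d15n_s0 + epsilon * (-f ln f / (1 - f)), with a constant
# alpha-beta split so every channel is well defined.
exact_mariotti_dataset <- function(epsilon = -10, d15n_s0 = -40,
                                   sp_offset = 3,
                                   conversions = seq(0.2, 0.7, by = 0.05),
                                   no_initial = 10300) {
  n2o <- conversions * no_initial / 2
  f <- 1 - conversions
  x <- rayleigh_abscissa(f)
  bulk <- d15n_s0 + epsilon * x
  n2o_dataset(data.frame(
    replicate_id = "R1",
    time_min = seq_along(n2o) * 40,
    n2o_nmol = n2o,
    d15n_bulk = bulk,
    d15n_alpha = bulk + sp_offset / 2,
    d18o = 10 + 2 * x
  ), no_initial = no_initial)
}

# Dataset with prescribed per-row deltas on a fixed conversion grid.
delta_dataset <- function(d15n_bulk, d15n_alpha,
                          d18o = rep(0, length(d15n_bulk)),
                          no_initial = 10300) {
  n <- length(d15n_bulk)
  conversions <- seq(0.2, 0.7, length.out = n)
  n2o_dataset(data.frame(
    replicate_id = "R1",
    time_min = seq_len(n) * 40,
    n2o_nmol = conversions * no_initial / 2,
    d15n_bulk = d15n_bulk,
    d15n_alpha = d15n_alpha,
    d18o = d18o
  ), no_initial = no_initial)
}

R_STD_N <- 0.0036765
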