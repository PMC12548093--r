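#' Ground truth for the closed-system fractionation simulator
#'
#' Bundles the parameters driving [simulate_closed_system()]: the
#' finite NO pool, its initial isotopic composition, constant per-site
#' KIEs for the two nitrogen positions, the KIE of the oxygen atom
#' retained in N2O and the enrichment factor of the oxygen atom lost
#' to water, the IRMS measurement noise, and the sampling design.
#'
#' Noise is injected only on the channels the instrument actually
#' measures (bulk 15N via m/z 45:44, the alpha position via the NO+
#' fragment 31:30, and 18O), with the per-channel standard
#' reproducibilities of 0.5, 0.7 and 0.5 permil; the beta-site delta
#' is derived as `2*bulk - alpha` and therefore inherits correlated
#' noise, just as it does for real measurements.
#'
#' @param no_initial initial NO, nmol.
#' @param d15n_s0 initial substrate delta15N, permil vs air-N2.
#' @param kie_n_alpha,kie_n_beta true per-site nitrogen KIEs.
#' @param d18o_s0 initial substrate delta18O, permil vs VSMOW.
#' @param kie_o_incorporated KIE of the O atom retained in N2O.
#' @param o_branch_epsilon enrichment factor (permil) of the O atom
#'   lost to water.
#' @param noise_sd named numeric: per-channel Gaussian SDs in permil
#'   for `d15n_bulk`, `d15n_alpha`, `d18o`.
#' @param sample_fractions conversion grid, as target `(1 - f)`
#'   values: either one strictly increasing vector shared by all
#'   replicates or a list with one vector per replicate.
#' @param replicates number of replicate bottles.
#' @param seed integer seed for the measurement noise.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(no_initial = 10300,
                      d15n_s0 = -40.5,
                      kie_n_alpha = 1 / epsilon_to_alpha(-7.2),
                      kie_n_beta = 1 / epsilon_to_alpha(-9.9),
                      d18o_s0 = 0,
                      kie_o_incorporated = 1 / epsilon_to_alpha(-25),
                      o_branch_epsilon = -14.8,
                      noise_sd = c(d15n_bulk = 0.5, d15n_alpha = 0.7,
                                   d18o = 0.5),
                      sample_fractions = seq(0.2, 0.74, length.out = 5),
                      replicates = 3,
                      seed = 1L) {
  stopifnot(no_initial > 0, kie_n_alpha > 0, kie_n_beta > 0,
            kie_o_incorporated > 0, replicates >= 1)
  if (!is.list(sample_fractions)) {
    sample_fractions <- rep(list(sample_fractions), replicates)
  }
  if (length(sample_fractions) != replicates) {
    stop("'sample_fractions' must have one grid per replicate",
         call. = FALSE)
  }
  for (g in sample_fractions) {
    if (any(g <= 0) || any(g >= 1) || is.unsorted(g, strictly = TRUE)) {
      stop("sample fractions must be strictly increasing within (0, 1)",
           call. = FALSE)
    }
  }
  nm <- c("d15n_bulk", "d15n_alpha", "d18o")
  if (!all(nm %in% names(noise_sd)) || any(noise_sd[nm] < 0)) {
    stop("'noise_sd' needs non-negative entries named ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  structure(list(no_initial = no_initial, d15n_s0 = d15n_s0,
                 kie_n_alpha = kie_n_alpha, kie_n_beta = kie_n_beta,
                 d18o_s0 = d18o_s0,
                 kie_o_incorporated = kie_o_incorporated,
                 o_branch_epsilon = o_branch_epsilon,
                 noise_sd = noise_sd[nm],
                 sample_fractions = sample_fractions,
                 replicates = replicates, seed = seed),
            class = "sim_truth")
}

# Deterministic closed-system trajectory: equal N2O increments, exact
# atom bookkeeping. Instantaneous product ratio at each N site is
# R_substrate / KIE_site (constant-KIE first-order kinetics); one O
# atom is retained (R_substrate,O / KIE_O) and one lost to water
# (offset by the branch enrichment factor).
sim_trajectory <- function(truth, n_steps = 10000, conv_max = 0.9999) {
  rn <- std_air_n2()$r_standard
  ro <- std_vsmow_o()$r_standard
  rs_n0 <- ratio_from_delta(truth$d15n_s0, rn)
  rs_o0 <- ratio_from_delta(truth$d18o_s0, ro)
  no <- truth$no_initial
  h_n <- no * rs_n0 / (1 + rs_n0); l_n <- no - h_n
  h_o <- no * rs_o0 / (1 + rs_o0); l_o <- no - h_o
  total_n15 <- h_n; total_o18 <- h_o

  inv_ka <- 1 / truth$kie_n_alpha
  inv_kb <- 1 / truth$kie_n_beta
  inv_ko <- 1 / truth$kie_o_incorporated
  alpha_w <- epsilon_to_alpha(truth$o_branch_epsilon)

  d_n2o <- (no / 2) * conv_max / n_steps
  ha <- la <- hb <- lb <- hop <- lop <- hw <- lw <- 0
  out <- matrix(NA_real_, n_steps, 9)
  colnames(out) <- c("n2o_cum", "f", "d15n_substrate", "d18o_substrate",
                     "d15n_bulk", "d15n_alpha", "d15n_beta", "d18o",
                     "conservation_err")
  for (i in seq_len(n_steps)) {
    r_n <- h_n / l_n
    r_o <- h_o / l_o
    ra <- r_n * inv_ka; rb <- r_n * inv_kb
    rop <- r_o * inv_ko; rw <- r_o * alpha_w
    xa <- ra / (1 + ra); xb <- rb / (1 + rb)
    xo <- rop / (1 + rop); xw <- rw / (1 + rw)
    ha <- ha + d_n2o * xa; la <- la + d_n2o * (1 - xa)
    hb <- hb + d_n2o * xb; lb <- lb + d_n2o * (1 - xb)
    hop <- hop + d_n2o * xo; lop <- lop + d_n2o * (1 - xo)
    hw <- hw + d_n2o * xw; lw <- lw + d_n2o * (1 - xw)
    h_n <- h_n - d_n2o * (xa + xb); l_n <- l_n - d_n2o * (2 - xa - xb)
    h_o <- h_o - d_n2o * (xo + xw); l_o <- l_o - d_n2o * (2 - xo - xw)
    cons <- max(abs(h_n + ha + hb - total_n15),
                abs(h_o + hop + hw - total_o18))
    out[i, ] <- c(i * d_n2o, 1 - 2 * i * d_n2o / no,
                  delta_from_ratio(h_n / l_n, rn),
                  delta_from_ratio(h_o / l_o, ro),
                  delta_from_ratio((ha + hb) / (la + lb), rn),
                  delta_from_ratio(ha / la, rn),
                  delta_from_ratio(hb / lb, rn),
                  delta_from_ratio(hop / lop, ro),
                  cons)
  }
  as.data.frame(out)
}

#' Simulate closed-system position-specific N2O fractionation
#'
#' Forward model of the study design the analysis assumes: a finite,
#' well-mixed NO pool consumed 2:1 into N2O in equal increments, with
#' constant per-site nitrogen KIEs, a branched oxygen atom (one
#' retained in N2O, one lost to water), exact isotope-atom
#' bookkeeping, and Gaussian IRMS noise on the measured channels.
#' Cumulative product deltas are read off at each replicate's target
#' conversion grid; the beta-site delta is derived from the noisy bulk
#' and alpha values, as in real data reduction.
#'
#' @param truth a [sim_truth].
#' @param n_steps number of equal N2O increments (>= 1000).
#' @param rate_nmol_min nominal N2O production rate used to assign
#'   sampling times (nmol/min).
#' @return List of class `sim_output` with elements `observations`
#'   (an [n2o_dataset] in the same schema as read input data), `truth`
#'   and `trajectory` (the per-step substrate and accumulated-product
#'   deltas, for oracle checks; includes the running atom-conservation
#'   error).
#' @examples
#' out <- simulate_closed_system(sim_truth(seed = 7), n_steps = 2000)
#' head(out$observations)
#' @export
simulate_closed_system <- function(truth, n_steps = 10000,
                                   rate_nmol_min = 24) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_steps < 1000) stop("'n_steps' must be >= 1000", call. = FALSE)
  conv_all <- unlist(truth$sample_fractions)
  if (max(conv_all) >= 0.9999) {
    stop("sample fractions beyond the simulated range", call. = FALSE)
  }
  traj <- sim_trajectory(truth, n_steps = n_steps)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(truth$seed)

  obs <- do.call(rbind, lapply(seq_len(truth$replicates), function(r) {
    grid <- truth$sample_fractions[[r]]
    idx <- vapply(grid, function(cv) {
      which.min(abs((1 - traj$f) - cv))
    }, integer(1))
    n <- length(idx)
    sd <- truth$noise_sd
    bulk <- traj$d15n_bulk[idx] + stats::rnorm(n, 0, sd[["d15n_bulk"]])
    alph <- traj$d15n_alpha[idx] + stats::rnorm(n, 0, sd[["d15n_alpha"]])
    d18o <- traj$d18o[idx] + stats::rnorm(n, 0, sd[["d18o"]])
    data.frame(replicate_id = sprintf("R%d", r),
               time_min = traj$n2o_cum[idx] / rate_nmol_min,
               n2o_nmol = traj$n2o_cum[idx],
               d15n_bulk = bulk, d15n_alpha = alph, d18o = d18o)
  }))
  dataset <- n2o_dataset(obs, no_initial = truth$no_initial)
  structure(list(observations = dataset, truth = truth,
                 trajectory = traj),
            class = "sim_output")
}

#' Study-like synthetic dataset preset
#'
#' Convenience preset reproducing the experimental design of the cNOR
#' study: 10.3 umol of NO, three replicate bottles sampled on
#' staggered conversion grids spanning (1 - f) of about 0.20-0.74 (13
#' retained observations in total), substrate delta15N of -40.5
#' permil, per-site enrichment factors of -7.2 (central N) and -9.9
#' permil (terminal N), and the standard IRMS reproducibilities.
#'
#' @param seed integer seed for the measurement noise.
#' @param noise_sd optional override of the per-channel noise SDs
#'   (set all to 0 for noise-free recovery checks).
#' @param n_steps increments passed to [simulate_closed_system()].
#' @return A `sim_output` whose `observations` hold 13 rows.
#' @examples
#' sim <- generate_study_like(seed = 1)
#' nrow(sim$observations)   # 13
#' @export
generate_study_like <- function(seed = 1L, noise_sd = NULL,
                                n_steps = 10000) {
  grids <- list(c(0.20, 0.35, 0.50, 0.65),
                c(0.25, 0.40, 0.55, 0.70),
                c(0.22, 0.38, 0.52, 0.66, 0.74))
  args <- list(sample_fractions = grids, replicates = 3, seed = seed)
  if (!is.null(noise_sd)) {
    if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
      noise_sd <- c(d15n_bulk = noise_sd, d15n_alpha = noise_sd,
                    d18o = noise_sd)
    }
    args$noise_sd <- noise_sd
  }
  simulate_closed_system(do.call(sim_truth, args), n_steps = n_steps)
}
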