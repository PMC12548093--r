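#' Isotope-ratio standards
#'
#' Reference heavy/light abundance ratios against which delta values are
#' expressed. Bulk and position-specific nitrogen deltas are reported
#' against atmospheric N2; oxygen deltas against Vienna Standard Mean
#' Ocean Water (VSMOW). The absolute ratio only matters where atom
#' amounts are reconstructed from deltas (the Expanded Rayleigh fit);
#' sensitivity to the constant is weak, and both defaults can be
#' overridden.
#'
#' @param name label for the standard.
#' @param r_standard heavy/light abundance ratio, in (0, 1).
#' @return An object of class `isotope_standard`.
#' @examples
#' std_air_n2()
#' isotope_standard("custom", 0.004)
#' @export
isotope_standard <- function(name, r_standard) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(r_standard) || length(r_standard) != 1L ||
      !is.finite(r_standard) || r_standard <= 0 || r_standard >= 1) {
    stop("'r_standard' must be a single ratio in (0, 1)", call. = FALSE)
  }
  structure(list(name = name, r_standard = r_standard),
            class = "isotope_standard")
}

#' @rdname isotope_standard
#' @export
std_air_n2 <- function() isotope_standard("air-N2 15N/14N", 0.0036765)

#' @rdname isotope_standard
#' @export
std_vsmow_o <- function() isotope_standard("VSMOW 18O/16O", 0.0020052)

#' @export
print.isotope_standard <- function(x, ...) {
  cat(sprintf("<isotope_standard> %s  R = %.7f\n", x$name, x$r_standard))
  invisible(x)
}

r_std <- function(standard) {
  if (inherits(standard, "isotope_standard")) return(standard$r_standard)
  if (is.numeric(standard) && length(standard) == 1L && standard > 0 &&
      standard < 1) return(standard)
  stop("'standard' must be an isotope_standard or a ratio in (0, 1)",
       call. = FALSE)
}

#' Convert between delta notation and isotope abundance ratios
#'
#' `ratio_from_delta()` maps a per-mil delta value to the sample
#' heavy/light ratio, `R = (delta/1000 + 1) * R_standard`;
#' `delta_from_ratio()` is its exact inverse. Deltas at or below
#' -1000 permil (ratios at or below zero) are non-physical and raise
#' an error.
#'
#' @param delta delta value(s) in permil relative to `standard`.
#' @param ratio heavy/light abundance ratio(s), strictly positive.
#' @param standard an [isotope_standard] (or a bare ratio).
#' @return Numeric vector: abundance ratio(s) or delta value(s).
#' @examples
#' ratio_from_delta(0, std_air_n2())         # the standard itself
#' delta_from_ratio(2 * 0.0036765, std_air_n2())  # 1000 permil
#' @export
ratio_from_delta <- function(delta, standard = std_air_n2()) {
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    stop("delta values must be finite and > -1000 permil", call. = FALSE)
  }
  (delta / 1000 + 1) * r_std(standard)
}

#' @rdname ratio_from_delta
#' @export
delta_from_ratio <- function(ratio, standard = std_air_n2()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("ratios must be finite and strictly positive", call. = FALSE)
  }
  (ratio / r_std(standard) - 1) * 1000
}

#' Convert between enrichment factor, fractionation factor and KIE
#'
#' The enrichment factor epsilon (permil) and fractionation factor
#' alpha are related by `epsilon = (alpha - 1) * 1000`; the kinetic
#' isotope effect is `KIE = 1/alpha`, so a normal isotope effect
#' (light isotope reacts faster, epsilon < 0) gives KIE > 1.
#'
#' @param epsilon enrichment factor(s), permil; must exceed -1000.
#' @param alpha fractionation factor(s), strictly positive.
#' @param kie kinetic isotope effect(s), strictly positive.
#' @return Numeric vector.
#' @examples
#' alpha_to_kie(epsilon_to_alpha(-9.9))   # 1.0100 at 4 dp
#' @export
epsilon_to_alpha <- function(epsilon) {
  if (any(!is.finite(epsilon)) || any(epsilon <= -1000)) {
    stop("epsilon must be finite and > -1000 permil", call. = FALSE)
  }
  1 + epsilon / 1000
}

#' @rdname epsilon_to_alpha
#' @export
alpha_to_epsilon <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("alpha must be finite and strictly positive", call. = FALSE)
  }
  (alpha - 1) * 1000
}

#' @rdname epsilon_to_alpha
#' @export
alpha_to_kie <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("alpha must be finite and strictly positive", call. = FALSE)
  }
  1 / alpha
}

#' @rdname epsilon_to_alpha
#' @export
kie_to_alpha <- function(kie) {
  if (any(!is.finite(kie)) || any(kie <= 0)) {
    stop("KIE must be finite and strictly positive", call. = FALSE)
  }
  1 / kie
}

#' Site arithmetic for N2O nitrogen deltas
#'
#' Bulk delta15N of N2O is the mean of the central (alpha) and terminal
#' (beta) nitrogen deltas, so the beta delta follows from measured bulk
#' and alpha values as `2 * bulk - alpha`. Site preference (SP) is the
#' alpha minus beta difference, the near-conservative signature used to
#' distinguish N2O sources.
#'
#' @param d15n_bulk,d15n_alpha,d15n_beta delta15N values in permil.
#' @return Numeric vector of derived delta values (permil).
#' @examples
#' beta_from_bulk_alpha(-43, -44)   # -42
#' site_preference(10.19, -11.65)   # 21.84
#' @export
beta_from_bulk_alpha <- function(d15n_bulk, d15n_alpha) {
  2 * d15n_bulk - d15n_alpha
}

#' @rdname beta_from_bulk_alpha
#' @export
site_preference <- function(d15n_alpha, d15n_beta) {
  d15n_alpha - d15n_beta
}

#' Isotope-atom amounts in cumulative N2O product
#'
#' Reconstructs nmol amounts of 15N and 14N in the bulk product and in
#' its alpha position from measured deltas, using exact isotope
#' fractions `R/(1+R)` (not the rare-isotope approximation). Each N2O
#' molecule carries two N atoms in bulk and one at the alpha site, so
#' `n15_bulk + n14_bulk = 2 * n2o` and `n15_alpha + n14_alpha = n2o`.
#' These amounts feed the Expanded Rayleigh quantities
#' rho = 15N-alpha/15N-bulk and tau = 14N-alpha/14N-bulk.
#'
#' @param d15n_bulk,d15n_alpha measured deltas, permil vs air-N2.
#' @param n2o cumulative N2O amount(s), nmol, strictly positive.
#' @param standard the nitrogen [isotope_standard].
#' @return A data.frame with columns `n15_bulk`, `n14_bulk`,
#'   `n15_alpha`, `n14_alpha` (nmol).
#' @examples
#' atom_amounts(0, 0, 1000)
#' @export
atom_amounts <- function(d15n_bulk, d15n_alpha, n2o,
                         standard = std_air_n2()) {
  if (any(!is.finite(n2o)) || any(n2o <= 0)) {
    stop("'n2o' must be finite and strictly positive", call. = FALSE)
  }
  r_b <- ratio_from_delta(d15n_bulk, standard)
  r_a <- ratio_from_delta(d15n_alpha, standard)
  n15_bulk <- 2 * n2o * r_b / (1 + r_b)
  n15_alpha <- n2o * r_a / (1 + r_a)
  data.frame(
    n15_bulk = n15_bulk,
    n14_bulk = 2 * n2o - n15_bulk,
    n15_alpha = n15_alpha,
    n14_alpha = n2o - n15_alpha
  )
}
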