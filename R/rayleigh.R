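#' Rayleigh (Mariotti) linear regression of a delta channel
#'
#' Ordinary least-squares fit of the selected delta channel against the
#' Rayleigh abscissa `-f ln f / (1 - f)`. For bulk delta15N the slope
#' is the enrichment factor epsilon (permil) and the intercept is the
#' initial substrate delta15N. For delta18O the slope is reported as a
#' slope only: it folds in the fractionation of the second oxygen atom
#' lost to water and is not the true 18O enrichment factor.
#'
#' Conventions: `RMSE = sqrt(SSR/n)`; `R2 = 1 - SSR/SST` with SST about
#' the mean (defined as 0, with a flag, when SST is 0); the slope
#' p-value is the two-sided t-test of slope = 0 with n - 2 degrees of
#' freedom; coefficient standard errors are classical OLS.
#'
#' @param dataset an [n2o_dataset], normally already passed through
#'   [filter_observations()].
#' @param delta_field which channel to regress: one of `"d15n_bulk"`,
#'   `"d15n_alpha"`, `"d15n_beta"`, `"d18o"`, `"sp"`.
#' @return An object of class `rayleigh_fit`: list with `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `r2`, `rmse`, `p_slope`,
#'   `n`, `residuals`, `fitted`, `delta_field`, `degenerate_sst`.
#' @examples
#' sim <- generate_study_like(seed = 1)
#' fit <- fit_rayleigh_linear(sim$observations, "d15n_bulk")
#' fit$slope   # enrichment factor, permil
#' @export
fit_rayleigh_linear <- function(dataset, delta_field = "d15n_bulk") {
  stopifnot(inherits(dataset, "n2o_dataset"))
  delta_field <- match.arg(delta_field,
                           c("d15n_bulk", "d15n_alpha", "d15n_beta",
                             "d18o", "sp"))
  y <- dataset[[delta_field]]
  x <- dataset$abscissa
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations to fit", call. = FALSE)
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    stop("degenerate abscissa: all values (numerically) equal",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact synthetic data ("essentially perfect fit")
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  degenerate <- sst < .Machine$double.eps
  structure(list(
    slope = unname(cf["x", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    se_slope = unname(cf["x", "Std. Error"]),
    se_intercept = unname(cf["(Intercept)", "Std. Error"]),
    r2 = if (degenerate) 0 else 1 - ssr / sst,
    rmse = sqrt(ssr / n),
    p_slope = unname(cf["x", "Pr(>|t|)"]),
    n = n,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    delta_field = delta_field,
    degenerate_sst = degenerate
  ), class = "rayleigh_fit")
}

#' @export
print.rayleigh_fit <- function(x, ...) {
  lab <- if (identical(x$delta_field, "d18o")) "slope" else "epsilon"
  cat(sprintf(
    "<rayleigh_fit> %s: %s = %.2f +/- %.2f permil, intercept = %.2f +/- %.2f\n",
    x$delta_field, lab, x$slope, x$se_slope, x$intercept, x$se_intercept))
  cat(sprintf("  n = %d, R2 = %.3f, RMSE = %.3f, p(slope) = %.3g\n",
              x$n, x$r2, x$rmse, x$p_slope))
  invisible(x)
}

#' Bulk KIE from a Rayleigh regression
#'
#' Converts the slope of the bulk delta15N Rayleigh fit into the
#' fractionation factor `alpha = 1 + epsilon/1000` and kinetic isotope
#' effect `KIE = 1/alpha`, with first-order standard-error propagation
#' `SE(KIE) = SE(epsilon)/1000 / alpha^2`.
#'
#' @param fit a `rayleigh_fit` of a delta15N channel.
#' @return List with `epsilon`, `se_epsilon`, `alpha`, `kie`, `se_kie`.
#' @export
bulk_kie <- function(fit) {
  stopifnot(inherits(fit, "rayleigh_fit"))
  alpha <- epsilon_to_alpha(fit$slope)
  if (alpha <= 0) stop("fractionation factor <= 0", call. = FALSE)
  list(epsilon = fit$slope, se_epsilon = fit$se_slope, alpha = alpha,
       kie = alpha_to_kie(alpha),
       se_kie = fit$se_slope / 1000 / alpha^2)
}

#' Site-preference trend over reaction progress
#'
#' Regresses site preference against the Rayleigh abscissa with the
#' same OLS machinery as [fit_rayleigh_linear()] and summarises the SP
#' distribution (mean and SD, the convention used for the pooled
#' values).
#'
#' @param dataset an [n2o_dataset].
#' @return A `rayleigh_fit` with extra elements `sp_mean` and `sp_sd`.
#' @export
sp_trend <- function(dataset) {
  fit <- fit_rayleigh_linear(dataset, "sp")
  fit$sp_mean <- mean(dataset$sp)
  fit$sp_sd <- stats::sd(dataset$sp)
  fit
}
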