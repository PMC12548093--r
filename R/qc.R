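#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test on a numeric vector (here: regression
#' residuals). The statistic is `G = max |r_i - mean(r)| / sd(r)` and
#' the critical value at level `alpha_level` is
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha_level/(2n), n - 2)`. At most one index is
#' flagged; ties on the extreme residual are broken by first index.
#' A zero-spread sample returns a no-outlier result with a note.
#'
#' @param residuals numeric vector, length >= 3.
#' @param alpha_level significance level (default 0.05).
#' @return An object of class `outlier_report`: list with
#'   `g_statistic`, `critical_value`, `alpha_level`, `outlier_index`
#'   (NA if none), `removed` (flag: statistic exceeded the critical
#'   value), `note`.
#' @examples
#' grubbs_one_outlier(c(rep(0, 9), 100))   # index 10 flagged
#' @export
grubbs_one_outlier <- function(residuals, alpha_level = 0.05) {
  n <- length(residuals)
  if (n < 3L) stop("Grubbs test needs at least 3 values", call. = FALSE)
  if (any(!is.finite(residuals))) {
    stop("residuals must be finite", call. = FALSE)
  }
  s <- stats::sd(residuals)
  crit <- grubbs_critical(n, alpha_level)
  if (s == 0) {
    return(structure(list(g_statistic = 0, critical_value = crit,
                          alpha_level = alpha_level,
                          outlier_index = NA_integer_, removed = FALSE,
                          note = "zero spread: no outlier detectable"),
                     class = "outlier_report"))
  }
  dev <- abs(residuals - mean(residuals))
  idx <- which.max(dev)           # first index on ties
  g <- dev[idx] / s
  structure(list(g_statistic = g, critical_value = crit,
                 alpha_level = alpha_level,
                 outlier_index = if (g > crit) idx else NA_integer_,
                 removed = g > crit, note = NULL),
            class = "outlier_report")
}

#' @rdname grubbs_one_outlier
#' @param n sample size.
#' @export
grubbs_critical <- function(n, alpha_level = 0.05) {
  stopifnot(n >= 3, alpha_level > 0, alpha_level < 1)
  tq <- stats::qt(1 - alpha_level / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> G = %.3f, critical = %.3f (alpha = %g)\n",
              x$g_statistic, x$critical_value, x$alpha_level))
  if (x$removed) cat(sprintf("  outlier at index %d\n", x$outlier_index))
  else cat("  no outlier\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Remove a Grubbs-flagged observation from a dataset
#'
#' Applies [grubbs_one_outlier()] to the residuals of the bulk
#' delta15N Rayleigh regression and, if an outlier is flagged, removes
#' that entire observation (all delta channels) and logs it. At most
#' one observation is removed per pooled dataset; re-fitting is the
#' caller's responsibility.
#'
#' @param dataset a filtered, pooled [n2o_dataset].
#' @param fit the bulk `rayleigh_fit` whose residuals are screened; if
#'   missing it is computed from `dataset`.
#' @param alpha_level Grubbs significance level.
#' @return The dataset (possibly one row shorter) with an updated
#'   `exclusion_log` and the `outlier_report` attached as attribute
#'   `outlier_report`.
#' @export
apply_outlier_policy <- function(dataset, fit = NULL, alpha_level = 0.05) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  if (is.null(fit)) fit <- fit_rayleigh_linear(dataset, "d15n_bulk")
  rep_out <- grubbs_one_outlier(fit$residuals, alpha_level)
  if (!rep_out$removed) {
    attr(dataset, "outlier_report") <- rep_out
    return(dataset)
  }
  i <- rep_out$outlier_index
  log_new <- data.frame(
    replicate_id = as.character(dataset$replicate_id[i]),
    time_min = dataset$time_min[i],
    reason = sprintf("Grubbs outlier (G = %.3f > %.3f)",
                     rep_out$g_statistic, rep_out$critical_value),
    stringsAsFactors = FALSE)
  kept <- as.data.frame(dataset)[-i, , drop = FALSE]
  rownames(kept) <- NULL
  out <- keep_dataset_attrs(kept, dataset,
                            exclusion_log = rbind(attr(dataset, "exclusion_log"),
                                                  log_new))
  attr(out, "outlier_report") <- rep_out
  out
}

#' Bootstrap uncertainty for the Rayleigh and Expanded Rayleigh models
#'
#' Resamples the pooled observations with replacement (same n), refits
#' the bulk linear Rayleigh model and the Expanded Rayleigh rho/tau
#' estimates on every resample, and averages KIEs, enrichment factors
#' and both RMSE statistics across successful resamples. Resamples on
#' which the nonlinear fit fails (including degenerate resamples whose
#' abscissa values coincide) are counted and excluded.
#'
#' Reproducibility: the whole resampling plan is drawn up-front from
#' `seed`, so a given (dataset, n_boot, seed) triple yields an
#' identical summary on every run.
#'
#' @param dataset a filtered, pooled [n2o_dataset] with >= 5 rows.
#' @param n_boot number of resamples (default 1000).
#' @param seed integer seed for the resampling plan.
#' @return An object of class `bootstrap_summary`: list with per-
#'   quantity `mean` and `sd` (KIE and epsilon for bulk/alpha/beta,
#'   linear and nonlinear RMSE), plus `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_models <- function(dataset, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  n <- nrow(dataset)
  if (n < 5L) stop("bootstrap needs at least 5 observations", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  plan <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)

  qty <- c("kie_bulk", "kie_n_alpha", "kie_n_beta",
           "eps_bulk", "eps_n_alpha", "eps_n_beta",
           "linear_rmse", "nonlinear_rmse")
  draws <- matrix(NA_real_, n_boot, length(qty),
                  dimnames = list(NULL, qty))
  base_df <- as.data.frame(dataset)
  for (b in seq_len(n_boot)) {
    rows <- base_df[plan[b, ], , drop = FALSE]
    rows$replicate_id <- paste0(rows$replicate_id, "#", seq_len(n))
    rownames(rows) <- NULL
    boot_ds <- keep_dataset_attrs(rows, dataset,
                                  exclusion_log = empty_exclusion_log())
    res <- tryCatch({
      if (diff(range(boot_ds$abscissa)) < .Machine$double.eps^0.5) {
        stop("degenerate resample")
      }
      bf <- fit_rayleigh_linear(boot_ds, "d15n_bulk")
      rt <- estimate_rho_tau(boot_ds)
      ps <- position_specific(rt, bf)
      c(kie_bulk = ps$bulk$kie, kie_n_alpha = ps$n_alpha$kie,
        kie_n_beta = ps$n_beta$kie,
        eps_bulk = ps$bulk$epsilon, eps_n_alpha = ps$n_alpha$epsilon,
        eps_n_beta = ps$n_beta$epsilon,
        linear_rmse = bf$rmse, nonlinear_rmse = rt$nonlinear_rmse)
    }, error = function(e) NULL)
    if (!is.null(res)) draws[b, ] <- res
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * n_boot) {
    warning(sprintf("%d of %d bootstrap fits failed", n_failed, n_boot))
  }
  structure(list(
    mean = colMeans(draws[ok, , drop = FALSE]),
    sd = apply(draws[ok, , drop = FALSE], 2, stats::sd),
    n_boot = n_boot, n_failed = n_failed, seed = seed
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %d resamples (%d failed), seed %s\n",
              x$n_boot, x$n_failed, format(x$seed)))
  tab <- data.frame(mean = x$mean, sd = x$sd)
  print(round(tab, 5))
  invisible(x)
}
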