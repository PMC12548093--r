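#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one validated object,
#' echoed into reports for provenance.
#'
#' @param no_initial_nmol initial NO amount, nmol.
#' @param r_standard_n,r_standard_o heavy/light ratios of the N and O
#'   reference standards.
#' @param n2o_is_cumulative whether the input `n2o_nmol` column is
#'   already cumulative (`TRUE`) or in-bottle amounts accompanied by a
#'   `n2o_nmol_removed` column (`FALSE`).
#' @param min_conversion,plateau_fraction observation filters, see
#'   [filter_observations()].
#' @param grubbs_alpha significance level of the outlier screen.
#' @param outlier_policy `"remove"` (drop a flagged observation and
#'   refit) or `"flag"` (report only).
#' @param n_boot bootstrap resamples (0 disables the bootstrap).
#' @param seed integer seed for the bootstrap resampling plan.
#' @return An object of class `n2o_config`.
#' @export
n2o_config <- function(no_initial_nmol = 10300,
                       r_standard_n = 0.0036765,
                       r_standard_o = 0.0020052,
                       n2o_is_cumulative = TRUE,
                       min_conversion = 0.1,
                       plateau_fraction = 0.01,
                       grubbs_alpha = 0.05,
                       outlier_policy = c("remove", "flag"),
                       n_boot = 1000,
                       seed = 1L) {
  outlier_policy <- match.arg(outlier_policy)
  stopifnot(no_initial_nmol > 0,
            r_standard_n > 0, r_standard_n < 1,
            r_standard_o > 0, r_standard_o < 1,
            min_conversion >= 0, min_conversion < 1,
            plateau_fraction >= 0, plateau_fraction < 1,
            grubbs_alpha > 0, grubbs_alpha < 1,
            n_boot >= 0)
  structure(list(no_initial_nmol = no_initial_nmol,
                 r_standard_n = r_standard_n,
                 r_standard_o = r_standard_o,
                 n2o_is_cumulative = isTRUE(n2o_is_cumulative),
                 min_conversion = min_conversion,
                 plateau_fraction = plateau_fraction,
                 grubbs_alpha = grubbs_alpha,
                 outlier_policy = outlier_policy,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "n2o_config")
}

#' Read a configuration file
#'
#' Accepts JSON (always) or YAML (when the yaml package is available);
#' keys are the arguments of [n2o_config()], unknown keys error.
#'
#' @param path path to the configuration file.
#' @return An `n2o_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(n2o_config)))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(n2o_config, vals)
}

#' Read an observation CSV into an n2o_dataset
#'
#' One row per sampling event with columns `replicate_id`, `time_min`,
#' `n2o_nmol` (cumulative, or in-bottle plus `n2o_nmol_removed` when
#' `config$n2o_is_cumulative` is `FALSE`), `d15n_bulk`, `d15n_alpha`,
#' `d18o` and optionally `d15n_beta`. Malformed rows are rejected with
#' their line numbers; a provided beta column is taken as-is, with a
#' warning when it is inconsistent with bulk and alpha beyond 0.05
#' permil.
#'
#' @param path CSV path.
#' @param config an [n2o_config].
#' @return An [n2o_dataset] (unfiltered).
#' @export
read_observations <- function(path, config = n2o_config()) {
  stopifnot(inherits(config, "n2o_config"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("replicate_id", "time_min", "n2o_nmol",
                "d15n_bulk", "d15n_alpha", "d18o")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("time_min", "n2o_nmol", "n2o_nmol_removed",
                          "d15n_bulk", "d15n_alpha", "d15n_beta", "d18o"),
                        names(raw))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data line(s) %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at data line(s) %s",
                   col, paste(which(is.na(v)), collapse = ", ")),
           call. = FALSE)
    }
    raw[[col]] <- v
  }
  if (!config$n2o_is_cumulative) {
    if (!"n2o_nmol_removed" %in% names(raw)) {
      stop("in-bottle amounts need a 'n2o_nmol_removed' column",
           call. = FALSE)
    }
    raw <- raw[order(raw$replicate_id, raw$time_min), ]
    raw$n2o_nmol <- stats::ave(
      seq_len(nrow(raw)), raw$replicate_id,
      FUN = function(i) cumulative_n2o(raw$n2o_nmol[i],
                                       raw$n2o_nmol_removed[i]))
    raw$n2o_nmol_removed <- NULL
  }
  n2o_dataset(raw, no_initial = config$no_initial_nmol,
              standard_n = isotope_standard("N standard",
                                            config$r_standard_n),
              standard_o = isotope_standard("O standard",
                                            config$r_standard_o))
}

#' Run the full closed-system KIE analysis
#'
#' Executes the complete workflow on an observation dataset: filter
#' (minimum conversion + plateau) -> pooled bulk delta15N Rayleigh fit
#' -> Grubbs outlier screen on its residuals (optionally removing one
#' flagged observation and refitting) -> Expanded Rayleigh rho/tau ->
#' position-specific enrichment factors and KIEs -> delta18O slope ->
#' site-preference trend -> bootstrap. The result mirrors the usual
#' results-table layout: one row per measurement with epsilon +/- SE,
#' KIE +/- SE, R2, linear and nonlinear RMSE and the p-values for the
#' bulk slope, rho and tau.
#'
#' @param dataset an [n2o_dataset] (as from [read_observations()] or
#'   the simulator), or a path to a CSV readable by
#'   [read_observations()].
#' @param config an [n2o_config].
#' @return An object of class `n2o_report`: list with elements
#'   `table` (the per-measurement summary data.frame), `fits` (bulk,
#'   d18o, sp fits; rho_tau; position_specific), `outlier`,
#'   `bootstrap` (NULL when `n_boot = 0`), `exclusion_log`, `config`,
#'   `n_used`.
#' @export
run_full_analysis <- function(dataset, config = n2o_config()) {
  stopifnot(inherits(config, "n2o_config"))
  if (is.character(dataset)) {
    dataset <- read_observations(dataset, config)
  }
  stopifnot(inherits(dataset, "n2o_dataset"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  filtered <- stage("filter",
                    filter_observations(dataset,
                                        min_conversion = config$min_conversion,
                                        plateau_fraction = config$plateau_fraction))
  bulk <- stage("bulk fit", fit_rayleigh_linear(filtered, "d15n_bulk"))
  screened <- stage("outlier screen", {
    ds <- apply_outlier_policy(filtered, bulk,
                               alpha_level = config$grubbs_alpha)
    if (config$outlier_policy == "flag") {
      # report the screen but keep every observation
      rep_out <- attr(ds, "outlier_report")
      ds <- filtered
      attr(ds, "outlier_report") <- rep_out
    }
    ds
  })
  if (nrow(screened) < nrow(filtered)) {
    bulk <- stage("bulk refit", fit_rayleigh_linear(screened, "d15n_bulk"))
  }
  rho_tau <- stage("expanded Rayleigh", estimate_rho_tau(screened))
  pos <- stage("position-specific", position_specific(rho_tau, bulk))
  d18o <- stage("d18o slope", fit_rayleigh_linear(screened, "d18o"))
  sp <- stage("site-preference trend", sp_trend(screened))
  boot <- if (config$n_boot > 0) {
    stage("bootstrap", bootstrap_models(screened, n_boot = config$n_boot,
                                        seed = config$seed))
  } else NULL

  tab <- data.frame(
    measurement = c("15N", "15N-alpha", "15N-beta", "18O-slope"),
    epsilon = c(pos$bulk$epsilon, pos$n_alpha$epsilon,
                pos$n_beta$epsilon, d18o$slope),
    se_epsilon = c(pos$bulk$se_epsilon, pos$n_alpha$se_epsilon,
                   pos$n_beta$se_epsilon, d18o$se_slope),
    kie = c(pos$bulk$kie, pos$n_alpha$kie, pos$n_beta$kie, NA),
    se_kie = c(pos$bulk$se_kie, pos$n_alpha$se_kie, pos$n_beta$se_kie,
               NA),
    r2 = c(bulk$r2, bulk$r2, bulk$r2, d18o$r2),
    linear_rmse = c(bulk$rmse, bulk$rmse, bulk$rmse, d18o$rmse),
    nonlinear_rmse = c(NA, rho_tau$nonlinear_rmse,
                       rho_tau$nonlinear_rmse, NA),
    p_epsilon = c(bulk$p_slope, bulk$p_slope, bulk$p_slope,
                  d18o$p_slope),
    p_rho = c(NA, rho_tau$p_rho, rho_tau$p_rho, NA),
    p_tau = c(NA, rho_tau$p_tau, rho_tau$p_tau, NA),
    stringsAsFactors = FALSE)

  structure(list(
    table = tab,
    fits = list(bulk = bulk, d18o = d18o, sp = sp, rho_tau = rho_tau,
                position_specific = pos),
    outlier = attr(screened, "outlier_report"),
    bootstrap = boot,
    exclusion_log = attr(screened, "exclusion_log"),
    config = config,
    n_used = nrow(screened),
    d15n_s0 = bulk$intercept,
    se_d15n_s0 = bulk$se_intercept,
    sp_mean = sp$sp_mean, sp_sd = sp$sp_sd,
    package_version = as.character(utils::packageVersion("n2okie"))
  ), class = "n2o_report")
}

#' @export
print.n2o_report <- function(x, ...) {
  cat(sprintf("<n2o_report> n = %d observations used\n", x$n_used))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("  d15N_s0 = %.1f +/- %.1f permil;  SP = %.1f +/- %.1f permil (mean +/- SD)\n",
              x$d15n_s0, x$se_d15n_s0, x$sp_mean, x$sp_sd))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap (%d reps): KIE 15N = %.4f +/- %.4f\n",
                x$bootstrap$n_boot, x$bootstrap$mean[["kie_bulk"]],
                x$bootstrap$sd[["kie_bulk"]]))
  }
  if (nrow(x$exclusion_log)) {
    cat(sprintf("  %d observation(s) excluded; see $exclusion_log\n",
                nrow(x$exclusion_log)))
  }
  invisible(x)
}

#' Write and re-read analysis reports
#'
#' `write_report()` serialises an `n2o_report` to a JSON file (full
#' fidelity, used by `read_report()`) and a companion CSV of the
#' per-measurement table; `read_report()` restores the JSON.
#'
#' @param report an `n2o_report`.
#' @param path output path for the JSON report; the CSV companion
#'   replaces the extension with `.csv`.
#' @return `write_report()` the path, invisibly; `read_report()` the
#'   restored report list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "n2o_report"))
  out <- unclass(report)
  out$fits <- lapply(report$fits, unclass)
  out$outlier <- if (!is.null(report$outlier)) unclass(report$outlier)
  out$bootstrap <- if (!is.null(report$bootstrap)) {
    b <- unclass(report$bootstrap)
    b$mean <- as.list(b$mean); b$sd <- as.list(b$sd)
    b
  }
  out$config <- unclass(report$config)
  out$config_hash <- config_hash(report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  utils::write.csv(report$table,
                   sub("\\.[A-Za-z0-9]+$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# stable hash of the configuration for report provenance
config_hash <- function(config) {
  txt <- paste(names(config), vapply(config, format, character(1)),
               sep = "=", collapse = ";")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 1e9
}
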