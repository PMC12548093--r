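#' Cumulative enzymatic N2O from in-bottle amounts
#'
#' Headspace sampling removes product, so the cumulative enzymatic N2O
#' at sampling point i is the amount present in the bottle at i plus
#' everything removed at earlier sampling points.
#'
#' @param in_bottle nmol of N2O present in the reaction vessel at each
#'   sampling point, in time order.
#' @param removed nmol removed at each sampling point (the amount taken
#'   as the sample); length equal to `in_bottle` or one shorter (the
#'   final removal never affects any measurement). Defaults to no
#'   removals.
#' @return Numeric vector of cumulative enzymatic N2O, nmol.
#' @examples
#' cumulative_n2o(c(100, 150), removed = c(10, 0))  # 100, 160
#' @export
cumulative_n2o <- function(in_bottle, removed = rep(0, length(in_bottle))) {
  if (any(!is.finite(in_bottle)) || any(in_bottle < 0)) {
    stop("'in_bottle' amounts must be finite and non-negative",
         call. = FALSE)
  }
  if (length(removed) == length(in_bottle) - 1L) removed <- c(removed, 0)
  if (length(removed) != length(in_bottle)) {
    stop("'removed' must have length equal to (or one less than) 'in_bottle'",
         call. = FALSE)
  }
  if (any(!is.finite(removed)) || any(removed < 0)) {
    stop("'removed' amounts must be finite and non-negative", call. = FALSE)
  }
  prior_removed <- c(0, cumsum(removed)[-length(removed)])
  in_bottle + prior_removed
}

#' Fraction of substrate NO remaining
#'
#' Each N2O consumes two NO (2 NO + 2 e- + 2 H+ -> N2O + H2O), so with
#' `n2o_cum` nmol of cumulative product the fraction of the initial NO
#' pool remaining is `f = (no_initial - 2 * n2o_cum) / no_initial`.
#'
#' @param n2o_cum cumulative enzymatic N2O, nmol.
#' @param no_initial initial NO amount, nmol.
#' @return Numeric vector `f` in \[0, 1\].
#' @examples
#' fraction_remaining(3000, 10300)   # 1 - f is ~0.58 conversion
#' @export
fraction_remaining <- function(n2o_cum, no_initial) {
  stopifnot(is.numeric(no_initial), length(no_initial) == 1L,
            is.finite(no_initial), no_initial > 0)
  if (any(!is.finite(n2o_cum)) || any(n2o_cum < 0)) {
    stop("'n2o_cum' must be finite and non-negative", call. = FALSE)
  }
  if (any(2 * n2o_cum > no_initial)) {
    stop("2 * n2o_cum exceeds the initial NO amount: stoichiometry violated",
         call. = FALSE)
  }
  (no_initial - 2 * n2o_cum) / no_initial
}

#' Rayleigh abscissa for accumulated product regressions
#'
#' The accumulated-product form of Mariotti's approximation predicts
#' product delta as `delta_s0 + epsilon * x(f)` with
#' `x(f) = -f * ln(f) / (1 - f)`. The function is strictly increasing
#' on (0, 1) with limits 0 (complete conversion) and 1 (reaction
#' start), evaluated by continuity at the endpoints.
#'
#' @param f fraction of substrate remaining, in \[0, 1\].
#' @return Numeric vector in \[0, 1\].
#' @examples
#' rayleigh_abscissa(0.5)   # log(2)
#' @export
rayleigh_abscissa <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("'f' must lie in [0, 1]", call. = FALSE)
  }
  x <- ifelse(f == 0, 0, ifelse(f == 1, 1, -f * log(f) / (1 - f)))
  as.numeric(x)
}

#' Assemble a closed-system N2O observation dataset
#'
#' Builds the pooled observation table used by all fitting stages from
#' per-sample measurements: computes the fraction of NO remaining `f`,
#' the Rayleigh abscissa, the beta-site delta (when not measured
#' directly) and site preference.
#'
#' @param data data.frame with columns `replicate_id`, `time_min`,
#'   `n2o_nmol` (cumulative enzymatic N2O), `d15n_bulk`, `d15n_alpha`,
#'   `d18o`, and optionally `d15n_beta`.
#' @param no_initial initial NO amount, nmol (all replicates share it).
#' @param standard_n,standard_o isotope standards for N and O deltas.
#' @return An object of class `n2o_dataset`: the observation
#'   data.frame (with derived columns `d15n_beta`, `sp`, `f`,
#'   `abscissa`) carrying attributes `no_initial`, `standard_n`,
#'   `standard_o`, `exclusion_log`.
#' @seealso [filter_observations()], [read_observations()]
#' @export
n2o_dataset <- function(data, no_initial,
                        standard_n = std_air_n2(),
                        standard_o = std_vsmow_o()) {
  required <- c("replicate_id", "time_min", "n2o_nmol",
                "d15n_bulk", "d15n_alpha", "d18o")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)
  for (col in setdiff(c(required, "d15n_beta"), "replicate_id")) {
    if (col %in% names(data) && !is.numeric(data[[col]])) {
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    }
  }
  if (anyDuplicated(data[c("replicate_id", "time_min")])) {
    stop("duplicated (replicate_id, time_min) rows", call. = FALSE)
  }
  # within-replicate cumulative product must not decrease
  for (rep_id in unique(data$replicate_id)) {
    rows <- data[data$replicate_id == rep_id, ]
    rows <- rows[order(rows$time_min), ]
    if (is.unsorted(rows$n2o_nmol)) {
      warning(sprintf("cumulative N2O decreases within replicate '%s'",
                      rep_id))
    }
  }
  beta_derived <- !("d15n_beta" %in% names(data))
  if (beta_derived) {
    data$d15n_beta <- beta_from_bulk_alpha(data$d15n_bulk, data$d15n_alpha)
  } else {
    gap <- abs(data$d15n_bulk - (data$d15n_alpha + data$d15n_beta) / 2)
    if (any(gap > 0.05)) {
      warning(sprintf(
        "%d row(s) with |bulk - (alpha+beta)/2| > 0.05 permil (max %.3f)",
        sum(gap > 0.05), max(gap)))
    }
  }
  data$sp <- site_preference(data$d15n_alpha, data$d15n_beta)
  data$f <- fraction_remaining(data$n2o_nmol, no_initial)
  data$abscissa <- rayleigh_abscissa(data$f)
  data <- data[order(data$replicate_id, data$time_min), ]
  rownames(data) <- NULL
  structure(data,
            no_initial = no_initial,
            standard_n = standard_n,
            standard_o = standard_o,
            beta_derived = beta_derived,
            exclusion_log = empty_exclusion_log(),
            class = c("n2o_dataset", "data.frame"))
}

empty_exclusion_log <- function() {
  data.frame(replicate_id = character(), time_min = numeric(),
             reason = character(), stringsAsFactors = FALSE)
}

#' @export
print.n2o_dataset <- function(x, ...) {
  cat(sprintf(
    "<n2o_dataset> %d observations, %d replicate(s), NO(0) = %g nmol\n",
    nrow(x), length(unique(x$replicate_id)), attr(x, "no_initial")))
  excl <- attr(x, "exclusion_log")
  if (nrow(excl)) cat(sprintf("  %d excluded row(s) in exclusion_log\n",
                              nrow(excl)))
  print(as.data.frame(x), ...)
  invisible(x)
}

keep_dataset_attrs <- function(new_df, template, exclusion_log = NULL) {
  structure(new_df,
            no_initial = attr(template, "no_initial"),
            standard_n = attr(template, "standard_n"),
            standard_o = attr(template, "standard_o"),
            beta_derived = attr(template, "beta_derived"),
            exclusion_log = if (is.null(exclusion_log))
              attr(template, "exclusion_log") else exclusion_log,
            class = c("n2o_dataset", "data.frame"))
}

#' Apply the observation filters used before Rayleigh fitting
#'
#' Two rules: (1) observations before a conversion `(1 - f)` of
#' `min_conversion` are excluded, because the Mariotti linearisation is
#' least accurate near the start of the reaction; (2) within each
#' replicate, observations from the first plateau point onward are
#' excluded, a plateau point being one whose cumulative N2O increment
#' over the previous sample is below `plateau_fraction` of its
#' cumulative amount (N2O production has effectively stopped). Each
#' removal is logged with its reason; surviving rows from all
#' replicates remain pooled.
#'
#' @param dataset an [n2o_dataset].
#' @param min_conversion minimum `(1 - f)` retained (default 0.1).
#' @param plateau_fraction relative cumulative increment below which a
#'   point is treated as on the plateau (default 0.01).
#' @return The filtered `n2o_dataset`; removals appended to the
#'   `exclusion_log` attribute.
#' @export
filter_observations <- function(dataset, min_conversion = 0.1,
                                plateau_fraction = 0.01) {
  stopifnot(inherits(dataset, "n2o_dataset"))
  drop <- rep(FALSE, nrow(dataset))
  reason <- rep(NA_character_, nrow(dataset))

  early <- (1 - dataset$f) < min_conversion
  drop[early] <- TRUE
  reason[early] <- sprintf("conversion (1-f) below %g", min_conversion)

  for (rep_id in unique(dataset$replicate_id)) {
    idx <- which(dataset$replicate_id == rep_id)
    idx <- idx[order(dataset$time_min[idx])]
    if (length(idx) < 2L) next
    n2o <- dataset$n2o_nmol[idx]
    inc <- diff(n2o)
    # inc <= 0 always counts as "stopped increasing", even at tolerance 0
    plateau <- which(inc < plateau_fraction * n2o[-1L] | inc <= 0)
    if (length(plateau)) {
      at_and_after <- idx[(min(plateau) + 1L):length(idx)]
      newly <- at_and_after[!drop[at_and_after]]
      drop[at_and_after] <- TRUE
      reason[newly] <- "at or after N2O production plateau"
    }
  }

  log_new <- data.frame(
    replicate_id = as.character(dataset$replicate_id[drop]),
    time_min = dataset$time_min[drop],
    reason = reason[drop],
    stringsAsFactors = FALSE)
  kept <- as.data.frame(dataset)[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0L) {
    stop("no observations remain after filtering", call. = FALSE)
  }
  keep_dataset_attrs(kept, dataset,
                     exclusion_log = rbind(attr(dataset, "exclusion_log"),
                                           log_new))
}
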