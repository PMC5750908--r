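#' Log-normal exposure model for a stratum
#'
#' A per-stratum model of private-water-supply arsenic concentrations:
#' `ln(concentration) ~ Normal(ln(gm), sigma_log^2)`.
#'
#' `gm` is the geometric mean in ug/L (the log-normal median).
#' `sigma_log` is the standard deviation of natural-log concentrations —
#' the quantity tabulated as "geometric standard deviation" in stratified
#' environmental surveys of this kind — and is dimensionless.  It is NOT
#' `exp(sd(log(x)))`.
#'
#' @param gm geometric mean, ug/L, > 0.
#' @param sigma_log SD of natural-log concentrations, >= 0.
#' @param n optional number of samples behind the fit.
#' @return an object of class `lognormal_model`.
#' @examples
#' m <- lognormal_model(gm = 1.213, sigma_log = 2.542)
#' exceedance_probability(m, 10)
#' @export
lognormal_model <- function(gm, sigma_log, n = NA_integer_) {
  gm <- as.numeric(gm)
  sigma_log <- as.numeric(sigma_log)
  if (!is.finite(gm) || gm <= 0) {
    stop("gm must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(sigma_log) || sigma_log < 0) {
    stop("sigma_log must be a non-negative finite number", call. = FALSE)
  }
  structure(list(gm = gm, sigma_log = sigma_log,
                 n = as.integer(if (is.null(n) || is.na(n)) NA else n)),
            class = "lognormal_model")
}

as_lognormal_model <- function(x) {
  if (inherits(x, "lognormal_model")) return(x)
  if (is.list(x) && all(c("gm", "sigma_log") %in% names(x))) {
    return(lognormal_model(x$gm, x$sigma_log,
                           if (is.null(x$n)) NA_integer_ else x$n))
  }
  stop("cannot interpret object as a lognormal_model", call. = FALSE)
}

#' @export
print.lognormal_model <- function(x, ...) {
  cat(sprintf("Log-normal exposure model: GM %.4g ug/L, sigma_log %.4g%s\n",
              x$gm, x$sigma_log,
              if (is.na(x$n)) "" else sprintf(" (n = %d)", x$n)))
  invisible(x)
}

#' Fit a log-normal model by log-moment matching
#'
#' `gm = exp(mean(ln x))`; `sigma_log = sd(ln x)` with the sample
#' (n - 1) denominator.  Censored values are expected to have been
#' substituted at the LOD before fitting.
#'
#' @param values positive concentrations, ug/L; length >= 2.
#' @return a [lognormal_model()].
#' @examples
#' fit_lognormal(c(1, exp(2), exp(4)))  # gm = e^2, sigma_log = 2
#' @export
fit_lognormal <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("need at least 2 values to fit a log-normal model", call. = FALSE)
  }
  if (any(!is.finite(values) | values <= 0)) {
    stop("all concentrations must be positive and finite", call. = FALSE)
  }
  lx <- log(values)
  lognormal_model(gm = exp(mean(lx)), sigma_log = stats::sd(lx),
                  n = length(values))
}

#' Exposure-category probabilities under a log-normal model
#'
#' Converts a fitted model to the probabilities of the four exposure
#' bands `<b1`, `[b1, b2)`, `[b2, b3)`, `>= b3` via the log-normal CDF
#' `Phi((ln c - ln gm) / sigma_log)`.  Defaults are the arsenic bands
#' <1, 1-5, 5-10 and >=10 ug/L, the last being exceedance of the
#' prescribed concentration value (PCV).
#'
#' A degenerate model (`sigma_log = 0`) is a point mass at `gm`: all
#' probability falls in the band containing `gm` (the upper band is
#' closed at its lower edge).
#'
#' @param model a [lognormal_model()].
#' @param boundaries three strictly increasing band edges, ug/L.
#' @return an object of class `exposure_probs`: a named numeric vector
#'   `c(p_low, p_med, p_high, p_exceed)` summing to 1.
#' @examples
#' category_probabilities(lognormal_model(0.885, 1.805))
#' @export
category_probabilities <- function(model, boundaries = c(1, 5, 10)) {
  model <- as_lognormal_model(model)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0) ||
      boundaries[1] <= 0) {
    stop("boundaries must be three strictly increasing positive values",
         call. = FALSE)
  }
  if (model$sigma_log == 0) {
    cum <- as.numeric(model$gm < boundaries)
  } else {
    z <- (log(boundaries) - log(model$gm)) / model$sigma_log
    cum <- stats::pnorm(z)
  }
  p <- c(cum[1], cum[2] - cum[1], cum[3] - cum[2], 1 - cum[3])
  structure(stats::setNames(p, c("p_low", "p_med", "p_high", "p_exceed")),
            boundaries = boundaries, class = "exposure_probs")
}

#' Probability of exceeding a concentration threshold
#'
#' Upper-tail probability `1 - Phi((ln t - ln gm) / sigma_log)` of the
#' stratum's log-normal model; with the default threshold this is the
#' modelled proportion of dwellings over the arsenic PCV of 10 ug/L.
#'
#' @param model a [lognormal_model()].
#' @param threshold concentration threshold, ug/L, > 0.
#' @return a probability in `[0, 1]`.
#' @export
exceedance_probability <- function(model, threshold = 10) {
  model <- as_lognormal_model(model)
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  if (model$sigma_log == 0) {
    return(as.numeric(model$gm >= threshold))
  }
  stats::pnorm((log(threshold) - log(model$gm)) / model$sigma_log,
               lower.tail = FALSE)
}

#' Four-level hazard rank from a PCV-exceedance probability
#'
#' Rank 1 (highest hazard) when more than 10% of dwellings are modelled
#' over the PCV; rank 2 for 5-10%; rank 3 for 1-5%; rank 4 (lowest)
#' below 1%.  The 5% and 10% edges belong to rank 2 and the 1% edge to
#' rank 3.
#'
#' @param p_exceed exceedance probability (or vector of them) in `[0, 1]`.
#' @param thresholds three strictly decreasing rank cut-points
#'   (defaults 0.10, 0.05, 0.01).
#' @return integer rank(s) in 1..4.
#' @examples
#' hazard_rank(c(0.203, 0.0093))  # 1, 4
#' @export
hazard_rank <- function(p_exceed, thresholds = c(0.10, 0.05, 0.01)) {
  p_exceed <- as.numeric(p_exceed)
  if (any(!is.finite(p_exceed) | p_exceed < 0 | p_exceed > 1)) {
    stop("p_exceed must lie in [0, 1]", call. = FALSE)
  }
  if (length(thresholds) != 3 || any(diff(thresholds) >= 0)) {
    stop("thresholds must be three strictly decreasing values",
         call. = FALSE)
  }
  ifelse(p_exceed > thresholds[1], 1L,
         ifelse(p_exceed >= thresholds[2], 2L,
                ifelse(p_exceed >= thresholds[3], 3L, 4L)))
}

# round half away from zero; base round() rounds half to even
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Predicted dwelling counts per exposure band
#'
#' Multiplies band probabilities by the number of dwellings with a
#' private supply on the stratum.  Expected counts are real-valued;
#' rounded counts round half away from zero per band.
#'
#' @param probs an `exposure_probs` object from [category_probabilities()].
#' @param n_dwellings non-negative dwelling total for the stratum.
#' @return a list with `expected` and `rounded` (each a named length-4
#'   vector) and `n_dwellings`.
#' @export
predict_dwellings <- function(probs, n_dwellings) {
  stopifnot(inherits(probs, "exposure_probs"))
  if (!is.finite(n_dwellings) || n_dwellings < 0) {
    stop("n_dwellings must be non-negative", call. = FALSE)
  }
  expected <- as.numeric(probs) * n_dwellings
  names(expected) <- names(probs)
  list(expected = expected,
       rounded = stats::setNames(as.integer(round_half_up(expected)),
                                 names(probs)),
       n_dwellings = n_dwellings)
}

hazard_row <- function(sbgc, model, n_dwellings,
                       boundaries = c(1, 5, 10),
                       rank_thresholds = c(0.10, 0.05, 0.01)) {
  model <- as_lognormal_model(model)
  probs <- category_probabilities(model, boundaries)
  pred <- predict_dwellings(probs, n_dwellings)
  data.frame(
    sbgc = sbgc,
    n = if (is.na(model$n)) NA_integer_ else model$n,
    gm = model$gm,
    sigma_log = model$sigma_log,
    pct_lt1 = 100 * probs[["p_low"]],
    pct_1_5 = 100 * probs[["p_med"]],
    pct_5_10 = 100 * probs[["p_high"]],
    pct_ge10 = 100 * probs[["p_exceed"]],
    rank = hazard_rank(probs[["p_exceed"]], rank_thresholds),
    n_dwellings = as.integer(n_dwellings),
    exp_lt1 = pred$expected[["p_low"]],
    exp_1_5 = pred$expected[["p_med"]],
    exp_5_10 = pred$expected[["p_high"]],
    exp_ge10 = pred$expected[["p_exceed"]],
    stringsAsFactors = FALSE
  )
}

#' Build a hazard table for a set of stratum models
#'
#' One row per stratum with model parameters, band percentages, hazard
#' rank and predicted dwelling counts.
#'
#' @param models a named list of [lognormal_model()] objects (names are
#'   stratum labels).
#' @param n_dwellings dwelling totals: a single number recycled to all
#'   strata, or a vector/named vector matching `models`.
#' @param boundaries three exposure band edges, ug/L.
#' @param rank_thresholds three decreasing rank cut-points.
#' @return a `data.frame`, one row per stratum, in the column order
#'   written by [write_hazard_table()].
#' @export
hazard_table <- function(models, n_dwellings = 0,
                         boundaries = c(1, 5, 10),
                         rank_thresholds = c(0.10, 0.05, 0.01)) {
  stopifnot(is.list(models), length(models) > 0)
  labels <- names(models)
  if (is.null(labels)) labels <- as.character(seq_along(models))
  if (length(n_dwellings) == 1) {
    n_dwellings <- rep(n_dwellings, length(models))
  }
  if (!is.null(names(n_dwellings))) {
    n_dwellings <- n_dwellings[labels]
  }
  stopifnot(length(n_dwellings) == length(models))
  rows <- Map(function(lbl, m, nd) {
    hazard_row(lbl, m, nd, boundaries, rank_thresholds)
  }, labels, models, n_dwellings)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-wide prediction of PCV exceedances
#'
#' Aggregates per-stratum expected exceedance counts over a region.
#' Totals are computed from the unrounded per-stratum expectations and
#' rounded only at the end (per-stratum rounding first would bias the
#' total upward).
#'
#' @param models named list of [lognormal_model()] objects.
#' @param n_dwellings per-stratum dwelling totals (single value recycled,
#'   or a vector/named vector).
#' @param boundaries,rank_thresholds passed to [hazard_table()].
#' @return an object of class `region_prediction`: a list with `rows`
#'   (the hazard table), `total_expected_exceedances`, `total_rounded`,
#'   and `per_stratum_share` (fractions of the expected exceedances,
#'   summing to 1 when the total is positive).
#' @examples
#' models <- cornwall_sbgc_params()
#' predict_region(models, n_dwellings = 200)$total_rounded
#' @export
predict_region <- function(models, n_dwellings,
                           boundaries = c(1, 5, 10),
                           rank_thresholds = c(0.10, 0.05, 0.01)) {
  rows <- hazard_table(models, n_dwellings, boundaries, rank_thresholds)
  total <- sum(rows$exp_ge10)
  share <- if (total > 0) rows$exp_ge10 / total else rep(0, nrow(rows))
  structure(list(
    rows = rows,
    total_expected_exceedances = total,
    total_rounded = as.integer(round_half_up(total)),
    per_stratum_share = stats::setNames(share, rows$sbgc)
  ), class = "region_prediction")
}

#' @export
print.region_prediction <- function(x, ...) {
  cat(sprintf("Region prediction over %d strata\n", nrow(x$rows)))
  cat(sprintf("  expected PCV exceedances: %.2f (rounded %d)\n",
              x$total_expected_exceedances, x$total_rounded))
  top <- order(x$per_stratum_share, decreasing = TRUE)[1]
  cat(sprintf("  largest share: %s (%.1f%%)\n",
              x$rows$sbgc[top], 100 * x$per_stratum_share[top]))
  invisible(x)
}

#' Fraction of exceedances captured by a set of hazard ranks
#'
#' The share of region-wide expected PCV exceedances that falls on
#' strata whose hazard rank is in `rank_set` — e.g. the fraction of all
#' exceedances a testing programme restricted to rank-1 and rank-2
#' geologies would capture.
#'
#' @param region a `region_prediction` from [predict_region()].
#' @param rank_set integer ranks to include (subset of 1..4).
#' @return a fraction in `[0, 1]`; 0 when the region total is 0.
#' @export
capture_fraction <- function(region, rank_set) {
  stopifnot(inherits(region, "region_prediction"))
  rank_set <- as.integer(rank_set)
  if (region$total_expected_exceedances == 0) return(0)
  keep <- region$rows$rank %in% rank_set
  sum(region$rows$exp_ge10[keep]) / region$total_expected_exceedances
}

#' Packaged Cornwall SBGC log-normal parameters
#'
#' The ten per-stratum log-normal models (geometric mean, ug/L; SD of
#' log concentrations; sample size) fitted to the 2011-2013 Cornwall
#' private-water-supply arsenic survey, keyed by simplified bedrock
#' geological category.  These are the published model parameters, so
#' the hazard table and regional predictions can be reproduced without
#' any sample data ("skip-fitting" mode).
#'
#' @return a named list of [lognormal_model()] objects.
#' @examples
#' hazard_table(cornwall_sbgc_params(), n_dwellings = 200)
#' @export
cornwall_sbgc_params <- function() {
  path <- system.file("extdata", "cornwall_sbgc_params.json",
                      package = "pwshazard", mustWork = TRUE)
  read_model_params(path)
}
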