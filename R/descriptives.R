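#' Descriptive statistics for one stratum
#'
#' Summarises the concentrations of a single stratum on the ug/L scale:
#' arithmetic mean, median, 25th/75th percentiles (linear interpolation
#' between order statistics, the "type 7" rule), minimum, maximum,
#' geometric mean `exp(mean(ln x))`, `sigma_log = sd(ln x)` (n - 1
#' denominator), and the empirical exposure-band fractions.
#'
#' Censored values enter at their substituted value (the LOD), which is
#' why a stratum's minimum can equal the LOD exactly.
#'
#' @param records a sample `data.frame` containing a single stratum, or
#'   any subset of rows to summarise together; needs >= 2 rows.
#' @param boundaries three exposure band edges, ug/L.
#' @return an object of class `stratum_summary` (a one-row `data.frame`
#'   with columns `sbgc`, `n`, `arithmetic_mean`, `median`, `p25`, `p75`,
#'   `minimum`, `maximum`, `gm`, `sigma_log`, `frac_lt1`, `frac_1_5`,
#'   `frac_5_10`, `frac_ge10`).
#' @export
summarise_stratum <- function(records, boundaries = c(1, 5, 10)) {
  check_samples(records)
  x <- records$arsenic_ugL
  if (length(x) < 2) {
    stop("need at least 2 records to summarise a stratum", call. = FALSE)
  }
  lx <- log(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  fr <- empirical_band_fractions(records, boundaries)
  lbl <- unique(records$sbgc)
  out <- data.frame(
    sbgc = if (length(lbl) == 1) lbl else "combined",
    n = length(x),
    arithmetic_mean = mean(x),
    median = q[2],
    p25 = q[1],
    p75 = q[3],
    minimum = min(x),
    maximum = max(x),
    gm = exp(mean(lx)),
    sigma_log = stats::sd(lx),
    frac_lt1 = fr[[1]],
    frac_1_5 = fr[[2]],
    frac_5_10 = fr[[3]],
    frac_ge10 = fr[[4]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("stratum_summary", "data.frame")
  out
}

#' Empirical exposure-band fractions
#'
#' Fractions of records in the bands `[0, b1)`, `[b1, b2)`, `[b2, b3)`
#' and `[b3, Inf)`.  Bands are closed on the left, so a value exactly at
#' the top edge (10 ug/L by default) counts as a PCV exceedance.
#'
#' @param records sample `data.frame` with >= 1 row.
#' @param boundaries three strictly increasing band edges, ug/L.
#' @return a named numeric vector of four fractions summing to 1.
#' @export
empirical_band_fractions <- function(records, boundaries = c(1, 5, 10)) {
  check_samples(records)
  if (nrow(records) < 1) stop("no records", call. = FALSE)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0)) {
    stop("boundaries must be three strictly increasing values",
         call. = FALSE)
  }
  x <- records$arsenic_ugL
  counts <- c(sum(x < boundaries[1]),
              sum(x >= boundaries[1] & x < boundaries[2]),
              sum(x >= boundaries[2] & x < boundaries[3]),
              sum(x >= boundaries[3]))
  stats::setNames(counts / length(x),
                  c("frac_lt1", "frac_1_5", "frac_5_10", "frac_ge10"))
}

#' Per-stratum summary table for a whole study
#'
#' Applies [summarise_stratum()] to every stratum present, in order of
#' first appearance.
#'
#' @param samples sample `data.frame` covering one or more strata.
#' @param boundaries three exposure band edges, ug/L.
#' @return a `data.frame` with one `stratum_summary` row per stratum.
#' @export
summarise_study <- function(samples, boundaries = c(1, 5, 10)) {
  check_samples(samples)
  labels <- unique(samples$sbgc)
  rows <- lapply(labels, function(lbl) {
    summarise_stratum(samples[samples$sbgc == lbl, , drop = FALSE],
                      boundaries)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a study summary table to CSV
#'
#' @param summary a `data.frame` from [summarise_study()].
#' @param path output file path.
#' @param digits significant figures for numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path, digits = 3) {
  stopifnot(is.data.frame(summary), nrow(summary) > 0)
  out <- summary
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
  out[num] <- lapply(out[num], signif, digits = digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
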