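#' Tukey ladder-of-powers transformations
#'
#' The nine classical candidate transformations used to normalise
#' positive right- or left-skewed data: cubic, square, identity, square
#' root, log (natural), inverse square root, inverse, inverse square,
#' inverse cubic.  Inverse-family transforms are not sign-negated: the
#' order reversal they induce is irrelevant to a normality test.
#'
#' @format character vector of the nine transformation names, strongest
#'   expansion first.
#' @export
ladder_transformations <- c("cubic", "square", "identity", "sqrt", "log",
                            "inv_sqrt", "inverse", "inv_square", "inv_cubic")

#' Apply a ladder-of-powers transformation
#'
#' @param values positive numeric values.
#' @param name one of [ladder_transformations].
#' @return the transformed values.
#' @examples
#' apply_transformation(c(1, exp(1)), "log")  # 0, 1
#' @export
apply_transformation <- function(values, name) {
  values <- as.numeric(values)
  name <- match.arg(name, ladder_transformations)
  if (any(!is.finite(values) | values <= 0)) {
    stop("ladder transformations require strictly positive values",
         call. = FALSE)
  }
  switch(name,
         cubic = values^3,
         square = values^2,
         identity = values,
         sqrt = sqrt(values),
         log = log(values),
         inv_sqrt = 1 / sqrt(values),
         inverse = 1 / values,
         inv_square = 1 / values^2,
         inv_cubic = 1 / values^3)
}

# Z-transform of the sample skewness (D'Agostino 1970).
skewness_z <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  m2 <- mean(m^2)
  m3 <- mean(m^3)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  delta * asinh(y / alpha)
}

# Z-transform of the sample kurtosis (Anscombe & Glynn 1983).
kurtosis_z <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  m2 <- mean(m^2)
  b2 <- mean(m^4) / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  (1 - 2 / (9 * a) - term2) / sqrt(2 / (9 * a))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardised sample skewness and kurtosis into
#' `K2 = Z(sqrt(b1))^2 + Z(b2)^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom (upper tail).  Small K2 /
#' large p indicate compatibility with normality.  Requires n >= 20 for
#' the kurtosis normalisation to be reliable.
#'
#' @param values numeric sample, n >= 20.
#' @return a list with `k2_stat` and `p_value`.
#' @export
normality_k2 <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 20) {
    stop("normality_k2 requires at least 20 observations (got ", n, ")",
         call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("normality_k2 is undefined for constant data", call. = FALSE)
  }
  k2 <- skewness_z(values)^2 + kurtosis_z(values)^2
  list(k2_stat = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Select the best normalising transformation for a stratum
#'
#' Evaluates each ladder transformation with [normality_k2()] and selects
#' the one with the largest p-value (ties broken toward log, then toward
#' identity).  Two situations fall back to an *assumed* log transform,
#' mirroring standard practice for environmental concentration data:
#'
#' * fewer than `min_n` observations — too few to identify a
#'   transformation reliably, no test is run;
#' * no transformation reaches `p >= alpha` — normality is not
#'   appropriate on any rung of the ladder.
#'
#' @param values positive concentrations.
#' @param min_n minimum sample size for running the search (default 30).
#' @param alpha significance level below which no transformation is
#'   considered adequate (default 0.05).
#' @return a `data.frame` with one row per evaluated transformation
#'   (columns `name`, `k2_stat`, `p_value`, `selected`,
#'   `assumed_default`); exactly one row has `selected = TRUE`.  When no
#'   test was run (n < `min_n`), a single log row with `NA` statistics.
#' @export
select_transformation <- function(values, min_n = 30, alpha = 0.05) {
  values <- as.numeric(values)
  if (any(!is.finite(values) | values <= 0)) {
    stop("values must be strictly positive", call. = FALSE)
  }
  if (length(values) < min_n) {
    return(data.frame(name = "log", k2_stat = NA_real_,
                      p_value = NA_real_, selected = TRUE,
                      assumed_default = TRUE, stringsAsFactors = FALSE))
  }
  res <- lapply(ladder_transformations, function(nm) {
    k <- normality_k2(apply_transformation(values, nm))
    data.frame(name = nm, k2_stat = k$k2_stat, p_value = k$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  # tie-break preference: log, then identity, then ladder order
  pref <- match(tab$name, c("log", "identity"))
  pref[is.na(pref)] <- 3L
  ord <- order(-tab$p_value, pref)
  best <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == best
  if (tab$p_value[best] < alpha) {
    # none of the rungs is adequately normal: impose log
    tab$selected <- tab$name == "log"
    tab$assumed_default <- tab$name == "log"
  } else {
    tab$assumed_default <- FALSE
  }
  rownames(tab) <- NULL
  tab
}

#' Ladder report over a whole study
#'
#' Runs [select_transformation()] per stratum and stacks the selected
#' rows (plus the full nine-rung table when `full = TRUE`).
#'
#' @param samples sample `data.frame`.
#' @param min_n,alpha passed to [select_transformation()].
#' @param full return all evaluated rungs per stratum rather than only
#'   the selected one.
#' @return a `data.frame` with a leading `sbgc` column.
#' @export
ladder_report <- function(samples, min_n = 30, alpha = 0.05, full = FALSE) {
  check_samples(samples)
  labels <- unique(samples$sbgc)
  rows <- lapply(labels, function(lbl) {
    tab <- select_transformation(
      samples$arsenic_ugL[samples$sbgc == lbl], min_n, alpha)
    if (!full) tab <- tab[tab$selected, , drop = FALSE]
    cbind(sbgc = lbl, tab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normal quantile-quantile points
#'
#' Pairs the sorted, standardised observations with standard-normal
#' quantiles at plotting positions `(i - 0.5) / n`.  Points near the
#' identity line indicate compatibility with normality.
#'
#' @param values numeric sample, n >= 3.
#' @return a `data.frame` with columns `theoretical` and `observed`
#'   (observations standardised by sample mean and SD).
#' @export
qq_points <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("qq_points requires at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("qq_points is undefined for constant data", call. = FALSE)
  data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    observed = (sort(values) - mean(values)) / s
  )
}
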