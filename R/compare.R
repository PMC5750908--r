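#' Robust Levene test for equality of variances
#'
#' Brown-Forsythe-type Levene statistic on absolute deviations
#' `Z_ij = |x_ij - c_i|` from a robust per-group centre: the group
#' median, or the 10% trimmed mean (`floor(0.1 n)` observations removed
#' from each tail; trimming affects the centring only, not the
#' deviations).  `W` is the one-way ANOVA F statistic of the `Z_ij`,
#' referred to `F(k - 1, N - k)`.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @param center `"median"` (default) or `"trimmed_mean_10"`.
#' @return a list with `W`, `df1`, `df2`, `p_value`.
#' @export
levene_robust <- function(groups, center = c("median", "trimmed_mean_10")) {
  center <- match.arg(center)
  stopifnot(is.list(groups))
  if (length(groups) < 2) {
    stop("levene_robust needs at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  centre_fun <- switch(center,
                       median = stats::median,
                       trimmed_mean_10 = function(x) mean(x, trim = 0.1))
  z <- lapply(groups, function(x) abs(x - centre_fun(x)))
  k <- length(z)
  n_tot <- sum(sizes)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / n_tot
  between <- sum(sizes * (zbar_i - zbar)^2)
  within <- sum(vapply(seq_len(k),
                       function(i) sum((z[[i]] - zbar_i[i])^2), numeric(1)))
  if (within == 0) {
    stop("degenerate data: zero within-group spread of deviations",
         call. = FALSE)
  }
  w <- (n_tot - k) / (k - 1) * between / within
  list(W = w, df1 = k - 1, df2 = n_tot - k,
       p_value = stats::pf(w, k - 1, n_tot - k, lower.tail = FALSE))
}

#' Kruskal-Wallis rank-sum test
#'
#' Compares group medians via mid-ranks, with the usual tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; the statistic is referred to a
#' chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, total N >= 3).
#' @return a list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) {
    stop("kruskal_wallis needs at least 2 groups", call. = FALSE)
  }
  x <- unlist(groups)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1) {
    stop("degenerate data: all observations identical", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Compare arsenic distributions across strata
#'
#' The between-stratum decision flow: both robust Levene variants
#' (median and 10%-trimmed-mean centring) are run on log concentrations;
#' the strata are treated as homoscedastic only if BOTH are
#' non-significant at `alpha`.  If homoscedastic, means of the log
#' concentrations are compared with a pooled two-sample t-test (two
#' strata) or one-way ANOVA (more than two); otherwise the Kruskal-Wallis
#' rank-sum test compares the distributions (ranks are unaffected by the
#' log transform, so it is applied to raw concentrations).
#'
#' @param samples sample `data.frame` covering >= 2 strata.
#' @param alpha significance level for the homoscedasticity gate
#'   (default 0.05).
#' @return an object of class `comparison_report`: a list with
#'   `levene_median`, `levene_trimmed`, `homoscedastic`, `final_test`
#'   (`"t_test"`, `"anova"` or `"kruskal_wallis"`), `final_stat`,
#'   `final_df`, `final_p`, `alpha`, `k`.
#' @export
compare_strata <- function(samples, alpha = 0.05) {
  check_samples(samples)
  labels <- unique(samples$sbgc)
  if (length(labels) < 2) {
    stop("compare_strata needs at least 2 strata", call. = FALSE)
  }
  groups_raw <- split(samples$arsenic_ugL, factor(samples$sbgc, labels))
  groups_log <- lapply(groups_raw, log)
  lev_med <- levene_robust(groups_log, "median")
  lev_trim <- levene_robust(groups_log, "trimmed_mean_10")
  homo <- lev_med$p_value >= alpha && lev_trim$p_value >= alpha
  k <- length(labels)
  if (homo && k == 2) {
    tt <- stats::t.test(groups_log[[1]], groups_log[[2]], var.equal = TRUE)
    final <- list(test = "t_test", stat = unname(tt$statistic),
                  df = unname(tt$parameter), p = tt$p.value)
  } else if (homo) {
    x <- unlist(groups_log)
    g <- factor(rep(labels, lengths(groups_log)))
    ow <- stats::oneway.test(x ~ g, var.equal = TRUE)
    final <- list(test = "anova", stat = unname(ow$statistic),
                  df = unname(ow$parameter), p = ow$p.value)
  } else {
    kw <- kruskal_wallis(groups_raw)
    final <- list(test = "kruskal_wallis", stat = kw$H, df = kw$df,
                  p = kw$p_value)
  }
  structure(list(
    levene_median = lev_med,
    levene_trimmed = lev_trim,
    homoscedastic = homo,
    final_test = final$test,
    final_stat = final$stat,
    final_df = final$df,
    final_p = final$p,
    alpha = alpha,
    k = k
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Between-stratum comparison (%d strata)\n", x$k))
  cat(sprintf("  Levene (median centre):       W = %.4g, p = %.3g\n",
              x$levene_median$W, x$levene_median$p_value))
  cat(sprintf("  Levene (10%% trimmed centre):  W = %.4g, p = %.3g\n",
              x$levene_trimmed$W, x$levene_trimmed$p_value))
  cat(sprintf("  homoscedastic at alpha = %.3g: %s\n", x$alpha,
              if (x$homoscedastic) "yes" else "no"))
  cat(sprintf("  final test: %s, statistic = %.4g, p = %.3g\n",
              x$final_test, x$final_stat, x$final_p))
  invisible(x)
}

comparison_report_to_list <- function(x) {
  list(
    levene_median = x$levene_median,
    levene_trimmed = x$levene_trimmed,
    homoscedastic = x$homoscedastic,
    final_test = x$final_test,
    final_stat = x$final_stat,
    final_df = x$final_df,
    final_p = x$final_p,
    alpha = x$alpha,
    k = x$k
  )
}

#' Write a comparison report to JSON
#'
#' @param report a `comparison_report` from [compare_strata()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(comparison_report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
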