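#' Statistical tests used by the cohort comparisons
#'
#' Cohort proper-pair counts are compared with the Wilcoxon rank sum test
#' with continuity correction (two-sided, P < 0.05 significant), and the
#' relation between chromosome length and per-chromosome segregation
#' frequency with the Pearson correlation coefficient.
#'
#' @name cohort_stats
NULL

new_stat_result <- function(statistic, p_value, method, n_x, n_y,
                            extra = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p-value outside [0, 1]")
  }
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method, n_x = n_x, n_y = n_y), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, p = %.4g (n_x = %d, n_y = %d)\n",
              x$method, x$statistic, x$p_value, x$n_x, x$n_y))
  invisible(x)
}

#' Wilcoxon rank sum test
#'
#' Two-sided rank sum test with midranks for ties. The exact null
#' distribution (full enumeration over rank assignments) is used when the
#' combined sample size is at most 12 and the data are tie-free; otherwise
#' the normal approximation with tie-corrected variance and a 0.5
#' continuity correction is applied. The chosen path is recorded in the
#' result's `exact` field.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param continuity Apply the continuity correction on the approximate
#'   path (default TRUE).
#' @param exact_max Combined-size threshold for the exact path
#'   (default 12).
#' @return A `stat_result` with the rank-sum statistic `W` (number of
#'   (x, y) pairs with x > y, ties counted half), the two-sided p-value,
#'   and group means.
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE, exact_max = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exact_max && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = continuity))
  new_stat_result(res$statistic, res$p.value,
                  if (exact) "Wilcoxon rank sum test (exact)" else
                    "Wilcoxon rank sum test with continuity correction",
                  length(x), length(y),
                  extra = list(exact = exact, mean_x = mean(x),
                               mean_y = mean(y), ties = ties))
}

#' Pearson correlation
#'
#' Standard product-moment correlation with the usual t-based two-sided
#' p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `stat_result` with the correlation coefficient `r`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  res <- stats::cor.test(x, y, method = "pearson")
  new_stat_result(unname(res$estimate), res$p.value,
                  "Pearson correlation", length(x), length(y))
}

#' Compare observed proper-pair counts with the random null
#'
#' @param observed_counts Observed per-embryo proper-pair counts.
#' @param null_counts Simulated null counts (vector or matrix from
#'   [simulate_random_null()]).
#' @return A `stat_result` (Wilcoxon rank sum) carrying both group means.
#' @export
compare_observed_to_null <- function(observed_counts, null_counts) {
  null_counts <- as.vector(null_counts)
  wilcoxon_rank_sum(observed_counts, null_counts)
}
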