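#' Enrichment threshold from a negative-control intensity distribution
#'
#' Mean plus two sample standard deviations (n - 1 denominator) of the
#' control intensities: the classification cutoff used against
#' negative-control vesicle populations (0% target lipid, or
#' expression-inhibited controls).
#'
#' @param control_intensities Numeric vector, >= 2 finite values.
#' @return The threshold (a.u.).
#' @examples
#' enrichment_threshold(c(0, 2))  # 1 + 2*sqrt(2)
#' @export
enrichment_threshold <- function(control_intensities) {
  x <- as.numeric(control_intensities)
  .assert(length(x) >= 2 && all(is.finite(x)),
          "insufficient control: need >= 2 finite control intensities")
  mean(x) + 2 * stats::sd(x)
}

#' Classify vesicles as lipid-enriched
#'
#' Strict comparison: a vesicle is enriched when its intensity is strictly
#' greater than the threshold (a value exactly at the threshold is not
#' enriched).
#'
#' @param intensities Numeric vector of per-vesicle intensities.
#' @param threshold Finite threshold (a.u.), typically from
#'   [enrichment_threshold()].
#' @return A list of class `enrichment_result`: `threshold`, `n_total`,
#'   `n_enriched`, `percent_enriched` (in `[0, 100]`), and the logical
#'   `enriched` vector.
#' @export
classify_enriched <- function(intensities, threshold) {
  x <- as.numeric(intensities)
  .assert(length(x) >= 1, "empty input: no intensities to classify")
  .assert(all(is.finite(x)), "intensities must be finite")
  .assert(.is_num1(threshold), "threshold must be finite")
  enr <- x > threshold
  structure(list(threshold = threshold, n_total = length(x),
                 n_enriched = sum(enr),
                 percent_enriched = 100 * sum(enr) / length(x),
                 enriched = enr),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d / %d vesicles enriched (%.1f%%) at threshold %.4g a.u.\n",
              x$n_enriched, x$n_total, x$percent_enriched, x$threshold))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample SD (n - 1) divided by the mean. Used to compare the dispersion of
#' single-vesicle intensities between synthesizing populations and controls
#' with a predetermined lipid fraction.
#'
#' @param values Numeric vector with positive mean.
#' @return `sd(values) / mean(values)`.
#' @export
coefficient_of_variation <- function(values) {
  x <- as.numeric(values)
  .assert(length(x) >= 2 && all(is.finite(x)), "need >= 2 finite values")
  m <- mean(x)
  .assert(m > 0, "undefined CV: mean must be positive")
  stats::sd(x) / m
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (wraps [stats::t.test()]).
#'
#' @param group_a,group_b Numeric vectors, each >= 2 values; the pooled
#'   standard error must be positive.
#' @return A list with `t`, `p_value`, `df`.
#' @export
welch_test <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  .assert(length(a) >= 2 && length(b) >= 2, "each group needs >= 2 values")
  .assert(all(is.finite(a)) && all(is.finite(b)), "values must be finite")
  .assert(stats::var(a) > 0 || stats::var(b) > 0,
          "degenerate variance: both groups are constant")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Box-plot statistics
#'
#' Quartiles by linear interpolation (type 7); whiskers extend to the most
#' extreme data points within 1.5 interquartile ranges of the box ends;
#' points beyond the whiskers are outliers. Every point is either inside
#' the whiskers or an outlier, never both.
#'
#' @param values Numeric vector, >= 1 value.
#' @return A list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_stats <- function(values) {
  x <- as.numeric(values)
  .assert(length(x) >= 1 && all(is.finite(x)), "need >= 1 finite value")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(x[inside]), whisker_high = max(x[inside]),
       outliers = sort(x[!inside]))
}

#' Pearson correlation
#'
#' Sample Pearson correlation coefficient, e.g. between initial PG content
#' of the membrane and the yield of synthesized lipid.
#'
#' @param x,y Numeric vectors, `n >= 3`, non-zero variance.
#' @return The correlation coefficient.
#' @seealso [pearson_repeats()] for per-repeat application.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3, "need n >= 3")
  .assert(all(is.finite(x)) && all(is.finite(y)), "values must be finite")
  .assert(stats::var(x) > 0 && stats::var(y) > 0,
          "zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Per-repeat Pearson correlation, summarised as mean and SD
#'
#' Computes [pearson_correlation()] within each level of `repeat_id` (one
#' level per independent experiment) and reports the mean and SD across
#' repeats — the form in which correlations over independent experimental
#' repeats are conventionally quoted.
#'
#' @param x,y Numeric vectors.
#' @param repeat_id Factor-like vector assigning each point to a repeat.
#' @return A list with `mean`, `sd`, `per_repeat` (named vector).
#' @export
pearson_repeats <- function(x, y, repeat_id) {
  .assert(length(x) == length(y) && length(x) == length(repeat_id),
          "x, y and repeat_id must have equal length")
  rho <- vapply(split(seq_along(x), repeat_id),
                function(i) pearson_correlation(x[i], y[i]), numeric(1))
  list(mean = mean(rho), sd = stats::sd(rho), per_repeat = rho)
}
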