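# Strain-level proportion statistics: Wilson intervals, Fisher's exact
# two-group comparison with figure-style significance labels, and
# percent-change arithmetic.

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, @param n trials, @param conf confidence level.
#' @return length-2 numeric (lower, upper).
#' @noRd
wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Proportion with Wilson 95% confidence interval
#'
#' @param k number of cells with the feature (e.g. an obvious cluster).
#' @param n number of cells examined.
#' @param conf confidence level (default 0.95).
#' @return list: k, n, proportion, percent (one decimal, matching the
#'   reporting convention), ci_lower, ci_upper (proportions).
#' @export
#' @examples
#' proportion_summary(140, 234)  # 59.8%
proportion_summary <- function(k, n, conf = 0.95) {
  if (length(k) != 1L || length(n) != 1L) stop("k and n must be scalars")
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  ci <- wilson_interval(k, n, conf)
  list(k = as.integer(k), n = as.integer(n),
       proportion = k / n,
       percent = round(100 * k / n, 1),
       ci_lower = ci[1], ci_upper = ci[2])
}

#' Compare two proportions (Fisher's exact test + significance label)
#'
#' Two-sided Fisher's exact test on the 2x2 count table, exact for small
#' and large counts alike. A two-proportion z-test p-value is reported
#' alongside, since borderline contrasts can flip between tests. Labels:
#' \code{'***'} for p < 0.0001, \code{'ns'} for p > 0.05,
#' \code{'intermediate'} otherwise (always reported with the raw p).
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list: p_value (Fisher), p_ztest, label, table.
#' @export
#' @examples
#' compare_two_proportions(332, 372, 140, 234)
compare_two_proportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("both groups need at least one trial")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts out of range")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE,
                dimnames = list(group = c("g1", "g2"),
                                outcome = c("yes", "no")))
  p_fisher <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  # pooled two-proportion z-test, no continuity correction
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  p_z <- if (se == 0) 1 else 2 * stats::pnorm(-abs(p1 - p2) / se)
  label <- if (p_fisher < 1e-4) "***" else if (p_fisher > 0.05) "ns" else
    "intermediate"
  list(p_value = p_fisher, p_ztest = p_z, label = label, table = tab)
}

#' Percent change, in both conventions
#'
#' A "decrease of 12.8%" of a proportion is ambiguous: it may mean 12.8
#' percentage points or a relative change of 12.8%. Both are returned,
#' labeled, and neither is asserted as the other.
#'
#' @param value_new new value, @param value_ref reference value.
#' @param proportions if TRUE (default) the absolute difference is also
#'   expressed in percentage points (x100).
#' @return list: absolute_pp (percentage points; NA when
#'   \code{proportions = FALSE} gives the raw difference instead),
#'   relative_percent.
#' @export
#' @examples
#' percent_change(0.771, 0.899)   # -12.8 percentage points
#' percent_change(1.718, 1.0)     # +71.8% relative
percent_change <- function(value_new, value_ref, proportions = TRUE) {
  if (!is.finite(value_new) || !is.finite(value_ref)) stop("non-finite input")
  if (value_ref == 0) stop("relative change undefined for value_ref = 0")
  list(
    absolute_pp = if (proportions) 100 * (value_new - value_ref) else
      value_new - value_ref,
    relative_percent = 100 * (value_new - value_ref) / value_ref
  )
}
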