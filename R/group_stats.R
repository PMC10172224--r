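# Group-level statistics: Shapiro-Wilk normality gating, two-group
# comparisons (Student's t / Wilcoxon rank-sum) with Bonferroni correction,
# and the summary conventions used for reporting (median +/- MAD,
# mean +/- STD, variance tables).

#' Normality gate for a feature sample
#'
#' TRUE (treat as normal) iff the Shapiro-Wilk test does not reject at
#' \code{alpha}. A constant sample is non-normal by convention (warning).
#' Missing values are removed first.
#'
#' @param values numeric vector, at least 3 non-missing values.
#' @param alpha gate level (default 0.05).
#' @return Logical scalar.
#' @export
normalityGate <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 3L) stop("need at least 3 non-missing values")
  if (length(unique(x)) == 1L) {
    warning("constant sample: treated as non-normal")
    return(FALSE)
  }
  if (length(x) > 5000L) x <- x[seq_len(5000L)]  # shapiro.test limit
  stats::shapiro.test(x)$p.value >= alpha
}

#' Compare a treated group against its control
#'
#' Test selection follows the normality gate: if both samples pass, a
#' two-tailed two-sample Student's t test (pooled variance); otherwise the
#' two-sided Wilcoxon rank-sum test (exact when both n <= 20 and no ties,
#' normal approximation with continuity and tie correction otherwise). When
#' exactly one sample is normal the more conservative Wilcoxon branch is
#' used. The raw p value is Bonferroni-adjusted by the family size
#' \code{m}. Effect direction and percent change use the branch's location:
#' mean for Student's t, median for Wilcoxon.
#'
#' @param control,treated numeric vectors (missing values dropped), both
#'   with at least 3 non-missing values.
#' @param m Bonferroni family size (>= 1), the number of condition-vs-
#'   control comparisons in the family.
#' @param method "auto" (gate; default), or force "student"/"wilcoxon".
#' @param alpha significance level after adjustment (default 0.05).
#' @return A one-row data.frame: test_used, raw_p, adjusted_p,
#'   m_comparisons, significant, effect_direction, percent_change,
#'   n_control, n_treated.
#' @examples
#' set.seed(1)
#' compareGroups(rnorm(50), rnorm(50, 1), m = 3)
#' @export
compareGroups <- function(control, treated, m = 1L,
                          method = c("auto", "student", "wilcoxon"),
                          alpha = 0.05) {
  method <- match.arg(method)
  a <- control[!is.na(control)]
  b <- treated[!is.na(treated)]
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 non-missing values per group")
  m <- as.integer(m)
  stopifnot(m >= 1L)
  if (method == "auto") {
    normal <- suppressWarnings(normalityGate(a) && normalityGate(b))
    method <- if (normal) "student" else "wilcoxon"
  }
  if (method == "student") {
    p <- stats::t.test(b, a, var.equal = TRUE)$p.value
    loc_c <- mean(a); loc_t <- mean(b)
    test_used <- "student_t"
  } else {
    exact <- length(a) <= 20L && length(b) <= 20L &&
      !any(duplicated(c(a, b)))
    p <- suppressWarnings(stats::wilcox.test(b, a, exact = exact,
                                             correct = TRUE)$p.value)
    loc_c <- stats::median(a); loc_t <- stats::median(b)
    test_used <- "wilcoxon_rank_sum"
  }
  adj <- min(1, p * m)
  data.frame(test_used = test_used, raw_p = p, adjusted_p = adj,
             m_comparisons = m, significant = adj < alpha,
             effect_direction = sign(loc_t - loc_c),
             percent_change = if (loc_c != 0)
               100 * (loc_t - loc_c) / loc_c else NA_real_,
             n_control = length(a), n_treated = length(b),
             stringsAsFactors = FALSE)
}

#' Summary statistics of a feature sample
#'
#' Mean, standard deviation, median, MAD and variance; the reporting
#' conventions are median +/- MAD for skewed features and mean +/- STD for
#' symmetric ones. MAD is the plain median of absolute deviations from the
#' median (no consistency constant); variance uses the n - 1 denominator.
#'
#' @param values numeric vector with at least one non-missing value.
#' @return Named numeric: mean, std, median, mad, variance (std/variance NA
#'   at n = 1).
#' @examples
#' summarizeFeature(c(1, 2, 3, 4, 100))  # median 3, mad 1
#' @export
summarizeFeature <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) == 0L) stop("empty sample")
  med <- stats::median(x)
  c(mean = mean(x), std = stats::sd(x), median = med,
    mad = stats::median(abs(x - med)), variance = stats::var(x))
}

#' Per-condition feature variance table
#'
#' Condition-by-feature grid of sample variances with per-condition sample
#' sizes, mirroring how regularization of cell response is summarized:
#' rows are conditions (with n = cells contributing), columns the feature
#' variances. Missing values are excluded per feature; a feature with fewer
#' than 2 values in a condition yields NA.
#'
#' @param features data.frame of per-cell rows.
#' @param featureCols character vector of feature column names.
#' @param conditionCol name of the condition column (default "condition").
#' @return A data.frame: condition, n, then var_<feature> columns.
#' @export
varianceTable <- function(features, featureCols,
                          conditionCol = "condition") {
  stopifnot(conditionCol %in% names(features),
            all(featureCols %in% names(features)))
  conds <- unique(features[[conditionCol]])
  rows <- lapply(conds, function(cc) {
    sub <- features[features[[conditionCol]] == cc, , drop = FALSE]
    out <- data.frame(condition = cc, n = nrow(sub),
                      stringsAsFactors = FALSE)
    for (f in featureCols) {
      x <- sub[[f]][!is.na(sub[[f]])]
      out[[paste0("var_", f)]] <- if (length(x) >= 2L) stats::var(x) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
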