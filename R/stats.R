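#' One-sided exact binomial test (upper tail)
#'
#' Exact tail probability P(X >= k) for X ~ Binomial(n, p0), summed term by
#' term in log space — no normal approximation, so p-values far below
#' machine-friendly scales (e.g. 1e-25 for 81/81 correct calls at chance 0.5)
#' are computed accurately. This is the test used to ask whether an observed
#' rate of correct sex predictions beats chance (p0 = 0.5).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Success probability under the null; default 0.5 (chance).
#' @return Object of class `"binomial_result"`: list with `k`, `n`, `p0`,
#'   `p_value`.
#' @examples
#' exact_binomial_one_sided(8, 8)$p_value    # 0.00390625
#' exact_binomial_one_sided(81, 81)$p_value  # ~4.14e-25
#' @export
exact_binomial_one_sided <- function(k, n, p0 = 0.5) {
  if (!(is.numeric(k) && is.numeric(n) && length(k) == 1L && length(n) == 1L))
    stop("'k' and 'n' must be single numbers")
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L || k < 0L || k > n) stop("need 0 <= k <= n with n >= 1")
  if (!(p0 > 0 && p0 < 1)) stop("'p0' must be in (0, 1)")
  i <- k:n
  log_terms <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  # sum on the largest term's scale to avoid underflow of the total
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  structure(list(k = k, n = n, p0 = p0, p_value = min(p, 1)),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("one-sided exact binomial test: %d/%d vs chance %.3g, p = %.3g\n",
              x$k, x$n, x$p0, x$p_value))
  invisible(x)
}

# Student's t with a documented limit for zero-variance input, which
# stats::t.test rejects as essentially constant data.
t_result <- function(t, df, p) list(t = t, df = df, p_value = p)

#' Unpaired two-sample Student's t test
#'
#' Pooled-variance (classical Student) two-sided t test, the comparison used
#' for male vs female dosage groups. `var_equal = FALSE` switches to Welch.
#' Degenerate zero-variance input returns the documented limit: p = 1 when
#' the means agree, p = 0 (t infinite) otherwise.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test_two_sample <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(t_result(0, length(group_a) + length(group_b) - 2, 1))
    }
    return(t_result(sign(mean(group_a) - mean(group_b)) * Inf,
                    length(group_a) + length(group_b) - 2, 0))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = var_equal)
  t_result(unname(fit$statistic), unname(fit$parameter), fit$p.value)
}

#' One-sample Student's t test
#'
#' Two-sided test of the mean against `mu0`; used when only one reference
#' group exists (e.g. comparing the female dosage population to 0 when a
#' single male sample anchors the normalization).
#'
#' @param values Numeric vector with >= 2 values.
#' @param mu0 Null mean; default 0.
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test_one_sample <- function(values, mu0 = 0) {
  stopifnot(length(values) >= 2L)
  if (stats::sd(values) == 0) {
    if (mean(values) == mu0) return(t_result(0, length(values) - 1, 1))
    return(t_result(sign(mean(values) - mu0) * Inf, length(values) - 1, 0))
  }
  fit <- stats::t.test(values, mu = mu0)
  t_result(unname(fit$statistic), unname(fit$parameter), fit$p.value)
}

#' Estimate amplification efficiency from a dilution series
#'
#' Fits the standard curve Cq ~ log10(input) by least squares and converts
#' the slope to percent efficiency via `(10^(-1/slope) - 1) * 100`. A slope
#' of exactly -log10(2)^-1 = -3.3219 corresponds to 100% (perfect doubling).
#' Assays are conventionally accepted when efficiency falls within 90--110%.
#'
#' @param log10_inputs log10 of relative template input, strictly monotone.
#' @param cqs Measured Cq at each input (same length, >= 3 points).
#' @return Object of class `"efficiency_fit"`: list with `slope`,
#'   `intercept`, `efficiency` (percent; `NA` when the slope is
#'   non-negative), `r_squared`, and `in_range` (within `[90, 110]`).
#' @export
estimate_efficiency <- function(log10_inputs, cqs) {
  stopifnot(length(log10_inputs) == length(cqs), length(cqs) >= 3)
  d <- diff(log10_inputs)
  if (!(all(d > 0) || all(d < 0))) {
    stop("log10_inputs must be strictly increasing or decreasing")
  }
  fit <- stats::lm(cqs ~ log10_inputs)
  slope <- unname(stats::coef(fit)[2])
  eff <- if (slope < 0) (10^(-1 / slope) - 1) * 100 else NA_real_
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = eff,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    in_range = !is.na(eff) && eff >= 90 && eff <= 110
  ), class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, efficiency %s%% (%s 90-110%% window)\n",
              x$slope,
              if (is.na(x$efficiency)) "NA" else sprintf("%.1f", x$efficiency),
              if (isTRUE(x$in_range)) "inside" else "outside"))
  invisible(x)
}

#' Box-and-whisker summary statistics
#'
#' Median, quartiles (linear interpolation between order statistics, the
#' default `type = 7` convention), whiskers at the most extreme data points
#' within 1.5 x IQR of the quartiles, and the points beyond them as outliers.
#'
#' @param values Numeric vector (>= 1 value).
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_summary <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, !anyNA(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]),
       whisker_hi = max(values[inside]),
       outliers = values[!inside])
}

#' Score genotyping calls against known truth
#'
#' Joins per-sample calls to a truth table and reports the correct-call count
#' together with the one-sided exact binomial test against chance (50%).
#' Samples called `"repeat"` count as incorrect: a repeat is not a usable
#' prediction for the animal.
#'
#' @param result A `"cohort_result"` from [genotype_cohort()], or a data
#'   frame with `sample_id` and `call` columns.
#' @param truth Data frame with `sample_id` and `sex` (`"male"`/`"female"`).
#' @return List with `n`, `n_correct`, `accuracy` (fraction), and `binomial`
#'   (a `"binomial_result"`).
#' @export
score_calls <- function(result, truth) {
  calls <- if (inherits(result, "cohort_result")) result$samples else result
  stopifnot(all(c("sample_id", "call") %in% names(calls)),
            all(c("sample_id", "sex") %in% names(truth)))
  m <- merge(calls[, c("sample_id", "call")], truth[, c("sample_id", "sex")],
             by = "sample_id")
  if (nrow(m) == 0L) stop("no samples shared between calls and truth")
  n_correct <- sum(m$call == m$sex)
  list(n = nrow(m), n_correct = n_correct, accuracy = n_correct / nrow(m),
       binomial = exact_binomial_one_sided(n_correct, nrow(m), 0.5))
}
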