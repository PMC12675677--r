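#' Grade the agreement of two PWV methods
#'
#' Guideline grading of a device comparison from the bias and spread of the
#' paired differences: *excellent* if |bias| < 0.5 m/s and SD < 0.8 m/s,
#' *acceptable* if |bias| < 1.0 m/s and SD < 1.5 m/s, otherwise *poor*.
#' The bias is graded in absolute value (a negative bias of equal magnitude
#' is equally poor); boundary equality follows the strict `<` of the printed
#' criteria and falls to the next grade.
#'
#' @param bias mean of the paired differences, m/s.
#' @param sd_diff standard deviation of the differences, m/s (>= 0).
#' @return `"excellent"`, `"acceptable"` or `"poor"`.
#' @export
grade_agreement <- function(bias, sd_diff) {
  if (sd_diff < 0) cape_stop("sd_diff must be >= 0", "cape_input_error")
  if (abs(bias) < 0.5 && sd_diff < 0.8) "excellent"
  else if (abs(bias) < 1.0 && sd_diff < 1.5) "acceptable"
  else "poor"
}

#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `test - reference`, their mean (bias),
#' sample standard deviation (n-1 denominator, conventional for
#' Bland-Altman) and the 95% limits of agreement `bias +/- 1.96 * SD`, and
#' attaches the guideline grade.
#'
#' @param test,reference paired PWV series in m/s (equal length, n >= 2,
#'   all positive).
#' @return an object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `grade`, `differences`, `means`.
#' @export
bland_altman <- function(test, reference) {
  if (length(test) != length(reference))
    cape_stop("test and reference must have equal length", "cape_input_error")
  if (length(test) < 2)
    cape_stop("Bland-Altman needs at least 2 pairs", "cape_input_error")
  if (any(!is.finite(test)) || any(!is.finite(reference)) ||
      any(test <= 0) || any(reference <= 0))
    cape_stop("PWV values must be positive and finite", "cape_input_error")
  d <- test - reference
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff,
    loa_high = bias + 1.96 * sd_diff,
    n = length(d),
    grade = grade_agreement(bias, sd_diff),
    differences = d,
    means = (test + reference) / 2
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d: bias %.2f m/s, SD %.2f m/s, 95%% LoA [%.2f, %.2f] -> %s\n",
    x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high, x$grade))
  invisible(x)
}
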