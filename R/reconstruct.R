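#' Log hazard ratio and standard error from a reported confidence interval
#'
#' Recovers the log hazard ratio and its standard error from a hazard ratio
#' point estimate and a symmetric (on the log scale) confidence interval, the
#' standard indirect-estimation route for trials that report an HR with a CI
#' but no variance. The SE is the log-scale interval width divided by twice
#' the standard-normal quantile at `(1 + ci_level) / 2`.
#'
#' @param hr_point Hazard ratio point estimate (positive).
#' @param ci_low,ci_high Lower and upper confidence limits on the HR scale
#'   (positive, `ci_low < ci_high`).
#' @param ci_level Confidence level of the interval, default `0.95`.
#'
#' @return A tibble with columns `log_hr` and `se`. Inputs are vectorised and
#'   recycled to a common length.
#'
#' @examples
#' se_from_ci(0.48, 0.26, 0.88)
#' @export
se_from_ci <- function(hr_point, ci_low, ci_high, ci_level = 0.95) {
  n <- max(length(hr_point), length(ci_low), length(ci_high))
  hr_point <- rep_len(hr_point, n)
  ci_low <- rep_len(ci_low, n)
  ci_high <- rep_len(ci_high, n)
  ci_level <- rep_len(ci_level, n)
  if (any(!is.finite(hr_point) | hr_point <= 0)) {
    stop("`hr_point` must be positive and finite.", call. = FALSE)
  }
  if (any(!is.finite(ci_low) | ci_low <= 0 | !is.finite(ci_high) | ci_high <= 0)) {
    stop("confidence limits must be positive and finite.", call. = FALSE)
  }
  if (any(ci_low >= ci_high)) {
    stop("`ci_low` must be strictly below `ci_high` (degenerate or inverted interval).",
         call. = FALSE)
  }
  if (any(ci_level <= 0 | ci_level >= 1)) {
    stop("`ci_level` must lie in (0, 1).", call. = FALSE)
  }
  z <- stats::qnorm((1 + ci_level) / 2)
  tibble::tibble(
    log_hr = log(hr_point),
    se = (log(ci_high) - log(ci_low)) / (2 * z)
  )
}

#' Log hazard ratio and standard error from a log-rank p-value and events
#'
#' Indirect estimation of a log hazard ratio from a two-sided log-rank
#' p-value, the total number of events, and the randomisation split. The
#' observed-minus-expected variance is approximated by
#' `V = events_total * alloc_frac_a * (1 - alloc_frac_a)`, so that
#' `|log HR| = z / sqrt(V)` with `z` the standard-normal quantile at
#' `1 - p/2`, and `se = 1 / sqrt(V)`. The sign is taken from `direction`:
#' `"favours_b"` (the experimental arm) gives a negative log HR.
#'
#' @param p_two_sided Two-sided p-value in `(0, 1]`.
#' @param events_total Total observed events across both arms (>= 1).
#' @param alloc_frac_a Fraction of patients randomised to the comparator arm,
#'   in `(0, 1)`; `0.5` for 1:1 allocation.
#' @param direction `"favours_b"` or `"favours_a"`.
#'
#' @return A tibble with columns `log_hr` and `se`; vectorised.
#'
#' @examples
#' loghr_from_pvalue(0.05, 100, 0.5, "favours_b")
#' @export
loghr_from_pvalue <- function(p_two_sided, events_total, alloc_frac_a = 0.5,
                              direction = "favours_b") {
  n <- max(length(p_two_sided), length(events_total), length(alloc_frac_a),
           length(direction))
  p_two_sided <- rep_len(p_two_sided, n)
  events_total <- rep_len(events_total, n)
  alloc_frac_a <- rep_len(alloc_frac_a, n)
  direction <- rep_len(direction, n)
  if (any(!is.finite(p_two_sided) | p_two_sided <= 0 | p_two_sided > 1)) {
    stop("`p_two_sided` must lie in (0, 1]; p = 0 implies an infinite effect.",
         call. = FALSE)
  }
  if (any(!is.finite(events_total) | events_total < 1)) {
    stop("`events_total` must be a positive event count.", call. = FALSE)
  }
  if (any(alloc_frac_a <= 0 | alloc_frac_a >= 1)) {
    stop("`alloc_frac_a` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (!all(direction %in% c("favours_b", "favours_a"))) {
    stop("`direction` must be \"favours_b\" or \"favours_a\".", call. = FALSE)
  }
  V <- events_total * alloc_frac_a * (1 - alloc_frac_a)
  # upper-tail form avoids catastrophic cancellation for tiny p-values
  z <- stats::qnorm(p_two_sided / 2, lower.tail = FALSE)
  sgn <- ifelse(direction == "favours_b", -1, 1)
  tibble::tibble(log_hr = sgn * z / sqrt(V), se = 1 / sqrt(V))
}

#' Implied two-sided p-value of a log hazard ratio estimate
#'
#' The inverse of [loghr_from_pvalue()]: given a log HR and its SE, returns
#' the implied two-sided normal-test p-value and the implied information
#' `V = 1 / se^2`. Useful for round-trip checks and for degrading simulated
#' evidence to partially reported form.
#'
#' @param log_hr Log hazard ratio.
#' @param se Standard error (positive).
#' @return A tibble with columns `p_two_sided`, `V` and `direction`.
#' @export
implied_pvalue <- function(log_hr, se) {
  if (any(se <= 0)) stop("`se` must be positive.", call. = FALSE)
  tibble::tibble(
    p_two_sided = 2 * stats::pnorm(-abs(log_hr) / se),
    V = 1 / se^2,
    direction = ifelse(log_hr <= 0, "favours_b", "favours_a")
  )
}
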