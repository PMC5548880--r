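#' Decision thresholds for combined clinically meaningful benefit
#'
#' The decision rule flags a regimen when its posterior median HR is at or
#' below `hr_max` **and** its posterior probability of being better than the
#' reference is at or above `prob_min`, on both endpoints (OS and PFS).
#' Both inequalities are inclusive.
#'
#' @param hr_max Largest HR considered clinically meaningful (default 0.80).
#' @param prob_min Minimum posterior probability of beating the reference
#'   (default 0.95).
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(hr_max = 0.80, prob_min = 0.95) {
  stopifnot(hr_max > 0, prob_min > 0, prob_min < 1)
  structure(list(hr_max = hr_max, prob_min = prob_min),
            class = "decision_thresholds")
}

#' Posterior hazard ratio and credible interval versus the reference
#'
#' Exponentiated posterior median and equal-tailed credible limits of a
#' regimen's basic contrast. The reference regimen returns exactly
#' `(1, 1, 1)`; a regimen with no evidence for the endpoint returns `NA`s
#' (the "not estimable" cells of a summary table), not an error.
#'
#' @param fit An `nma_fit`.
#' @param regimen Regimen id.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param level Credible level, default 0.95.
#' @return A one-row tibble: `regimen`, `endpoint`, `hr_median`, `cri_low`,
#'   `cri_high`.
#' @export
hr_summary <- function(fit, regimen, endpoint, level = 0.95) {
  x <- contrast_draws(fit, regimen, endpoint)
  if (is.null(x)) {
    return(tibble::tibble(regimen = regimen, endpoint = endpoint,
                          hr_median = NA_real_, cri_low = NA_real_,
                          cri_high = NA_real_))
  }
  q <- stats::quantile(x, c(0.5, (1 - level) / 2, (1 + level) / 2),
                       names = FALSE)
  tibble::tibble(regimen = regimen, endpoint = endpoint,
                 hr_median = exp(q[1]), cri_low = exp(q[2]),
                 cri_high = exp(q[3]))
}

# draws matrix (pooled draws x regimens, id order) for one endpoint,
# reference included as a column of zeros
endpoint_draw_matrix <- function(fit, endpoint) {
  regs <- endpoint_regimens(fit, endpoint)
  if (length(regs) == 0) return(NULL)
  cols <- lapply(regs, function(r) contrast_draws(fit, r, endpoint))
  m <- do.call(cbind, cols)
  colnames(m) <- regs
  m
}

#' Posterior rank probabilities of the regimens for an endpoint
#'
#' In each posterior draw the regimens with evidence for the endpoint
#' (reference included) are ranked by their contrast — the lowest log HR is
#' rank 1, i.e. best. Entry `(j, k)` is the fraction of draws in which
#' regimen `j` attains rank `k`; every row and every column sums to 1. Exact
#' ties (measure-zero for continuous draws) are broken deterministically by
#' regimen id order.
#'
#' @inheritParams hr_summary
#' @return A `regimens x ranks` matrix of probabilities.
#' @export
rank_probabilities <- function(fit, endpoint) {
  m <- endpoint_draw_matrix(fit, endpoint)
  if (is.null(m) || ncol(m) < 2) {
    stop("need at least two regimens with ", endpoint, " draws", call. = FALSE)
  }
  a <- ncol(m)
  counts <- matrix(0L, a, a, dimnames = list(colnames(m), NULL))
  rk <- t(apply(m, 1, rank, ties.method = "first"))
  for (j in seq_len(a)) counts[j, ] <- tabulate(rk[, j], nbins = a)
  counts / nrow(m)
}

#' SUCRA: surface under the cumulative ranking curve
#'
#' `SUCRA_j = (1 / (a - 1)) * sum_{k=1}^{a-1} P(rank_j <= k)`: the average of
#' the cumulative probabilities of being ranked best, top two, top three and
#' so on. 1 means certainly best, 0 certainly worst; the mean across the `a`
#' regimens is always 1/2.
#'
#' @param rank_matrix A `regimens x ranks` probability matrix as returned by
#'   [rank_probabilities()].
#' @return Named numeric vector of SUCRA values in `[0, 1]`.
#' @export
sucra <- function(rank_matrix) {
  a <- ncol(rank_matrix)
  if (a < 2) stop("SUCRA is undefined for a single regimen", call. = FALSE)
  cum <- t(apply(rank_matrix, 1, cumsum))
  out <- rowSums(cum[, seq_len(a - 1), drop = FALSE]) / (a - 1)
  stats::setNames(as.numeric(out), rownames(rank_matrix))
}

#' Posterior probability a regimen is better than the reference
#'
#' Fraction of pooled posterior draws in which the regimen's contrast versus
#' the reference is negative (HR below 1). The reference itself has no such
#' probability and returns `NA` (a "not applicable" cell).
#'
#' @inheritParams hr_summary
#' @return Numeric scalar in `[0, 1]`, or `NA` for the reference or a
#'   regimen without draws for the endpoint.
#' @export
prob_better <- function(fit, regimen, endpoint) {
  if (identical(regimen, fit$network$reference)) return(NA_real_)
  x <- contrast_draws(fit, regimen, endpoint)
  if (is.null(x)) return(NA_real_)
  mean(x < 0)
}

#' Posterior probability each regimen is best
#'
#' Fraction of draws in which each regimen attains the minimum contrast
#' (best efficacy) for the endpoint; identical to the first column of
#' [rank_probabilities()] and sums to 1.
#'
#' @inheritParams hr_summary
#' @return Named numeric vector over the endpoint's regimens.
#' @export
prob_best <- function(fit, endpoint) {
  rp <- rank_probabilities(fit, endpoint)
  stats::setNames(rp[, 1], rownames(rp))
}

#' Combined clinically-meaningful-benefit flag for one regimen
#'
#' `TRUE` iff the posterior median HR is `<= hr_max` and the probability of
#' beating the reference is `>= prob_min` on *both* endpoints (inclusive
#' inequalities). If either endpoint is missing (`NA`), the flag is `FALSE`
#' and carries the attribute `not_evaluable = TRUE`.
#'
#' @param os_hr,os_prob Posterior median OS hazard ratio and probability
#'   better than reference.
#' @param pfs_hr,pfs_prob The same for PFS.
#' @param thresholds A [decision_thresholds()].
#' @return Logical scalar (with attribute `not_evaluable` when an endpoint is
#'   missing).
#' @examples
#' combined_benefit_flag(0.48, 0.99, 0.25, 1.00)  # TRUE
#' combined_benefit_flag(0.40, 0.91, 0.18, 1.00)  # FALSE: OS prob < 0.95
#' @export
combined_benefit_flag <- function(os_hr, os_prob, pfs_hr, pfs_prob,
                                  thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  vals <- c(os_hr, os_prob, pfs_hr, pfs_prob)
  if (anyNA(vals) || length(vals) != 4) {
    return(structure(FALSE, not_evaluable = TRUE))
  }
  os_hr <= thresholds$hr_max && os_prob >= thresholds$prob_min &&
    pfs_hr <= thresholds$hr_max && pfs_prob >= thresholds$prob_min
}

#' League table of all pairwise posterior hazard ratios
#'
#' Square matrices of posterior-median HRs and credible limits for every
#' ordered regimen pair: entry `(x, y)` summarizes the contrast of `y`
#' versus `x`. The diagonal is 1 and the point estimates satisfy
#' `entry(x, y) = 1 / entry(y, x)` exactly (the median is equivariant under
#' monotone transformation and sign flip).
#'
#' @inheritParams hr_summary
#' @return A list of class `league_table` with matrices `hr`, `cri_low`,
#'   `cri_high` (rows `x`, columns `y`).
#' @export
league_table <- function(fit, endpoint, level = 0.95) {
  m <- endpoint_draw_matrix(fit, endpoint)
  if (is.null(m) || ncol(m) < 2) {
    stop("need at least two regimens with ", endpoint, " draws", call. = FALSE)
  }
  regs <- colnames(m)
  a <- length(regs)
  hr <- lo <- hi <- matrix(NA_real_, a, a, dimnames = list(regs, regs))
  probs <- c(0.5, (1 - level) / 2, (1 + level) / 2)
  for (x in seq_len(a)) {
    for (y in seq_len(a)) {
      if (x == y) { hr[x, y] <- lo[x, y] <- hi[x, y] <- 1; next }
      if (y < x) {
        hr[x, y] <- 1 / hr[y, x]
        lo[x, y] <- 1 / hi[y, x]
        hi[x, y] <- 1 / lo[y, x]
        next
      }
      q <- stats::quantile(m[, y] - m[, x], probs, names = FALSE)
      hr[x, y] <- exp(q[1]); lo[x, y] <- exp(q[2]); hi[x, y] <- exp(q[3])
    }
  }
  structure(list(hr = hr, cri_low = lo, cri_high = hi, endpoint = endpoint,
                 level = level),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  cat("<league_table> ", x$endpoint, ", ", format(100 * x$level),
      "% CrI; entry (row, col) = HR of col vs row\n", sep = "")
  a <- nrow(x$hr)
  txt <- matrix("", a, a, dimnames = dimnames(x$hr))
  for (i in seq_len(a)) for (j in seq_len(a)) {
    txt[i, j] <- if (i == j) "1" else
      sprintf("%.*f (%.*f-%.*f)", digits, x$hr[i, j], digits, x$cri_low[i, j],
              digits, x$cri_high[i, j])
  }
  print(txt, quote = FALSE)
  invisible(x)
}

#' Full posterior summary table for a fitted network
#'
#' One row per (regimen, endpoint): posterior median HR with equal-tailed
#' CrI, SUCRA, probability best, and probability better than the reference.
#' Regimens lacking evidence for an endpoint appear with `NA`s and are
#' excluded from that endpoint's ranking. Also computes the combined
#' clinically-meaningful-benefit flag per regimen when both endpoints are
#' present (stored in the `"benefit"` attribute and shown by
#' [combined_benefit()]).
#'
#' @param fit An `nma_fit`.
#' @param level Credible level, default 0.95.
#' @param thresholds A [decision_thresholds()].
#' @return A tibble sorted by endpoint and descending SUCRA.
#' @export
summarize_nma <- function(fit, level = 0.95,
                          thresholds = decision_thresholds()) {
  stopifnot(inherits(fit, "nma_fit"))
  all_regs <- fit$network$regimens
  rows <- list()
  for (ep in fit$frame$endpoints) {
    regs_ep <- endpoint_regimens(fit, ep)
    su <- pb <- NULL
    if (length(regs_ep) >= 2) {
      rp <- rank_probabilities(fit, ep)
      su <- sucra(rp)
      pb <- prob_best(fit, ep)
    }
    for (r in all_regs) {
      hs <- hr_summary(fit, r, ep, level)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        hs,
        sucra = if (r %in% names(su)) unname(su[r]) else NA_real_,
        prob_best = if (r %in% names(pb)) unname(pb[r]) else NA_real_,
        prob_better_ref = prob_better(fit, r, ep)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$endpoint, dplyr::desc(.data$sucra))
  attr(out, "benefit") <- benefit_table(out, thresholds)
  attr(out, "thresholds") <- thresholds
  out
}

benefit_table <- function(summary_tbl, thresholds) {
  wide <- tidyr::pivot_wider(
    dplyr::select(summary_tbl, "regimen", "endpoint", "hr_median",
                  "prob_better_ref"),
    names_from = "endpoint",
    values_from = c("hr_median", "prob_better_ref")
  )
  for (col in c("hr_median_OS", "prob_better_ref_OS", "hr_median_PFS",
                "prob_better_ref_PFS")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  flags <- purrr::pmap(
    list(wide$hr_median_OS, wide$prob_better_ref_OS,
         wide$hr_median_PFS, wide$prob_better_ref_PFS),
    function(oh, op, ph, pp) combined_benefit_flag(oh, op, ph, pp, thresholds)
  )
  wide$combined_benefit <- vapply(flags, as.logical, logical(1))
  wide$evaluable <- !vapply(flags, function(f)
    isTRUE(attr(f, "not_evaluable")), logical(1))
  wide
}

#' Combined-benefit decision table
#'
#' Applies the [decision_thresholds()] rule to a fitted network (or to a
#' summary tibble from [summarize_nma()]): a regimen is flagged when HR
#' `<= hr_max` and probability better than reference `>= prob_min` hold on
#' both OS and PFS. Regimens missing an endpoint are marked not evaluable
#' and never flagged.
#'
#' @param x An `nma_fit` or the tibble returned by [summarize_nma()].
#' @param thresholds A [decision_thresholds()].
#' @return A tibble with per-regimen OS/PFS medians and probabilities,
#'   `combined_benefit`, and `evaluable`.
#' @export
combined_benefit <- function(x, thresholds = decision_thresholds()) {
  if (inherits(x, "nma_fit")) x <- summarize_nma(x, thresholds = thresholds)
  benefit_table(x, thresholds)
}

#' @rdname summarize_nma
#' @param x An `nma_fit`.
#' @param ... Passed to [summarize_nma()].
#' @export
tidy.nma_fit <- function(x, ...) summarize_nma(x, ...)

#' One-row fit overview
#'
#' @param x An `nma_fit`.
#' @param ... Unused.
#' @return A tibble with network size, draw counts, worst split R-hat,
#'   smallest bulk ESS, and the convergence flag.
#' @export
glance.nma_fit <- function(x, ...) {
  dg <- x$diagnostics
  finite <- dg$rhat[is.finite(dg$rhat)]
  tibble::tibble(
    n_regimens = length(x$network$regimens),
    n_studies = length(unique(x$network$estimates$study_id)),
    n_estimates = nrow(x$frame$est),
    n_chains = x$sampler$n_chains,
    n_draws = x$sampler$n_chains * x$sampler$n_samples,
    max_rhat = if (length(finite)) max(finite) else NA_real_,
    min_ess_bulk = min(dg$ess_bulk, na.rm = TRUE),
    converged = isTRUE(attr(dg, "converged"))
  )
}
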