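#' Simulate an evidence network from the model's own generative process
#'
#' Generates a connected network of randomised-trial contrasts the way the
#' hierarchical model assumes they arise: a spanning tree of contrasts first
#' (so every regimen is reachable from the reference), extra study contrasts
#' at random; per study and endpoint a study-specific effect is drawn around
#' the true contrast with between-study SD `tau_true`; event counts are
#' uniform on `events_range`, the within-study variance is `v = 4 /
#' n_events` (1:1 allocation, so `se = 1 / sqrt(V)` with `V = events / 4`);
#' and observed log HRs are drawn jointly multivariate normal around the
#' study effects with correlation `rho_true` for studies reporting both
#' endpoints. Spanning-tree studies always report both endpoints, which
#' keeps each endpoint's sub-network connected; the remaining studies report
#' OS only, PFS only, or both according to `endpoint_probs`.
#'
#' A fraction `degrade_fraction` of rows is emitted in partially reported
#' form — a two-sided p-value with total events and 1:1 allocation instead
#' of an HR with CI — and re-enters the returned network through
#' [loghr_from_pvalue()], exactly as real degraded evidence would.
#'
#' @param n_regimens Number of regimens including the reference (>= 2).
#' @param n_studies Number of studies (>= `n_regimens - 1` so a spanning
#'   tree exists).
#' @param true_d Named list with elements `OS` and `PFS`, each a named
#'   vector of true basic contrasts (log-HR scale) for the non-reference
#'   regimens `trt1, trt2, ...`; `NULL` uses the default pattern
#'   `-0.3, 0.1, -0.5, 0.2, -0.1, ...` on both endpoints.
#' @param tau_true Named vector `c(OS = , PFS = )` of true between-study
#'   SDs.
#' @param rho_true True within-study correlation of paired OS/PFS estimates,
#'   in `[0, 1)`.
#' @param events_range Integer range (length 2, lower bound >= 10) for the
#'   per-estimate event counts.
#' @param endpoint_probs Probabilities for non-tree studies to report
#'   `c(os_only, pfs_only, both)`; must sum to 1.
#' @param degrade_fraction Fraction of rows reported only as p-value +
#'   events, in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A list with elements `network` (an `hr_network`), `truth` (the
#'   latent record: per-row study effects, true variances, `true_d`,
#'   `tau_true`, `rho_true`), and `evidence` (the network in the ingest
#'   column layout, degraded rows included, ready for [write_evidence()]-style
#'   round trips via `readr::write_csv()` and [read_evidence()]).
#' @examples
#' sim <- simulate_network(n_regimens = 3, n_studies = 5, seed = 7)
#' sim$network
#' @export
simulate_network <- function(n_regimens = 4, n_studies = 12, true_d = NULL,
                             tau_true = c(OS = 0.15, PFS = 0.15),
                             rho_true = 0.5, events_range = c(50L, 300L),
                             endpoint_probs = c(os_only = 0.15,
                                                pfs_only = 0.15, both = 0.7),
                             degrade_fraction = 0, seed = 1) {
  stopifnot(n_regimens >= 2, rho_true >= 0, rho_true < 1,
            length(events_range) == 2, events_range[1] >= 10,
            events_range[1] <= events_range[2],
            degrade_fraction >= 0, degrade_fraction <= 1,
            abs(sum(endpoint_probs) - 1) < 1e-8)
  if (n_studies < n_regimens - 1) {
    stop("need at least ", n_regimens - 1, " studies to connect ", n_regimens,
         " regimens (spanning tree)", call. = FALSE)
  }
  reference <- "chemo"
  others <- paste0("trt", seq_len(n_regimens - 1))
  regimens <- c(reference, others)
  if (is.null(true_d)) {
    base <- rep_len(c(-0.3, 0.1, -0.5, 0.2, -0.1), n_regimens - 1)
    names(base) <- others
    true_d <- list(OS = base, PFS = base)
  }
  for (ep in c("OS", "PFS")) {
    if (!setequal(names(true_d[[ep]]), others)) {
      stop("`true_d$", ep, "` must name exactly: ",
           paste(others, collapse = ", "), call. = FALSE)
    }
  }
  d_of <- function(r, ep) if (r == reference) 0 else unname(true_d[[ep]][r])

  set.seed(seed)
  # contrasts: spanning tree then random extras
  contrasts <- matrix(NA_character_, n_studies, 2)
  for (j in seq_len(n_regimens - 1)) {
    earlier <- regimens[seq_len(j)]
    contrasts[j, ] <- c(sample(earlier, 1), others[j])
  }
  if (n_studies >= n_regimens) {
    for (j in n_regimens:n_studies) {
      contrasts[j, ] <- sample(regimens, 2)
    }
  }
  study_eps <- character(n_studies)
  study_eps[seq_len(n_regimens - 1)] <- "both"
  if (n_studies >= n_regimens) {
    study_eps[n_regimens:n_studies] <-
      sample(c("os_only", "pfs_only", "both"),
             n_studies - n_regimens + 1, replace = TRUE,
             prob = endpoint_probs)
  }

  rows <- list()
  for (j in seq_len(n_studies)) {
    a <- contrasts[j, 1]; b <- contrasts[j, 2]
    eps <- switch(study_eps[j], os_only = "OS", pfs_only = "PFS",
                  both = c("OS", "PFS"))
    ev_pool <- seq(events_range[1], events_range[2])
    n_ev <- ev_pool[sample.int(length(ev_pool), length(eps), replace = TRUE)]
    v <- 4 / n_ev
    delta <- vapply(seq_along(eps), function(k) {
      stats::rnorm(1, d_of(b, eps[k]) - d_of(a, eps[k]), tau_true[eps[k]])
    }, 0)
    if (length(eps) == 2) {
      z <- stats::rnorm(2)
      e1 <- sqrt(v[1]) * z[1]
      e2 <- sqrt(v[2]) * (rho_true * z[1] + sqrt(1 - rho_true^2) * z[2])
      y <- delta + c(e1, e2)
    } else {
      y <- delta + stats::rnorm(1, 0, sqrt(v))
    }
    rows[[j]] <- tibble::tibble(
      study_id = sprintf("study_%02d", j), regimen_a = a, regimen_b = b,
      endpoint = eps, y = y, v = v, n_events = as.integer(n_ev), delta = delta
    )
  }
  truth_tbl <- dplyr::bind_rows(rows)

  n_rows <- nrow(truth_tbl)
  n_degrade <- round(degrade_fraction * n_rows)
  degraded <- rep(FALSE, n_rows)
  if (n_degrade > 0) degraded[sample.int(n_rows, n_degrade)] <- TRUE

  z975 <- stats::qnorm(0.975)
  se <- sqrt(truth_tbl$v)
  evidence <- tibble::tibble(
    study_id = truth_tbl$study_id, subgroup = "simulated",
    regimen_a = truth_tbl$regimen_a, regimen_b = truth_tbl$regimen_b,
    endpoint = truth_tbl$endpoint,
    hr = ifelse(degraded, NA_real_, exp(truth_tbl$y)),
    ci_low = ifelse(degraded, NA_real_, exp(truth_tbl$y - z975 * se)),
    ci_high = ifelse(degraded, NA_real_, exp(truth_tbl$y + z975 * se)),
    p_value = ifelse(degraded, 2 * stats::pnorm(-abs(truth_tbl$y) / se),
                     NA_real_),
    events_total = ifelse(degraded, truth_tbl$n_events, NA_real_),
    alloc_frac_a = ifelse(degraded, 0.5, NA_real_),
    direction = ifelse(degraded,
                       ifelse(truth_tbl$y <= 0, "favours_b", "favours_a"),
                       NA_character_),
    n_events = truth_tbl$n_events
  )

  # build the estimates the way ingest would see them
  est <- tibble::tibble(
    study_id = truth_tbl$study_id, subgroup = "simulated",
    regimen_a = truth_tbl$regimen_a, regimen_b = truth_tbl$regimen_b,
    endpoint = truth_tbl$endpoint,
    log_hr = truth_tbl$y, se = se, n_events = truth_tbl$n_events,
    provenance = ifelse(degraded, "reconstructed", "reported")
  )
  if (any(degraded)) {
    rec <- loghr_from_pvalue(evidence$p_value[degraded],
                             evidence$events_total[degraded], 0.5,
                             evidence$direction[degraded])
    est$log_hr[degraded] <- rec$log_hr
    est$se[degraded] <- rec$se
  }
  network <- build_network(est, reference = reference, subgroup = "simulated")
  list(
    network = network,
    truth = list(estimates = truth_tbl, true_d = true_d, tau_true = tau_true,
                 rho_true = rho_true, reference = reference,
                 degraded = degraded),
    evidence = evidence
  )
}

#' Deterministic fixture networks
#'
#' Four small evidence structures used throughout the tests and examples:
#'
#' * `pair` — two regimens, one OS study.
#' * `triangle` — three regimens in a closed OS loop (direct and indirect
#'   evidence for every contrast).
#' * `two_endpoint` — four regimens, twelve studies, both endpoints, with
#'   within-study OS-PFS correlation 0.6, generated by [simulate_network()]
#'   at a fixed seed.
#' * `disconnected` — a pathological two-component estimate table (as a
#'   plain tibble with a `reference` attribute); [build_network()] rejects
#'   it.
#'
#' @return A named list of three `hr_network` objects and one estimates
#'   tibble.
#' @examples
#' names(fixture_suite())
#' @export
fixture_suite <- function() {
  pair_est <- tibble::tibble(
    study_id = "study_01", regimen_a = "chemo", regimen_b = "trt1",
    endpoint = "OS", log_hr = -0.5, se = 0.2, n_events = 100L,
    provenance = "reported"
  )
  tri_est <- tibble::tibble(
    study_id = c("study_01", "study_02", "study_03"),
    regimen_a = c("chemo", "chemo", "trtA"),
    regimen_b = c("trtA", "trtB", "trtB"),
    endpoint = "OS",
    log_hr = c(-0.40, -0.10, 0.25),
    se = c(0.2, 0.2, sqrt(0.08)),
    n_events = c(100L, 100L, 50L),
    provenance = "reported"
  )
  disc_est <- tibble::tibble(
    study_id = c("study_01", "study_02"),
    regimen_a = c("chemo", "trt2"),
    regimen_b = c("trt1", "trt3"),
    endpoint = "OS",
    log_hr = c(-0.3, -0.2), se = c(0.2, 0.2), n_events = c(80L, 80L),
    provenance = "reported"
  )
  attr(disc_est, "reference") <- "chemo"
  list(
    pair = build_network(pair_est, reference = "chemo"),
    triangle = build_network(tri_est, reference = "chemo"),
    two_endpoint = simulate_network(n_regimens = 4, n_studies = 12,
                                    rho_true = 0.6, seed = 42)$network,
    disconnected = disc_est
  )
}
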