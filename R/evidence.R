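#' Read a study-level hazard-ratio evidence table
#'
#' Reads a delimited evidence file with one row per (study, treatment
#' contrast, endpoint) and returns a tibble of contrast estimates on the log
#' hazard-ratio scale. Rows reporting an HR with a confidence interval are
#' converted through [se_from_ci()]; rows reporting only a log-rank p-value
#' with event counts are reconstructed through [loghr_from_pvalue()]. The
#' `provenance` column records which route produced each estimate.
#'
#' The canonical columns are `study_id`, `subgroup`, `regimen_a`,
#' `regimen_b`, `endpoint` (`"OS"` or `"PFS"`), `hr`, `ci_low`, `ci_high`,
#' `p_value`, `events_total`, `alloc_frac_a`, `n_events`, and optionally
#' `direction` (`"favours_b"`/`"favours_a"`) for p-value-only rows. Blank
#' cells are allowed wherever the alternative statistic set is supplied.
#' By convention `log_hr < 0` favours `regimen_b` (the experimental
#' regimen); files oriented the other way are flipped via
#' `orientation = "a_vs_b"`.
#'
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(study_id = "trial")`.
#' @param orientation `"b_vs_a"` (default; HR reported for b relative to a)
#'   or `"a_vs_b"` (sign of the log HR is flipped on ingest).
#'
#' @return A tibble with columns `study_id`, `subgroup`, `regimen_a`,
#'   `regimen_b`, `endpoint`, `log_hr`, `se`, `n_events`, `provenance`.
#' @seealso [build_network()], [subgroup_networks()], [write_evidence()]
#' @export
read_evidence <- function(path, schema = NULL, orientation = c("b_vs_a", "a_vs_b")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("evidence file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop("schema maps `", canon, "` to missing column `", schema[[canon]], "`",
             call. = FALSE)
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  required <- c("study_id", "regimen_a", "regimen_b", "endpoint", "n_events")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("evidence file is missing required column(s): ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  has_ci_cols <- all(c("hr", "ci_low", "ci_high") %in% names(raw))
  has_p_cols <- all(c("p_value", "events_total") %in% names(raw))
  if (!has_ci_cols && !has_p_cols) {
    stop("evidence file must carry either `hr`/`ci_low`/`ci_high` or ",
         "`p_value`/`events_total` columns", call. = FALSE)
  }
  for (opt in c("hr", "ci_low", "ci_high", "p_value", "events_total",
                "alloc_frac_a")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA_real_
  }
  if (!"direction" %in% names(raw)) raw$direction <- NA_character_
  if (!"subgroup" %in% names(raw)) raw$subgroup <- NA_character_

  if (nrow(raw) == 0) return(empty_estimates())

  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    ci_route <- !is.na(row$hr) && !is.na(row$ci_low) && !is.na(row$ci_high)
    p_route <- !is.na(row$p_value)
    if (ci_route) {
      if (any(c(row$hr, row$ci_low, row$ci_high) <= 0)) {
        stop("row ", i, ": hazard ratio and confidence limits must be positive",
             call. = FALSE)
      }
      if (row$ci_low >= row$ci_high) {
        stop("row ", i, ": degenerate or inverted confidence interval (",
             row$ci_low, ", ", row$ci_high, ")", call. = FALSE)
      }
      est <- se_from_ci(row$hr, row$ci_low, row$ci_high)
      provenance <- "reported"
    } else if (p_route) {
      direction <- row$direction
      if (is.na(direction)) {
        if (is.na(row$hr) || row$hr == 1) {
          stop("row ", i, ": p-value row needs a `direction` or a non-unit `hr` ",
               "point estimate to fix the sign", call. = FALSE)
        }
        direction <- if (row$hr < 1) "favours_b" else "favours_a"
      }
      alloc <- if (is.na(row$alloc_frac_a)) 0.5 else row$alloc_frac_a
      est <- loghr_from_pvalue(row$p_value, row$events_total, alloc, direction)
      provenance <- "reconstructed"
    } else {
      stop("row ", i, ": neither an HR with CI nor a p-value with events is supplied",
           call. = FALSE)
    }
    out[[i]] <- tibble::tibble(
      study_id = as.character(row$study_id),
      subgroup = as.character(row$subgroup),
      regimen_a = as.character(row$regimen_a),
      regimen_b = as.character(row$regimen_b),
      endpoint = as.character(row$endpoint),
      log_hr = est$log_hr,
      se = est$se,
      n_events = as.integer(row$n_events),
      provenance = provenance
    )
  }
  estimates <- dplyr::bind_rows(out)
  if (orientation == "a_vs_b") estimates$log_hr <- -estimates$log_hr
  validate_estimates(estimates)
  estimates
}

#' Write contrast estimates back to the ingest format
#'
#' Serialises estimates (or a whole network) as a comma-separated file that
#' [read_evidence()] reads back; log HRs are written as exact HR/CI triples
#' so the round trip preserves `log_hr` and `se` to full precision.
#'
#' @param x A tibble of contrast estimates or an `hr_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(x, path) {
  estimates <- if (inherits(x, "hr_network")) x$estimates else x
  validate_estimates(estimates)
  z <- stats::qnorm(0.975)
  tab <- tibble::tibble(
    study_id = estimates$study_id,
    subgroup = estimates$subgroup,
    regimen_a = estimates$regimen_a,
    regimen_b = estimates$regimen_b,
    endpoint = estimates$endpoint,
    hr = exp(estimates$log_hr),
    ci_low = exp(estimates$log_hr - z * estimates$se),
    ci_high = exp(estimates$log_hr + z * estimates$se),
    p_value = NA_real_,
    events_total = NA_real_,
    alloc_frac_a = NA_real_,
    direction = NA_character_,
    n_events = estimates$n_events
  )
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

empty_estimates <- function() {
  tibble::tibble(
    study_id = character(), subgroup = character(),
    regimen_a = character(), regimen_b = character(),
    endpoint = character(), log_hr = double(), se = double(),
    n_events = integer(), provenance = character()
  )
}

validate_estimates <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  needed <- c("study_id", "regimen_a", "regimen_b", "endpoint", "log_hr",
              "se", "n_events")
  missing_cols <- setdiff(needed, names(estimates))
  if (length(missing_cols)) {
    stop("estimates are missing column(s): ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  if (nrow(estimates) == 0) return(invisible(estimates))
  if (!all(estimates$endpoint %in% c("OS", "PFS"))) {
    stop("`endpoint` must be \"OS\" or \"PFS\"", call. = FALSE)
  }
  if (any(!is.finite(estimates$se) | estimates$se <= 0)) {
    stop("all standard errors must be positive and finite", call. = FALSE)
  }
  if (any(is.na(estimates$n_events) | estimates$n_events < 1)) {
    stop("`n_events` must be a positive event count on every row", call. = FALSE)
  }
  if (any(estimates$regimen_a == estimates$regimen_b)) {
    stop("a contrast must compare two distinct regimens", call. = FALSE)
  }
  key <- paste(estimates$study_id, estimates$regimen_a, estimates$regimen_b,
               estimates$endpoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- estimates[duplicated(key), ]
    stop("duplicate (study, contrast, endpoint) row(s): ",
         paste(dup$study_id, paste(dup$regimen_b, "vs", dup$regimen_a),
               dup$endpoint, collapse = "; "), call. = FALSE)
  }
  invisible(estimates)
}

#' Assemble and validate an evidence network
#'
#' Builds an `hr_network` from contrast estimates: infers the regimen set,
#' checks that the designated reference regimen appears, and verifies that
#' the contrast graph (regimens as nodes, estimates as edges, pooled over
#' endpoints) is connected. Trials with no path of common comparators to the
#' rest of the evidence cannot be synthesised and trigger an error listing
#' the disconnected components.
#'
#' @param estimates Tibble of contrast estimates as returned by
#'   [read_evidence()] (columns `study_id`, `regimen_a`, `regimen_b`,
#'   `endpoint`, `log_hr`, `se`, `n_events`; `subgroup`/`provenance`
#'   optional).
#' @param reference Regimen id used as the anchor of all basic contrasts
#'   (e.g. chemotherapy with no maintenance).
#' @param subgroup Optional subgroup label for the network.
#' @return An object of class `hr_network`: a list with elements
#'   `estimates`, `regimens`, `reference`, `subgroup`.
#' @examples
#' est <- fixture_suite()$triangle$estimates
#' net <- build_network(est, reference = "chemo")
#' net
#' @export
build_network <- function(estimates, reference, subgroup = NULL) {
  if (!"provenance" %in% names(estimates)) estimates$provenance <- "reported"
  if (!"subgroup" %in% names(estimates)) estimates$subgroup <- NA_character_
  validate_estimates(estimates)
  if (nrow(estimates) == 0) stop("no estimates supplied", call. = FALSE)
  regimens <- sort(unique(c(estimates$regimen_a, estimates$regimen_b)))
  if (!reference %in% regimens) {
    stop("reference regimen `", reference, "` appears in no estimate",
         call. = FALSE)
  }
  comps <- graph_components(estimates$regimen_a, estimates$regimen_b, regimens)
  if (length(comps) > 1) {
    ref_comp <- which(vapply(comps, function(cc) reference %in% cc, logical(1)))
    others <- comps[-ref_comp]
    stop("evidence network is disconnected; no common comparator links ",
         "component(s): ",
         paste(vapply(others, function(cc) paste0("{", paste(cc, collapse = ", "), "}"),
                      character(1)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(subgroup)) {
    sg <- unique(estimates$subgroup[!is.na(estimates$subgroup)])
    subgroup <- if (length(sg) == 1) sg else NA_character_
  }
  structure(
    list(estimates = estimates, regimens = regimens, reference = reference,
         subgroup = subgroup),
    class = "hr_network"
  )
}

# connected components of the contrast graph, as a list of node-name vectors
graph_components <- function(from, to, nodes) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' Split pooled evidence into one independent network per subgroup
#'
#' Evidence rows are grouped by their `subgroup` label and each group is
#' validated into its own network; subgroups are analysed independently and
#' never share estimates. Subgroups whose graph is disconnected or lacks the
#' reference are reported as unbuildable (with a warning) while the valid
#' networks are still returned.
#'
#' @inheritParams build_network
#' @return A named list of `hr_network` objects, one per buildable subgroup,
#'   with an attribute `"unbuildable"` — a named character vector of failure
#'   messages for the rest.
#' @export
subgroup_networks <- function(estimates, reference) {
  if (nrow(estimates) == 0) {
    out <- list()
    attr(out, "unbuildable") <- character(0)
    return(out)
  }
  if (any(is.na(estimates$subgroup))) {
    stop("every estimate needs a `subgroup` label", call. = FALSE)
  }
  groups <- split(estimates, estimates$subgroup)
  nets <- list()
  failures <- character(0)
  for (sg in names(groups)) {
    res <- tryCatch(build_network(groups[[sg]], reference, subgroup = sg),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "hr_network")) nets[[sg]] <- res
    else failures[[sg]] <- res
  }
  if (length(failures)) {
    warning("subgroup(s) could not be built: ",
            paste(names(failures), collapse = ", "), call. = FALSE)
  }
  attr(nets, "unbuildable") <- failures
  nets
}

#' Endpoint-specific sub-network connected to the reference
#'
#' A regimen can contribute evidence for one endpoint only (a trial may
#' report PFS but not OS), so the contrast graph restricted to one endpoint
#' can be smaller than the full network. This returns the estimates of the
#' requested endpoint lying in the connected component that contains the
#' reference, together with the regimens reachable there. Estimates outside
#' that component are dropped with a warning; such regimens are simply not
#' estimable for this endpoint.
#'
#' @param network An `hr_network`.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A list with `estimates` (tibble) and `regimens` (character).
#' @export
endpoint_subnetwork <- function(network, endpoint) {
  stopifnot(inherits(network, "hr_network"))
  est <- network$estimates[network$estimates$endpoint == endpoint, ]
  if (nrow(est) == 0) {
    return(list(estimates = est, regimens = character(0)))
  }
  nodes <- sort(unique(c(est$regimen_a, est$regimen_b)))
  comps <- graph_components(est$regimen_a, est$regimen_b, nodes)
  ref_comp <- which(vapply(comps, function(cc) network$reference %in% cc,
                           logical(1)))
  if (length(ref_comp) == 0) {
    warning("reference regimen has no ", endpoint, " evidence; endpoint skipped",
            call. = FALSE)
    return(list(estimates = est[0, ], regimens = character(0)))
  }
  keep <- comps[[ref_comp]]
  drop <- est$regimen_a %in% keep & est$regimen_b %in% keep
  if (!all(drop)) {
    warning(sum(!drop), " ", endpoint, " estimate(s) disconnected from the ",
            "reference were dropped for this endpoint", call. = FALSE)
  }
  list(estimates = est[drop, ], regimens = sort(keep))
}

#' @export
print.hr_network <- function(x, ...) {
  n_study <- length(unique(x$estimates$study_id))
  cat("<hr_network>", if (!is.na(x$subgroup)) paste0("subgroup: ", x$subgroup),
      "\n")
  cat("  regimens: ", length(x$regimens), " (reference: ", x$reference, ")\n",
      sep = "")
  cat("  studies:  ", n_study, ", estimates: ", nrow(x$estimates), "\n", sep = "")
  for (ep in c("OS", "PFS")) {
    k <- sum(x$estimates$endpoint == ep)
    if (k > 0) cat("  ", ep, ": ", k, " estimate(s)\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network into its estimate table
#' @param x An `hr_network`.
#' @param ... Unused.
#' @return The tibble of contrast estimates.
#' @export
tidy.hr_network <- function(x, ...) x$estimates
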