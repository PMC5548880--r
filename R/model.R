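#' Model configuration: priors for the hierarchical hazard-ratio NMA
#'
#' Collects every prior hyperparameter of the model. Defaults encode:
#'
#' * a uniform prior on each endpoint's between-study SD `tau` on
#'   `(0, tau_upper)` with `tau_upper = log(2) / qnorm(0.975)` (about 0.354),
#'   calibrated so that at the upper endpoint 95% of study-specific relative
#'   efficacies lie within a factor of two of the mean contrast;
#' * vague `Normal(0, effect_prior_sd^2)` priors on the basic contrasts
#'   (log-HR scale, SD 10);
#' * inverse-gamma priors on within-study variances with mean pinned to the
#'   study's reported variance and concentration growing with the number of
#'   events (`ig_mode = "inverse_events"`: `alpha = 2 + ig_strength * n_events`,
#'   so better-reported studies get tighter priors); the alternative reading
#'   `"literal_events"` (`alpha = 2 + ig_strength / n_events`) is available;
#' * a uniform prior on the shared within-study correlation `rho` on
#'   `(rho_lower, rho_upper)`, default `(0, 0.95)`.
#'
#' @param tau_upper Upper bound of the uniform prior on the between-study SD.
#' @param effect_prior_sd Prior SD of the basic contrasts (log-HR scale).
#' @param ig_mode `"inverse_events"` or `"literal_events"`; how the
#'   inverse-gamma concentration depends on the event count.
#' @param ig_strength Positive multiplier on the event count in the
#'   inverse-gamma concentration.
#' @param rho_lower,rho_upper Support of the uniform prior on the
#'   within-study correlation; `0 <= rho_lower < rho_upper < 1`.
#' @return An object of class `nma_config`.
#' @export
nma_config <- function(tau_upper = log(2) / stats::qnorm(0.975),
                       effect_prior_sd = 10,
                       ig_mode = c("inverse_events", "literal_events"),
                       ig_strength = 1,
                       rho_lower = 0,
                       rho_upper = 0.95) {
  ig_mode <- match.arg(ig_mode)
  stopifnot(tau_upper > 0, effect_prior_sd > 0, ig_strength > 0,
            rho_lower >= 0, rho_lower < rho_upper, rho_upper < 1)
  structure(
    list(tau_upper = tau_upper, effect_prior_sd = effect_prior_sd,
         ig_mode = ig_mode, ig_strength = ig_strength,
         rho_lower = rho_lower, rho_upper = rho_upper),
    class = "nma_config"
  )
}

#' Inverse-gamma hyperparameters for a within-study variance prior
#'
#' Given a study's reported log-HR variance and event count, returns the
#' `(alpha, beta)` of an inverse-gamma prior whose mean equals the reported
#' variance (`beta / (alpha - 1) = v_reported` by construction) and whose
#' concentration is governed by the event count according to the configured
#' mode.
#'
#' @param v_reported Reported variance of the log HR (`se^2`), positive.
#' @param n_events Number of events behind the estimate (>= 1).
#' @param config An [nma_config()].
#' @return A tibble with columns `alpha` and `beta`; vectorised over inputs.
#' @examples
#' ig_hyperparams(0.04, 100, nma_config())
#' @export
ig_hyperparams <- function(v_reported, n_events, config = nma_config()) {
  stopifnot(inherits(config, "nma_config"))
  if (any(v_reported <= 0)) stop("`v_reported` must be positive", call. = FALSE)
  if (any(n_events < 1)) stop("`n_events` must be >= 1", call. = FALSE)
  alpha <- switch(config$ig_mode,
    inverse_events = 2 + config$ig_strength * n_events,
    literal_events = 2 + config$ig_strength / n_events
  )
  tibble::tibble(alpha = alpha, beta = v_reported * (alpha - 1))
}

# Internal: resolve a network + config into aligned model arrays.
#
# Estimates are restricted, per endpoint, to the component connected to the
# reference; each usable estimate gets integer indices into the basic
# contrast vector d (0 = reference), a study index, and inverse-gamma
# hyperparameters. d is laid out as one entry per (non-reference regimen,
# endpoint) pair present in that endpoint's sub-network.
model_frame <- function(network, config = nma_config()) {
  stopifnot(inherits(network, "hr_network"), inherits(config, "nma_config"))
  endpoints <- intersect(c("OS", "PFS"), unique(network$estimates$endpoint))
  est_list <- list()
  d_names <- character(0)
  for (ep in endpoints) {
    sub <- endpoint_subnetwork(network, ep)
    if (nrow(sub$estimates) == 0) next
    est_list[[ep]] <- sub$estimates
    d_names <- c(d_names,
                 paste(setdiff(sub$regimens, network$reference), ep, sep = "|"))
  }
  est <- dplyr::bind_rows(est_list)
  if (nrow(est) == 0) stop("network has no usable estimates", call. = FALSE)
  endpoints <- intersect(c("OS", "PFS"), unique(est$endpoint))
  d_index <- function(regimen, ep) {
    key <- paste(regimen, ep, sep = "|")
    ifelse(regimen == network$reference, 0L, match(key, d_names))
  }
  est$ia <- d_index(est$regimen_a, est$endpoint)
  est$ib <- d_index(est$regimen_b, est$endpoint)
  est$ep_index <- match(est$endpoint, endpoints)
  studies <- unique(est$study_id)
  est$study_index <- match(est$study_id, studies)
  hp <- ig_hyperparams(est$se^2, est$n_events, config)
  est$alpha <- hp$alpha
  est$beta <- hp$beta
  est$delta_name <- paste0("delta[", est$study_id, ":", est$regimen_b, ".vs.",
                           est$regimen_a, ":", est$endpoint, "]")
  est$s2_name <- paste0("s2[", est$study_id, ":", est$regimen_b, ".vs.",
                        est$regimen_a, ":", est$endpoint, "]")
  list(est = est, d_names = paste0("d[", d_names, "]"),
       d_keys = d_names, endpoints = endpoints, studies = studies,
       reference = network$reference, config = config)
}

#' Initial model state for a network
#'
#' Returns a full parameter state with basic contrasts at zero, study effects
#' at the observed log HRs, within-study variances at the reported variances,
#' `tau` at half its prior upper bound and `rho` at the prior midpoint. The
#' log posterior is finite at this state by construction.
#'
#' @param network An `hr_network`.
#' @param config An [nma_config()].
#' @return An object of class `nma_state`: a list with elements `d` (named),
#'   `delta`, `s2`, `tau` (named by endpoint), `rho`.
#' @export
initialize_state <- function(network, config = nma_config()) {
  frame <- model_frame(network, config)
  d <- stats::setNames(rep(0, length(frame$d_keys)), frame$d_keys)
  tau <- stats::setNames(rep(config$tau_upper / 2, length(frame$endpoints)),
                         frame$endpoints)
  structure(
    list(d = d, delta = frame$est$log_hr, s2 = frame$est$se^2, tau = tau,
         rho = (config$rho_lower + config$rho_upper) / 2),
    class = "nma_state",
    reference = frame$reference
  )
}

#' Consistency contrast between two regimens implied by a model state
#'
#' Under the consistency parameterisation every contrast is a difference of
#' basic contrasts, `d(y) - d(x)`, so transitivity
#' (`contrast(A,C) = contrast(A,B) + contrast(B,C)`) and antisymmetry hold
#' exactly.
#'
#' @param state An `nma_state`.
#' @param regimen_x,regimen_y Regimen ids; `regimen_y` relative to
#'   `regimen_x`.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return The log-HR contrast of y versus x (numeric scalar).
#' @export
contrast_effect <- function(state, regimen_x, regimen_y, endpoint) {
  stopifnot(inherits(state, "nma_state"))
  ref <- attr(state, "reference")
  lookup <- function(r) {
    if (identical(r, ref)) return(0)
    key <- paste(r, endpoint, sep = "|")
    if (!key %in% names(state$d)) {
      stop("regimen `", r, "` has no ", endpoint, " contrast in this state",
           call. = FALSE)
    }
    unname(state$d[[key]])
  }
  lookup(regimen_y) - lookup(regimen_x)
}

# log density of a zero-mean compound-symmetry multivariate normal with
# variances s2 and common correlation rho, evaluated at residuals r.
# Uses the closed-form determinant and inverse of the equicorrelation matrix.
mvn_cs_logpdf <- function(r, s2, rho) {
  m <- length(r)
  z <- r / sqrt(s2)
  logdet <- sum(log(s2)) + (m - 1) * log1p(-rho) + log1p((m - 1) * rho)
  quad <- (sum(z^2) - rho / (1 + (m - 1) * rho) * sum(z)^2) / (1 - rho)
  -0.5 * (m * log(2 * pi) + logdet + quad)
}

invgamma_logpdf <- function(x, alpha, beta) {
  alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(x) - beta / x
}

#' Joint log posterior of the hierarchical NMA model
#'
#' Evaluates the unnormalised joint log posterior of a full parameter state:
#' the per-study multivariate-normal observation density (diagonal variances
#' `s2`, common within-study correlation `rho` between a study's estimates),
#' the random-effects density of the study-specific effects around their
#' consistency means with endpoint-specific between-study SD `tau`, and the
#' priors of [nma_config()]. States outside the prior support return `-Inf`
#' rather than raising.
#'
#' @param network An `hr_network`.
#' @param state An `nma_state` conformable with the network.
#' @param config An [nma_config()].
#' @return The joint log posterior (numeric scalar; `-Inf` off support).
#' @export
log_posterior <- function(network, state, config = nma_config()) {
  frame <- model_frame(network, config)
  est <- frame$est
  n <- nrow(est)
  if (length(state$delta) != n || length(state$s2) != n) {
    stop("state has ", length(state$delta), " study effects but the network ",
         "needs ", n, call. = FALSE)
  }
  if (length(state$d) != length(frame$d_keys) ||
      !setequal(names(state$d), frame$d_keys)) {
    stop("state basic contrasts do not match the network's (regimen, endpoint) ",
         "layout", call. = FALSE)
  }
  if (!setequal(names(state$tau), frame$endpoints)) {
    stop("state `tau` entries do not match the network's endpoints", call. = FALSE)
  }
  d <- state$d[frame$d_keys]
  tau <- state$tau[frame$endpoints]
  # prior support
  if (any(state$s2 <= 0)) return(-Inf)
  if (any(tau <= 0 | tau >= config$tau_upper)) return(-Inf)
  if (state$rho < config$rho_lower || state$rho > config$rho_upper) return(-Inf)

  d_at <- function(idx) ifelse(idx == 0L, 0, d[pmax(idx, 1L)])
  mu <- d_at(est$ib) - d_at(est$ia)

  lp <- 0
  # observation blocks per study
  for (s in seq_along(frame$studies)) {
    rows <- which(est$study_index == s)
    lp <- lp + mvn_cs_logpdf(est$log_hr[rows] - state$delta[rows],
                             state$s2[rows], state$rho)
  }
  # random effects
  lp <- lp + sum(stats::dnorm(state$delta, mu, tau[est$ep_index], log = TRUE))
  # priors
  lp <- lp + sum(stats::dnorm(d, 0, config$effect_prior_sd, log = TRUE))
  lp <- lp + sum(invgamma_logpdf(state$s2, est$alpha, est$beta))
  lp <- lp - length(tau) * log(config$tau_upper)
  lp <- lp - log(config$rho_upper - config$rho_lower)
  lp
}
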