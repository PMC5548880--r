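#' Sampler configuration
#'
#' Settings for the adaptive Metropolis-within-Gibbs sampler. The defaults
#' (4 chains, 2,000 burn-in, 5,000 retained draws per chain) are desk-scale
#' settings suitable for the small networks in the examples and tests;
#' full-fidelity runs (e.g. 10 chains of 100,000 burn-in and 100,000 draws)
#' are obtained by raising the counts. Step sizes adapt toward
#' `target_accept` during burn-in only, so the retained draws come from a
#' fixed transition kernel. Chain `c` is seeded with `base_seed + c`, making
#' runs bit-reproducible.
#'
#' @param n_chains Number of independent chains (>= 1).
#' @param n_burnin Burn-in iterations per chain (discarded).
#' @param n_samples Retained iterations per chain.
#' @param base_seed Integer seed; chain `c` uses `base_seed + c`.
#' @param adapt_interval Iterations between step-size adaptations (burn-in
#'   only).
#' @param target_accept Target acceptance rate for scalar updates.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_burnin = 2000, n_samples = 5000,
                           base_seed = 1, adapt_interval = 50,
                           target_accept = 0.30) {
  stopifnot(n_chains >= 1, n_burnin >= 1, n_samples >= 1, adapt_interval >= 1,
            target_accept > 0, target_accept < 1)
  structure(
    list(n_chains = as.integer(n_chains), n_burnin = as.integer(n_burnin),
         n_samples = as.integer(n_samples), base_seed = as.integer(base_seed),
         adapt_interval = as.integer(adapt_interval),
         target_accept = target_accept),
    class = "sampler_config"
  )
}

#' Fit the hierarchical NMA model by MCMC
#'
#' Draws from the joint posterior of [log_posterior()] over an evidence
#' network using component-wise Metropolis-within-Gibbs updates (compiled
#' core). Between-study SDs and the within-study correlation are updated on
#' logit-transformed scales with Jacobian corrections; within-study variances
#' on the log scale. Returns the draws with per-parameter split R-hat and
#' bulk effective-sample-size diagnostics.
#'
#' @param network An `hr_network`.
#' @param config An [nma_config()].
#' @param sampler A [sampler_config()].
#' @return An object of class `nma_fit` with elements `draws` (array
#'   `chain x iteration x parameter`), `parameters` (names), `network`,
#'   `config`, `sampler`, `diagnostics` (tibble), `accept_rate`.
#' @examples
#' \donttest{
#' net <- fixture_suite()$pair
#' fit <- fit_nma(net, sampler = sampler_config(n_chains = 2, n_burnin = 500,
#'                                              n_samples = 500))
#' glance(fit)
#' }
#' @export
fit_nma <- function(network, config = nma_config(), sampler = sampler_config()) {
  stopifnot(inherits(network, "hr_network"), inherits(config, "nma_config"),
            inherits(sampler, "sampler_config"))
  frame <- model_frame(network, config)
  est <- frame$est
  init <- initialize_state(network, config)
  lp0 <- log_posterior(network, init, config)
  if (!is.finite(lp0)) {
    stop("non-finite log posterior at initialization; check the evidence ",
         "standard errors and event counts", call. = FALSE)
  }
  n_d <- length(frame$d_keys)
  n_ep <- length(frame$endpoints)
  params <- c(frame$d_names, est$delta_name, est$s2_name,
              paste0("tau[", frame$endpoints, "]"), "rho")
  P <- length(params)
  move_names <- c(params, paste0("shift:", frame$d_names))
  draws <- array(NA_real_,
                 dim = c(sampler$n_chains, sampler$n_samples, P),
                 dimnames = list(NULL, NULL, params))
  acc <- matrix(NA_real_, sampler$n_chains, length(move_names))
  for (ch in seq_len(sampler$n_chains)) {
    set.seed(sampler$base_seed + ch)
    res <- nma_sample_chain(
      y = est$log_hr, study = est$study_index - 1L, ep = est$ep_index - 1L,
      ia = est$ia - 1L, ib = est$ib - 1L,
      alpha = est$alpha, beta = est$beta,
      n_d = n_d, n_ep = n_ep,
      tau_upper = config$tau_upper, effect_sd = config$effect_prior_sd,
      rho_lo = config$rho_lower, rho_hi = config$rho_upper,
      d_init = unname(init$d), delta_init = init$delta, s2_init = init$s2,
      tau_init = unname(init$tau), rho_init = init$rho,
      n_burnin = sampler$n_burnin, n_samples = sampler$n_samples,
      adapt_interval = sampler$adapt_interval,
      target_accept = sampler$target_accept
    )
    draws[ch, , ] <- res$draws
    acc[ch, ] <- res$accept_rate
  }
  fit <- structure(
    list(draws = draws, parameters = params, network = network,
         config = config, sampler = sampler, frame = frame,
         accept_rate = stats::setNames(colMeans(acc), move_names)),
    class = "nma_fit"
  )
  fit$diagnostics <- mcmc_diagnostics(fit)
  fit
}

#' Posterior draws of a regimen's basic contrast
#'
#' Pools all chains' draws of the log-HR contrast of `regimen` versus the
#' network's reference for the given endpoint. The reference itself yields a
#' vector of exact zeros; a regimen with no evidence for the endpoint yields
#' `NULL`.
#'
#' @param fit An `nma_fit`.
#' @param regimen Regimen id.
#' @param endpoint `"OS"` or `"PFS"`.
#' @return Numeric vector of pooled draws, or `NULL` if not estimable.
#' @export
contrast_draws <- function(fit, regimen, endpoint) {
  stopifnot(inherits(fit, "nma_fit"))
  n <- fit$sampler$n_chains * fit$sampler$n_samples
  if (identical(regimen, fit$network$reference)) {
    if (!endpoint %in% fit$frame$endpoints) return(NULL)
    return(rep(0, n))
  }
  key <- paste0("d[", regimen, "|", endpoint, "]")
  if (!key %in% fit$parameters) return(NULL)
  as.vector(fit$draws[, , key])
}

# regimens with draws for an endpoint (reference included), in id order
endpoint_regimens <- function(fit, endpoint) {
  keys <- fit$frame$d_keys
  eps <- sub("^.*\\|", "", keys)
  regs <- sub("\\|[^|]*$", "", keys)
  out <- regs[eps == endpoint]
  if (endpoint %in% fit$frame$endpoints) out <- c(out, fit$network$reference)
  sort(out)
}

#' Convergence diagnostics: split R-hat and bulk effective sample size
#'
#' Computes, per parameter, the split-chain potential scale reduction factor
#' (each chain is halved, so `2 * n_chains` sequences enter the
#' between/within variance comparison) and a bulk effective sample size from
#' chain-averaged autocorrelations truncated by Geyer's initial monotone
#' positive-pair rule. With a single chain R-hat is undefined and reported
#' as `NA`.
#'
#' @param x An `nma_fit` or a 3-d array `chain x iteration x parameter`.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `rhat`,
#'   `ess_bulk`, plus an attribute `"converged"`: `TRUE` when the largest
#'   finite R-hat is below 1.01.
#' @export
mcmc_diagnostics <- function(x) {
  a <- if (inherits(x, "nma_fit")) x$draws else x
  stopifnot(is.array(a), length(dim(a)) == 3)
  n_chain <- dim(a)[1]; n_iter <- dim(a)[2]; P <- dim(a)[3]
  if (n_iter < 10) stop("need at least 10 iterations per chain", call. = FALSE)
  params <- dimnames(a)[[3]]
  if (is.null(params)) params <- paste0("p", seq_len(P))
  out <- tibble::tibble(
    parameter = params,
    mean = NA_real_, sd = NA_real_, rhat = NA_real_, ess_bulk = NA_real_
  )
  half <- floor(n_iter / 2)
  for (p in seq_len(P)) {
    m <- matrix(a[, , p], nrow = n_chain)
    out$mean[p] <- mean(m)
    out$sd[p] <- stats::sd(as.vector(m))
    # split each chain into halves
    splits <- vector("list", 2 * n_chain)
    for (ch in seq_len(n_chain)) {
      splits[[2 * ch - 1]] <- m[ch, seq_len(half)]
      splits[[2 * ch]] <- m[ch, (n_iter - half + 1):n_iter]
    }
    sm <- vapply(splits, mean, 0)
    sv <- vapply(splits, stats::var, 0)
    W <- mean(sv)
    B <- half * stats::var(sm)
    var_plus <- (half - 1) / half * W + B / half
    if (n_chain >= 2) {
      out$rhat[p] <- if (W > 0) sqrt(var_plus / W)
                     else if (B > 0) Inf else NA_real_
    }
    out$ess_bulk[p] <- ess_from_splits(splits, W, var_plus)
  }
  r <- out$rhat[!is.na(out$rhat)]
  attr(out, "converged") <-
    if (length(r) == 0) NA else all(is.finite(r)) && max(r) < 1.01
  out
}

# bulk ESS from split chains: chain-averaged autocovariances combined with
# the between-chain variance, truncated at the first non-positive
# monotone pair sum (Geyer).
ess_from_splits <- function(splits, W, var_plus) {
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  n <- length(splits[[1]])
  M <- length(splits)
  max_lag <- min(n - 2, 1000)
  acov <- matrix(0, M, max_lag + 1)
  nfft <- stats::nextn(2 * n, 2)
  for (j in seq_len(M)) {
    x <- splits[[j]] - mean(splits[[j]])
    f <- stats::fft(c(x, numeric(nfft - n)))
    ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / (nfft * n)
    acov[j, ] <- ac[seq_len(max_lag + 1)]
  }
  mean_acov <- colMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer initial monotone positive sequence on pair sums
  n_pairs <- floor(length(rho) / 2)
  pair <- numeric(0)
  # lag-0 + lag-1 pair uses rho_0 = 1
  p0 <- 1 + rho[1]
  if (is.na(p0) || p0 <= 0) return(n * M)
  pair <- p0
  for (k in seq_len(n_pairs)) {
    idx <- c(2 * k, 2 * k + 1)
    if (max(idx) > length(rho)) break
    pk <- rho[idx[1]] + rho[idx[2]]
    if (is.na(pk) || pk <= 0) break
    pk <- min(pk, pair[length(pair)])
    pair <- c(pair, pk)
  }
  tau_int <- -1 + 2 * sum(pair)
  max(1, n * M / max(tau_int, 1e-12))
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("<nma_fit> ", x$sampler$n_chains, " chains x ", x$sampler$n_samples,
      " draws (burn-in ", x$sampler$n_burnin, ")\n", sep = "")
  cat("  network: ", length(x$network$regimens), " regimens, ",
      length(unique(x$network$estimates$study_id)), " studies, endpoints: ",
      paste(x$frame$endpoints, collapse = ", "), "\n", sep = "")
  dg <- x$diagnostics
  finite_rhat <- dg$rhat[is.finite(dg$rhat)]
  if (length(finite_rhat)) {
    cat("  max split R-hat: ", format(max(finite_rhat), digits = 4),
        ", min bulk ESS: ", format(round(min(dg$ess_bulk, na.rm = TRUE))),
        "\n", sep = "")
  }
  invisible(x)
}
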