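test_that("ig_hyperparams pins the prior mean to the reported variance", {
  hp <- ig_hyperparams(0.04, 100, nma_config())
  expect_equal(hp$alpha, 102)
  expect_equal(hp$beta, 4.04, tolerance = 1e-12)

  hp <- ig_hyperparams(1.0, 1, nma_config())
  expect_equal(hp$alpha, 3)
  expect_equal(hp$beta, 2)
  # closed-form inverse-gamma variance beta^2 / ((alpha-1)^2 (alpha-2))
  expect_equal(hp$beta^2 / ((hp$alpha - 1)^2 * (hp$alpha - 2)), 1.0)

  # mean constraint holds for any admissible input, in both modes
  set.seed(3)
  for (mode in c("inverse_events", "literal_events")) {
    cfg <- nma_config(ig_mode = mode, ig_strength = runif(1, 0.2, 3))
    v <- exp(rnorm(20, -3, 1))
    ev <- sample(10:500, 20)
    hp <- ig_hyperparams(v, ev, cfg)
    expect_equal(hp$beta / (hp$alpha - 1), v, tolerance = 1e-14)
  }
  # inverse_events concentrates with more events; literal_events does not
  a_few <- ig_hyperparams(0.1, 10, nma_config())$alpha
  a_many <- ig_hyperparams(0.1, 400, nma_config())$alpha
  expect_gt(a_many, a_few)
  l_few <- ig_hyperparams(0.1, 10, nma_config(ig_mode = "literal_events"))$alpha
  l_many <- ig_hyperparams(0.1, 400, nma_config(ig_mode = "literal_events"))$alpha
  expect_lt(l_many, l_few)
})

test_that("inverse-gamma prior mean verifies by Monte Carlo", {
  set.seed(11)
  hp <- ig_hyperparams(0.04, 100, nma_config())
  draws <- hp$beta / rgamma(1e6, shape = hp$alpha)
  expect_equal(mean(draws), 0.04, tolerance = 0.005)
})

test_that("log_posterior reduces to the normal likelihood in d for one study", {
  est <- tibble::tibble(
    study_id = "s1", regimen_a = "chemo", regimen_b = "trt1",
    endpoint = "OS", log_hr = -0.45, se = 0.2, n_events = 100L
  )
  net <- build_network(est, reference = "chemo")
  cfg <- nma_config()
  # pin delta to the contrast and s2 to v: the only d-dependence left is the
  # observation density N(y; d, v) plus the d prior
  lp_at <- function(d) {
    st <- initialize_state(net, cfg)
    st$d["trt1|OS"] <- d
    st$delta <- d          # delta = d_b - d_a (tau term constant in d)
    st$s2 <- est$se^2
    log_posterior(net, st, cfg)
  }
  oracle <- function(d) {
    dnorm(est$log_hr, d, est$se, log = TRUE) + dnorm(d, 0, 10, log = TRUE)
  }
  d_grid <- c(-1, -0.45, -0.1, 0.3)
  lp <- vapply(d_grid, lp_at, 0)
  or <- vapply(d_grid, oracle, 0)
  expect_equal(diff(lp), diff(or), tolerance = 1e-10)
})

test_that("states outside the prior support give -Inf, not an error", {
  net <- fixture_suite()$pair
  cfg <- nma_config()
  st <- initialize_state(net, cfg)
  expect_true(is.finite(log_posterior(net, st, cfg)))
  st2 <- st; st2$tau[] <- cfg$tau_upper * 1.01
  expect_identical(log_posterior(net, st2, cfg), -Inf)
  st3 <- st; st3$rho <- 0.96
  expect_identical(log_posterior(net, st3, cfg), -Inf)
  st4 <- st; st4$s2[1] <- -0.01
  expect_identical(log_posterior(net, st4, cfg), -Inf)
})

test_that("log_posterior diverges to -Inf as any within-study variance degenerates", {
  net <- fixture_suite()$triangle
  cfg <- nma_config()
  st <- initialize_state(net, cfg)
  mid <- log_posterior(net, st, cfg)
  for (s2_1 in c(1e-6, 1e-10)) {
    st$s2[1] <- s2_1
    expect_lt(log_posterior(net, st, cfg), mid - 100)
  }
  st <- initialize_state(net, cfg)
  for (s2_1 in c(1e4, 1e8)) {
    st$s2[1] <- s2_1
    expect_lt(log_posterior(net, st, cfg), mid - 10)
  }
})

test_that("with rho = 0 the joint equals the product of univariate components", {
  # two estimates in one study
  est <- tibble::tibble(
    study_id = "s1", regimen_a = "chemo", regimen_b = "trt1",
    endpoint = c("OS", "PFS"), log_hr = c(-0.4, -0.6), se = c(0.2, 0.25),
    n_events = c(100L, 64L)
  )
  net <- build_network(est, reference = "chemo")
  cfg <- nma_config()
  st <- initialize_state(net, cfg)
  st$rho <- 0
  st$d[] <- c(-0.3, -0.5)
  st$delta <- c(-0.35, -0.55)
  lp <- log_posterior(net, st, cfg)

  # independent per-estimate oracle assembled by hand
  hp <- ig_hyperparams(est$se^2, est$n_events, cfg)
  oracle <- sum(dnorm(est$log_hr, st$delta, sqrt(st$s2), log = TRUE)) +
    sum(dnorm(st$delta, st$d, st$tau[c("OS", "PFS")], log = TRUE)) +
    sum(dnorm(st$d, 0, cfg$effect_prior_sd, log = TRUE)) +
    sum(hp$alpha * log(hp$beta) - lgamma(hp$alpha) -
          (hp$alpha + 1) * log(st$s2) - hp$beta / st$s2) -
    2 * log(cfg$tau_upper) - log(cfg$rho_upper - cfg$rho_lower)
  expect_equal(lp, oracle, tolerance = 1e-10)
})

test_that("one-estimate-per-study joint matches a brute-force univariate oracle", {
  set.seed(22)
  est_tbl <- tibble::tibble(
    study_id = paste0("s", 1:6),
    regimen_a = c("chemo", "chemo", "trt1", "chemo", "chemo", "trt2"),
    regimen_b = c("trt1", "trt2", "trt2", "trt1", "trt2", "trt1"),
    endpoint = c("OS", "OS", "OS", "PFS", "PFS", "PFS"),
    log_hr = rnorm(6, -0.2, 0.3), se = runif(6, 0.15, 0.3),
    n_events = sample(50:200, 6)
  )
  net <- build_network(est_tbl, reference = "chemo")
  cfg <- nma_config()
  st <- initialize_state(net, cfg)
  st$d[] <- rnorm(length(st$d), 0, 0.4)
  st$delta <- st$delta + rnorm(length(st$delta), 0, 0.2)
  st$s2 <- st$s2 * exp(rnorm(length(st$s2), 0, 0.3))
  st$rho <- 0.3  # irrelevant: every study has a single estimate

  frame <- hrnma:::model_frame(net, cfg)
  est <- frame$est
  mu <- vapply(seq_len(nrow(est)), function(i) {
    db <- if (est$ib[i] == 0) 0 else st$d[[est$ib[i]]]
    da <- if (est$ia[i] == 0) 0 else st$d[[est$ia[i]]]
    db - da
  }, 0)
  oracle <- sum(dnorm(est$log_hr, st$delta, sqrt(st$s2), log = TRUE)) +
    sum(dnorm(st$delta, mu, st$tau[frame$endpoints][est$ep_index], log = TRUE)) +
    sum(dnorm(st$d, 0, cfg$effect_prior_sd, log = TRUE)) +
    sum(est$alpha * log(est$beta) - lgamma(est$alpha) -
          (est$alpha + 1) * log(st$s2) - est$beta / st$s2) -
    length(frame$endpoints) * log(cfg$tau_upper) -
    log(cfg$rho_upper - cfg$rho_lower)
  expect_equal(log_posterior(net, st, cfg), oracle, tolerance = 1e-10)
})

test_that("compiled and reference log posteriors agree on randomized states", {
  sim <- simulate_network(seed = 3, rho_true = 0.5,
                          endpoint_probs = c(0, 0, 1))
  net <- sim$network
  cfg <- nma_config()
  frame <- hrnma:::model_frame(net, cfg)
  est <- frame$est
  set.seed(99)
  for (k in 1:10) {
    st <- initialize_state(net, cfg)
    st$d[] <- rnorm(length(st$d), 0, 0.5)
    st$delta <- st$delta + rnorm(length(st$delta), 0, 0.3)
    st$s2 <- st$s2 * exp(rnorm(length(st$s2), 0, 0.2))
    st$tau[] <- runif(length(st$tau), 0.01, cfg$tau_upper - 0.01)
    st$rho <- runif(1, 0, 0.94)
    lp_r <- log_posterior(net, st, cfg)
    lp_c <- hrnma:::nma_lp_cpp(
      est$log_hr, est$study_index - 1L, est$ep_index - 1L,
      est$ia - 1L, est$ib - 1L, est$alpha, est$beta,
      unname(st$d[frame$d_keys]), st$delta, st$s2,
      unname(st$tau[frame$endpoints]), st$rho,
      cfg$tau_upper, cfg$effect_prior_sd, cfg$rho_lower, cfg$rho_upper
    )
    expect_equal(lp_r, lp_c, tolerance = 1e-10)
  }
})

test_that("within-study covariance blocks are positive definite across rho", {
  set.seed(17)
  for (i in 1:30) {
    m <- sample(2:5, 1)
    s2 <- exp(rnorm(m, -3, 0.8))
    rho <- runif(1, 0, 0.949)
    sigma <- diag(s2)
    for (j in seq_len(m)) for (k in seq_len(m)) {
      if (j != k) sigma[j, k] <- rho * sqrt(s2[j] * s2[k])
    }
    expect_no_error(chol(sigma))
    # closed-form log-determinant used in the density matches chol
    expect_equal(hrnma:::mvn_cs_logpdf(numeric(m), s2, rho),
                 -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(chol(sigma))))),
                 tolerance = 1e-10)
  }
})

test_that("contrast_effect obeys reference, transitivity and antisymmetry", {
  net <- fixture_suite()$triangle
  st <- initialize_state(net)
  st$d[] <- c(-0.42, -0.17)
  expect_identical(contrast_effect(st, "chemo", "chemo", "OS"), 0)
  ab <- contrast_effect(st, "chemo", "trtA", "OS")
  bc <- contrast_effect(st, "trtA", "trtB", "OS")
  ac <- contrast_effect(st, "chemo", "trtB", "OS")
  expect_identical(ac, ab + bc)
  expect_identical(contrast_effect(st, "trtB", "trtA", "OS"), -bc)
  expect_error(contrast_effect(st, "chemo", "nope", "OS"), "nope")
})

test_that("non-conformable states raise structural errors", {
  net <- fixture_suite()$triangle
  cfg <- nma_config()
  st <- initialize_state(net, cfg)
  st_bad <- st; st_bad$delta <- st$delta[-1]
  expect_error(log_posterior(net, st_bad, cfg), "study effects")
  st_bad2 <- st; names(st_bad2$d)[1] <- "ghost|OS"
  expect_error(log_posterior(net, st_bad2, cfg), "layout")
})
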