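# Build a minimal nma_fit-shaped object whose basic-contrast draws are given
# directly, so the summary layer can be tested against exactly known draws.
# `d_draws` is a named list "regimen|endpoint" -> numeric vector.
make_fake_fit <- function(d_draws, reference = "chemo") {
  n <- length(d_draws[[1]])
  stopifnot(all(lengths(d_draws) == n))
  keys <- names(d_draws)
  endpoints <- unique(sub("^.*\\|", "", keys))
  regimens <- sort(unique(c(reference, sub("\\|[^|]*$", "", keys))))
  params <- paste0("d[", keys, "]")
  draws <- array(NA_real_, dim = c(1, n, length(keys)),
                 dimnames = list(NULL, NULL, params))
  for (k in seq_along(keys)) draws[1, , k] <- d_draws[[k]]
  structure(
    list(
      draws = draws, parameters = params,
      network = structure(list(regimens = regimens, reference = reference,
                               estimates = tibble::tibble(study_id = character())),
                          class = "hr_network"),
      sampler = list(n_chains = 1L, n_samples = n),
      frame = list(d_keys = keys, endpoints = endpoints)
    ),
    class = "nma_fit"
  )
}

# quick sampler settings for tests that only need a rough posterior
quick_sampler <- function(seed = 1) {
  sampler_config(n_chains = 2, n_burnin = 1000, n_samples = 2000,
                 base_seed = seed)
}

# write an estimates tibble to a temp CSV in the ingest layout and return path
write_ingest_csv <- function(tbl) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(tbl, path, na = "")
  path
}
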