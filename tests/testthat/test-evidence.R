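ingest_row <- function(study = "s1", subgroup = "egfr_pos", a = "chemo",
                       b = "trt1", endpoint = "OS", hr = NA, lo = NA, hi = NA,
                       p = NA, events = NA, alloc = NA, direction = NA,
                       n_events = 100L) {
  tibble::tibble(study_id = study, subgroup = subgroup, regimen_a = a,
                 regimen_b = b, endpoint = endpoint, hr = hr, ci_low = lo,
                 ci_high = hi, p_value = p, events_total = events,
                 alloc_frac_a = alloc, direction = direction,
                 n_events = n_events)
}

ingest_to_est <- function(sg) {
  tibble::tibble(
    study_id = c("s1", "s2"), subgroup = sg,
    regimen_a = "chemo", regimen_b = c("trt1", "trt2"),
    endpoint = "OS", log_hr = c(-0.3, -0.1), se = 0.2, n_events = 100L,
    provenance = "reported"
  )
}

test_that("read_evidence converts HR/CI rows and records provenance", {
  path <- write_ingest_csv(ingest_row(hr = 0.48, lo = 0.26, hi = 0.88))
  est <- read_evidence(path)
  expect_equal(nrow(est), 1L)
  expect_equal(est$log_hr, -0.7339692, tolerance = 1e-6)
  expect_equal(est$se, 0.3110364, tolerance = 1e-6)
  expect_identical(est$provenance, "reported")
})

test_that("read_evidence routes p-value rows through reconstruction", {
  path <- write_ingest_csv(ingest_row(p = 0.05, events = 100, alloc = 0.5,
                                      direction = "favours_b"))
  est <- read_evidence(path)
  expect_identical(est$provenance, "reconstructed")
  expect_equal(est$log_hr, -qnorm(0.975) / 5, tolerance = 1e-9)
  expect_equal(est$se, 0.2, tolerance = 1e-12)
  # sign from a non-unit HR point estimate when no direction is given
  path2 <- write_ingest_csv(ingest_row(hr = 1.4, p = 0.05, events = 100))
  est2 <- read_evidence(path2)
  expect_gt(est2$log_hr, 0)
  # the CI route wins when both a CI and a p-value are present
  path3 <- write_ingest_csv(ingest_row(hr = 0.5, lo = 0.3, hi = 0.9,
                                       p = 0.5, events = 10))
  est3 <- read_evidence(path3)
  expect_identical(est3$provenance, "reported")
  expect_equal(est3$log_hr, log(0.5), tolerance = 1e-12)
})

test_that("read_evidence rejects malformed rows with their index", {
  path <- write_ingest_csv(ingest_row(hr = 1.0, lo = 1.0, hi = 1.0))
  expect_error(read_evidence(path), "row 1.*degenerate")
  path <- write_ingest_csv(ingest_row(hr = -0.4, lo = 0.2, hi = 0.8))
  expect_error(read_evidence(path), "row 1.*positive")
  path <- write_ingest_csv(dplyr::bind_rows(
    ingest_row(hr = 0.5, lo = 0.3, hi = 0.9),
    ingest_row(study = "s2")
  ))
  expect_error(read_evidence(path), "row 2")
})

test_that("read_evidence reports missing columns by name and honours schema", {
  tbl <- ingest_row(hr = 0.5, lo = 0.3, hi = 0.9)
  path <- write_ingest_csv(dplyr::select(tbl, -"study_id"))
  expect_error(read_evidence(path), "`study_id`")
  # schema maps canonical names onto the file's headers
  tbl2 <- dplyr::rename(tbl, trial = "study_id")
  path2 <- write_ingest_csv(tbl2)
  est <- read_evidence(path2, schema = c(study_id = "trial"))
  expect_identical(est$study_id, "s1")
  expect_error(read_evidence(path2, schema = c(study_id = "nope")), "nope")
})

test_that("an empty file with a header yields an empty estimate table", {
  path <- write_ingest_csv(ingest_row(hr = 0.5, lo = 0.3, hi = 0.9)[0, ])
  est <- read_evidence(path)
  expect_equal(nrow(est), 0L)
})

test_that("orientation flip negates the log hazard ratio", {
  path <- write_ingest_csv(ingest_row(hr = 0.48, lo = 0.26, hi = 0.88))
  a <- read_evidence(path)
  b <- read_evidence(path, orientation = "a_vs_b")
  expect_equal(b$log_hr, -a$log_hr)
  expect_equal(b$se, a$se)
})

test_that("write_evidence/read_evidence round-trips estimates to 1e-12", {
  sim <- simulate_network(n_regimens = 4, n_studies = 10, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_evidence(sim$network, path)
  back <- read_evidence(path)
  orig <- sim$network$estimates
  expect_equal(back$log_hr, orig$log_hr, tolerance = 1e-12)
  expect_equal(back$se, orig$se, tolerance = 1e-12)
  expect_identical(back$study_id, orig$study_id)
  expect_identical(back$n_events, orig$n_events)
})

test_that("build_network validates connectivity and the reference", {
  est <- tibble::tibble(
    study_id = c("s1", "s2"), regimen_a = c("A", "B"), regimen_b = c("B", "C"),
    endpoint = "OS", log_hr = c(-0.2, 0.1), se = 0.2, n_events = 100L
  )
  net <- build_network(est, reference = "A")
  expect_s3_class(net, "hr_network")
  expect_setequal(net$regimens, c("A", "B", "C"))

  disc <- tibble::tibble(
    study_id = c("s1", "s2"), regimen_a = c("A", "C"), regimen_b = c("B", "D"),
    endpoint = "OS", log_hr = c(-0.2, 0.1), se = 0.2, n_events = 100L
  )
  expect_error(build_network(disc, reference = "A"), "\\{C, D\\}")
  expect_error(build_network(est, reference = "Z"), "appears in no estimate")

  single <- est[1, ]
  net2 <- build_network(single, reference = "B")
  expect_setequal(net2$regimens, c("A", "B"))
})

test_that("duplicate (study, contrast, endpoint) rows are rejected", {
  est <- tibble::tibble(
    study_id = "s1", regimen_a = "A", regimen_b = "B",
    endpoint = "OS", log_hr = c(-0.2, -0.3), se = 0.2, n_events = 100L
  )
  expect_error(build_network(est, reference = "A"), "duplicate")
  # same contrast in different studies or endpoints is fine
  est$study_id <- c("s1", "s2")
  expect_s3_class(build_network(est, reference = "A"), "hr_network")
})

test_that("connectivity agrees with a brute-force breadth-first search", {
  bfs_connected <- function(edges, nodes) {
    if (length(nodes) <= 1) return(TRUE)
    adj <- lapply(stats::setNames(nm = nodes), function(v) {
      unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
    })
    seen <- nodes[1]
    queue <- nodes[1]
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- setdiff(adj[[v]], seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    length(seen) == length(nodes)
  }
  set.seed(5)
  for (i in 1:40) {
    n_nodes <- sample(2:10, 1)
    nodes <- paste0("R", seq_len(n_nodes))
    n_edges <- sample(1:12, 1)
    edges <- data.frame(from = sample(nodes, n_edges, replace = TRUE),
                        to = sample(nodes, n_edges, replace = TRUE))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (nrow(edges) == 0) next
    comps <- hrnma:::graph_components(edges$from, edges$to, nodes)
    expect_identical(length(comps) == 1L, bfs_connected(edges, nodes))
  }
})

test_that("subgroup_networks builds independent per-subgroup networks", {
  est1 <- ingest_to_est(sg = "egfr_pos")
  est2 <- ingest_to_est(sg = "egfr_wt")
  nets <- subgroup_networks(dplyr::bind_rows(est1, est2), reference = "chemo")
  expect_named(nets, c("egfr_pos", "egfr_wt"))
  expect_length(attr(nets, "unbuildable"), 0)
  # estimates never shared across subgroups
  expect_equal(nrow(nets$egfr_pos$estimates), nrow(est1))

  # a subgroup lacking the reference fails alone
  bad <- ingest_to_est(sg = "squamous")
  bad$regimen_a <- "other"
  expect_warning(
    nets2 <- subgroup_networks(dplyr::bind_rows(est1, bad), reference = "chemo"),
    "squamous"
  )
  expect_named(nets2, "egfr_pos")
  expect_named(attr(nets2, "unbuildable"), "squamous")

  empty <- subgroup_networks(est1[0, ], reference = "chemo")
  expect_length(empty, 0)
})

test_that("endpoint sub-networks keep only the component joined to the reference", {
  est <- tibble::tibble(
    study_id = c("s1", "s2", "s3"),
    regimen_a = c("chemo", "chemo", "trt2"),
    regimen_b = c("trt1", "trt2", "trt3"),
    endpoint = c("OS", "PFS", "PFS"),
    log_hr = c(-0.3, -0.2, 0.1), se = 0.2, n_events = 100L
  )
  net <- build_network(est, reference = "chemo")
  os <- endpoint_subnetwork(net, "OS")
  expect_setequal(os$regimens, c("chemo", "trt1"))
  pfs <- endpoint_subnetwork(net, "PFS")
  expect_setequal(pfs$regimens, c("chemo", "trt2", "trt3"))
})
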