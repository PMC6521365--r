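# minimal stub detections for compile tests
stub_detection <- function(ids, flagged, method = "mcd",
                           vars = c("a", "b", "c")) {
  n <- length(ids)
  W <- matrix(rnorm(n * length(vars)), n, dimnames = list(ids, vars))
  res <- tibble::tibble(
    id = ids, distance = abs(rnorm(n)),
    outlyingness = runif(n), flag = ids %in% flagged
  )
  structure(
    list(result = res, threshold = 0.5, contributions = W,
         estimator = list(h = n), params = list(), method = method),
    class = c("qc_mcd", "qc_detection")
  )
}

test_that("the two-or-more rule decides listing", {
  ids <- sprintf("P%02d", 1:10)
  withr::with_seed(1, {
    runs <- list(
      mcd_adj = stub_detection(ids, c("P01", "P02")),
      mcd_unadj = stub_detection(ids, c("P02", "P03")),
      rpca_adj = stub_detection(ids, c("P04")),
      rpca_unadj = stub_detection(ids, c("P01", "P05"))
    )
  })
  rep <- compile_outlier_list(runs)
  tt <- tidy(rep)
  # P01: mcd_adj + rpca_unadj -> listed; P04: rpca_adj only -> not listed
  expect_true(tt$listed[tt$id == "P01"])
  expect_identical(sort(tt$flagged_by[tt$id == "P01"][[1]]),
                   c("mcd_adj", "rpca_unadj"))
  expect_false(tt$listed[tt$id == "P04"])
  expect_setequal(listed_ids(rep), c("P01", "P02"))
  # every listed participant carries contributions with provenance
  expect_true(all(listed_ids(rep) %in% rep$contributions$id))
  g <- glance(rep)
  expect_identical(g$n_listed, 2L)
  expect_lte(g$n_listed, g$n_flagged_any)

  # flagged by all four: 4 provenance tags
  withr::with_seed(2, {
    runs4 <- lapply(setNames(nm = names(runs)), function(nm) stub_detection(ids, "P07"))
  })
  rep4 <- compile_outlier_list(runs4)
  expect_identical(tidy(rep4)$n_methods[tt$id == "P07"], 4L)
  expect_setequal(
    unique(rep4$contributions$method[rep4$contributions$id == "P07"]),
    names(runs)
  )

  # order independence
  rep_rev <- compile_outlier_list(rev(runs))
  expect_setequal(listed_ids(rep_rev), listed_ids(rep))

  # mismatched participant sets error
  runs_bad <- runs
  runs_bad$mcd_adj <- withr::with_seed(3, stub_detection(sprintf("Q%02d", 1:10), "Q01"))
  expect_error(compile_outlier_list(runs_bad), "different participant sets")
})

test_that("merged contributions interleave per-method ranks", {
  ids <- sprintf("P%02d", 1:6)
  withr::with_seed(5, {
    runs <- list(a = stub_detection(ids, "P01"), b = stub_detection(ids, "P01"))
  })
  rep <- compile_outlier_list(runs, min_flags = 2)
  cc <- rep$contributions[rep$contributions$id == "P01", ]
  # the first two merged entries are both rank-1 picks, one per method
  expect_setequal(cc$method[cc$merged_rank <= 2], c("a", "b"))
  expect_identical(cc$rank[cc$merged_rank <= 2], c(1L, 1L))
})

test_that("the evaluation loop converges once data are static", {
  co <- generate_cohort(cohort_spec(n = 70, n_pairs = 3, n_blocks = 1,
                                    block_size = 4, seed = 19))
  it1 <- run_iteration(co$data, co$covariates, seed = 3)
  expect_false(it1$converged)  # first pass has no prior list to match
  it2 <- run_iteration(co$data, co$covariates, prior = it1, seed = 3)
  expect_true(it2$converged)
  expect_identical(it2$iteration, 2L)
  # applying a correction changes the fingerprint and blocks convergence
  corr <- tibble::tibble(id = co$data$id[1],
                         variable = "pair01_raw",
                         corrected_value = co$data$pair01_raw[1] + 50)
  it3 <- run_iteration(co$data, co$covariates, corrections = corr,
                       prior = it2, seed = 3)
  expect_false(it3$converged)
  expect_false(identical(it3$fingerprint, it2$fingerprint))
  expect_identical(nrow(it3$corrections_applied), 1L)
})

test_that("a masked second error needs a second correction iteration", {
  co <- generate_cohort(cohort_spec(n = 120, seed = 77))
  data <- co$data
  victim <- "P010"
  i <- match(victim, data$id)
  # two pair-breaking errors in one row; the larger initially dominates
  fit1 <- lm(pair01_tr ~ pair01_raw, data = data[-i, ])
  sd1 <- sd(resid(fit1))
  fit2 <- lm(pair02_tr ~ pair02_raw, data = data[-i, ])
  sd2 <- sd(resid(fit2))
  true1 <- data$pair01_tr[i]
  true2 <- data$pair02_tr[i]
  data$pair01_tr[i] <- predict(fit1, data[i, ]) + 12 * sd1
  data$pair02_tr[i] <- predict(fit2, data[i, ]) + 8 * sd2

  it1 <- run_iteration(data, co$covariates, seed = 5)
  expect_true(victim %in% listed_ids(it1$report))

  # verification finds error 1 and corrects it; the row is listed again
  corr1 <- tibble::tibble(id = victim, variable = "pair01_tr",
                          corrected_value = true1)
  it2 <- run_iteration(data, co$covariates, corrections = corr1,
                       prior = it1, seed = 5)
  expect_false(it2$converged)
  expect_true(victim %in% listed_ids(it2$report))

  # correcting error 2 as well; afterwards the loop goes static
  corr2 <- tibble::tibble(id = victim, variable = "pair02_tr",
                          corrected_value = true2)
  it3 <- run_iteration(it2$data, co$covariates, corrections = corr2,
                       prior = it2, seed = 5)
  expect_false(it3$converged)
  it4 <- run_iteration(it3$data, co$covariates, prior = it3, seed = 5)
  expect_true(it4$converged)
})

test_that("parameter sweep counts track the percentile and reproduce h", {
  co <- generate_cohort(cohort_spec(n = 90, n_pairs = 3, n_blocks = 1,
                                    block_size = 4, seed = 9))
  sweep <- parameter_sweep(co$data, alphas = c(0.6, 0.8, 1.0),
                           eps_rpca_values = c(0.85, 0.90, 0.95),
                           n_sims = 50, seed = 2)
  # h values reproduce compute_h at the number of variables used
  p <- ncol(co$data) - 1L
  expect_identical(
    sort(unique(sweep$h)),
    sort(unique(vapply(c(0.6, 0.8, 1.0), function(a) compute_h(90, p, a),
                       integer(1))))
  )
  # RPCA flag counts are non-increasing in eps at fixed alpha
  for (a in unique(sweep$alpha)) {
    sub <- sweep[sweep$alpha == a, ]
    sub <- sub[order(sub$eps_rpca), ]
    expect_true(all(diff(sub$n_flagged_rpca) <= 0))
  }
  # single-point grid agrees with a direct run
  one <- parameter_sweep(co$data, alphas = 0.8, eps_rpca_values = 0.90,
                         n_sims = 50, seed = 2)
  direct_mcd <- detect_mcd(qc_prepare(co$data), alpha = 0.8, n_sims = 50,
                           seed = 2)
  expect_identical(one$n_flagged_mcd, sum(direct_mcd$result$flag))
})

test_that("reports round-trip to CSV and JSON", {
  ids <- sprintf("P%02d", 1:8)
  withr::with_seed(11, {
    runs <- list(a = stub_detection(ids, c("P01", "P03")),
                 b = stub_detection(ids, "P03"))
  })
  rep <- compile_outlier_list(runs, min_flags = 2)
  csvf <- tempfile(fileext = ".csv")
  jsonf <- tempfile(fileext = ".json")
  write_report(rep, csv_path = csvf, json_path = jsonf)
  back <- read.csv(csvf)
  expect_identical(back$id, "P03")
  j <- jsonlite::fromJSON(jsonf, simplifyVector = FALSE)
  expect_identical(j[[1]]$id, "P03")
  expect_identical(sort(unlist(j[[1]]$methods)), c("a", "b"))
})
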