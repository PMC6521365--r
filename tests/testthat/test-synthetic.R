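test_that("cohort generation is deterministic and matches its spec", {
  spec <- cohort_spec(n = 100, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$covariates, c2$covariates)
  expect_identical(ncol(c1$data) - 1L,
                   2L * spec$n_pairs + spec$n_blocks * spec$block_size)
  expect_true(all(c1$covariates$age >= 55 & c1$covariates$age <= 85))
  expect_true(all(c1$covariates$education >= 6))
  expect_true(all(c1$covariates$sex %in% 0:1))
})

test_that("covariate distributions track the target demographics", {
  stats <- sapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(n = 161, seed = s))
    c(mean(co$covariates$age), sd(co$covariates$age),
      mean(co$covariates$sex))
  })
  expect_lt(abs(mean(stats[1, ]) - 68.72), 1.5)
  expect_lt(abs(mean(stats[2, ]) - 7.42), 0.8)
  expect_lt(abs(mean(stats[3, ]) - 110 / 161), 0.1)
})

test_that("raw/transformed pairs hit the target correlation", {
  co <- generate_cohort(cohort_spec(n = 500, seed = 3))
  cors <- mapply(function(r, t) cor(co$data[[r]], co$data[[t]]),
                 co$pairs$raw, co$pairs$transformed)
  expect_true(all(cors > 0.85 & cors < 0.95))
  # block variables are strongly mutually correlated
  b <- co$blocks[[1]]
  cm <- cor(as.matrix(co$data[, b]))
  expect_gt(min(cm[upper.tri(cm)]), 0.6)
})

test_that("zero noise with zero covariate effects gives constant columns", {
  spec <- cohort_spec(n = 30, n_pairs = 2, n_blocks = 1, block_size = 3,
                      covariate_effects = list(age = 0, sex = 0, education = 0),
                      noise_sd = 0, seed = 1)
  co <- generate_cohort(spec)
  sds <- apply(as.matrix(co$data[, -1]), 2, sd)
  expect_true(all(sds < 1e-8))
})

test_that("error injection logs exactly what it corrupts", {
  co <- generate_cohort(cohort_spec(n = 100, seed = 11))
  # k = 0: untouched data, empty log
  inj0 <- inject_errors(co, k = 0, seed = 2)
  expect_identical(inj0$data, co$data)
  expect_identical(nrow(inj0$log), 0L)

  inj <- inject_errors(co, k = 6, seed = 2)
  expect_identical(inj1 <- inject_errors(co, k = 6, seed = 2), inj)  # seed-stable
  # every entry's corrupted value differs from the original
  expect_true(all(inj$log$corrupted != inj$log$original))
  # the corrupted cells really hold the logged values
  for (k in seq_len(nrow(inj$log))) {
    i <- match(inj$log$id[k], inj$data$id)
    expect_identical(inj$data[[inj$log$variable[k]]][i], inj$log$corrupted[k])
    expect_identical(co$data[[inj$log$variable[k]]][i], inj$log$original[k])
  }

  # block miscounts touch every variable of exactly one block
  injb <- inject_errors(co, k = 3, mechanisms = c(block_miscount = 1), seed = 5)
  for (i in unique(injb$log$id)) {
    vars <- injb$log$variable[injb$log$id == i]
    expect_true(any(vapply(co$blocks, function(b) setequal(vars, b), logical(1))))
  }
})

test_that("pair-breaking errors are invisible to boxplots but break the pair", {
  for (seed in 1:5) {
    co <- generate_cohort(cohort_spec(n = 150, seed = seed))
    inj <- inject_errors(co, k = 4, mechanisms = c(transform_miscalc = 1),
                         seed = seed + 50)
    log <- inj$log[inj$log$mechanism == "transform_miscalc", ]
    for (k in seq_len(nrow(log))) {
      v <- log$variable[k]
      i <- match(log$id[k], inj$data$id)
      # the corrupted cell is inside its variable's fences
      b <- boxplot_detect(inj$data[[v]])
      expect_false(b$flags[i])
      # but its pair residual is gross
      praw <- co$pairs$raw[co$pairs$transformed == v]
      fit <- lm(inj$data[[v]][-i] ~ inj$data[[praw]][-i])
      pred <- coef(fit)[1] + coef(fit)[2] * inj$data[[praw]][i]
      expect_gt(abs(inj$data[[v]][i] - pred), 4 * sd(resid(fit)))
    }
  }
})

test_that("detection scoring computes sensitivity, burden and hit rate", {
  log <- tibble::tibble(id = c("P01", "P02"), variable = c("a", "b"),
                        mechanism = "transcription",
                        original = c(1, 2), corrupted = c(9, 9))
  participants <- tibble::tibble(
    id = sprintf("P%02d", 1:10),
    flagged_by = c(list(c("m1", "m2")), rep(list(character()), 9)),
    n_methods = c(2L, rep(0L, 9)),
    listed = c(TRUE, rep(FALSE, 9))
  )
  contribs <- tibble::tibble(id = "P01", method = "m1", rank = 1L,
                             variable = "a", value = 3, merged_rank = 1L)
  rep <- structure(
    list(participants = participants, contributions = contribs,
         min_flags = 2L, methods = c("m1", "m2")),
    class = "qc_report"
  )
  s <- score_detection(rep, log)
  expect_equal(s$sensitivity, 0.5)   # one of two injected ids listed
  expect_equal(s$burden, 0.1)        # 1 of 10 listed
  expect_equal(s$contribution_hit_rate, 1)  # its variable is rank 1

  # empty report: zero sensitivity and burden
  rep0 <- rep
  rep0$participants$listed <- FALSE
  rep0$participants$n_methods <- 0L
  s0 <- score_detection(rep0, log)
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$burden, 0)
})
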