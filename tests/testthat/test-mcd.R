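test_that("compute_h matches the floor formula and its boundary cases", {
  expect_identical(compute_h(161, 53, 0.8), 139L)
  expect_identical(compute_h(148, 29, 0.8), 124L)
  # alpha = 1 keeps everything; alpha = 0.5 gives the minimal subset
  for (np in list(c(50, 5), c(161, 53), c(23, 3))) {
    n <- np[1]; p <- np[2]
    expect_identical(compute_h(n, p, 1), as.integer(n))
    expect_identical(compute_h(n, p, 0.5), as.integer(floor((n + p + 1) / 2)))
    for (a in c(0.6, 0.75, 0.9)) {
      h <- compute_h(n, p, a)
      expect_true(h >= floor((n + p + 1) / 2) && h <= n)
    }
  }
  expect_error(compute_h(10, 10, 0.8), "more observations than variables")
})

test_that("mahalanobis_distances matches closed forms and rejects singular scatter", {
  mu <- c(1, 2)
  sigma <- diag(c(1, 4))
  expect_equal(mahalanobis_distances(rbind(mu), mu, sigma), 0)
  expect_equal(mahalanobis_distances(rbind(c(1, 4)), mu, sigma), 1)
  # identity scatter reduces to the Euclidean norm
  X <- rmvn_fixture(20, 3, seed = 5)
  expect_equal(
    mahalanobis_distances(X, rep(0, 3), diag(3)),
    sqrt(rowSums(X^2))
  )
  # cross-check against stats::mahalanobis on a random PD matrix
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_equal(
    mahalanobis_distances(X, rep(0, 3), S)^2,
    stats::mahalanobis(X, rep(0, 3), S),
    tolerance = 1e-10
  )
  sing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(mahalanobis_distances(X[, 1:2], c(0, 0), sing), "singular")
})

test_that("C-steps never increase the subset covariance determinant", {
  withr::with_seed(11, {
    violations <- 0L
    for (k in 1:250) {
      n <- sample(15:40, 1)
      p <- sample(2:4, 1)
      X <- matrix(rnorm(n * p), n, p)
      h <- compute_h(n, p, runif(1, 0.5, 1))
      start <- sample(n, max(p + 1, sample(p + 1:5, 1)))
      s1 <- tryCatch(c_step(X, start, h = h), error = function(e) NULL)
      if (is.null(s1)) next
      d1 <- det(cohortqc:::subset_mean_cov(X, s1)$sigma)
      s2 <- c_step(X, s1)
      d2 <- det(cohortqc:::subset_mean_cov(X, s2)$sigma)
      if (d2 > d1 + 1e-10) violations <- violations + 1L
    }
    expect_identical(violations, 0L)
  })
})

test_that("a fixed-point subset is returned unchanged by the C-step", {
  X <- rmvn_fixture(30, 2, seed = 3, contaminate = 3)
  fm <- fast_mcd(X, alpha = 0.75, seed = 2)
  expect_identical(c_step(X, fm$subset), fm$subset)
})

test_that("fast_mcd finds the exhaustive minimum on small instances", {
  for (seed in 1:6) {
    X <- rmvn_fixture(12, 2, seed = seed, contaminate = 2)
    fm <- fast_mcd(X, alpha = 0.5, n_starts = 300, seed = seed)
    expect_identical(fm$h, 7L)
    expect_equal(fm$det, brute_force_mcd_det(X, 7L), tolerance = 1e-8)
  }
})

test_that("fast_mcd with alpha = 1 is the classical estimate and runs are seed-stable", {
  X <- rmvn_fixture(60, 4, seed = 21)
  fm <- fast_mcd(X, alpha = 1, seed = 1)
  expect_equal(fm$mu, colMeans(X))
  expect_equal(fm$sigma, cov(X) * (59 / 60), tolerance = 1e-12)
  expect_identical(fm$c0, 1)

  fm1 <- fast_mcd(X, alpha = 0.7, seed = 42)
  fm2 <- fast_mcd(X, alpha = 0.7, seed = 42)
  expect_identical(fm1$subset, fm2$subset)
})

test_that("fast_mcd agrees with an independent MCD implementation", {
  # MASS::cov.rob also searches for the minimum-determinant subset; the two
  # searches should land on (at least) equally concentrated subsets
  X <- rmvn_fixture(80, 3, seed = 13, contaminate = 8)
  h <- compute_h(80, 3, 0.5)
  fm <- fast_mcd(X, alpha = 0.5, seed = 7)
  ms <- MASS::cov.rob(X, method = "mcd", quantile.used = h, nsamp = 2000)
  det_mass <- det(cohortqc:::subset_mean_cov(X, ms$best)$sigma)
  expect_lte(fm$det, det_mass * (1 + 1e-8))
})

test_that("consistency factor is 1 without trimming and matches quadrature at p = 1", {
  expect_identical(consistency_factor(100, 5, 100), 1)
  expect_gt(consistency_factor(100, 5, 80), 1)
  # 1-D oracle: variance of the central-half truncated standard normal
  cc <- qnorm(0.75)
  trunc_var <- integrate(function(z) z^2 * dnorm(z), -cc, cc)$value / 0.5
  expect_equal(consistency_factor(1000, 1, 500), 1 / trunc_var,
               tolerance = 1e-6)
})

test_that("outlyingness is the bounded strictly-increasing transform", {
  expect_equal(outlyingness(c(0, 1, 3)), c(0, 0.5, 0.75))
  m <- sort(runif(50, 0, 20))
  r <- outlyingness(m)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r < 1))
  expect_error(outlyingness(-0.1), "nonnegative")
})

test_that("simulated threshold matches the analytic 1-D folded-normal quantile", {
  est <- list(mu = 0, sigma = matrix(1, 1, 1))
  thr <- simulate_threshold(est, n = 1000, eps = 0.99, n_sims = 100, seed = 4)
  analytic <- 1 - 1 / (1 + qnorm(0.995))  # 0.99 quantile of |Z| through r
  expect_equal(thr, analytic, tolerance = 0.01)
  # threshold is deterministic per seed
  expect_identical(
    thr, simulate_threshold(est, n = 1000, eps = 0.99, n_sims = 100, seed = 4)
  )
})

test_that("flags are invariant under joint affine rescaling", {
  X <- rmvn_fixture(100, 4, seed = 17, contaminate = 4)
  fm <- fast_mcd(X, alpha = 0.8, seed = 5)
  r1 <- outlyingness(mahalanobis_distances(X, fm$mu, fm$sigma))
  # rescale data and estimates consistently: distances are unchanged
  A <- diag(c(2, 0.5, 3, 10))
  b <- c(1, -2, 0, 5)
  Xt <- sweep(X %*% A, 2, b, "+")
  r2 <- outlyingness(
    mahalanobis_distances(Xt, as.numeric(fm$mu %*% A) + b, t(A) %*% fm$sigma %*% A)
  )
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("corr-max contributions conserve the squared distance", {
  withr::with_seed(23, {
    worst <- 0
    for (k in 1:250) {
      p <- sample(2:6, 1)
      A <- matrix(rnorm(p * p), p)
      sigma <- crossprod(A) + diag(p) * 0.1
      mu <- rnorm(p)
      X <- MASS::mvrnorm(5, mu = mu, Sigma = sigma)
      est <- list(mu = mu, sigma = sigma)
      W <- corr_max_contributions(X, est)
      m2 <- mahalanobis_distances(X, mu, sigma)^2
      worst <- max(worst, max(abs(rowSums(W^2) - m2)))
    }
    expect_lt(worst, 1e-6)
  })
  # identity scatter: contributions are the plain deviations
  est <- list(mu = c(0, 0), sigma = diag(2))
  W <- corr_max_contributions(rbind(c(3, 4)), est)
  expect_equal(as.numeric(W), c(3, 4))
  expect_equal(sum(W^2), 25)
})

test_that("detect_mcd flags gross outliers and names the erroneous variable", {
  X <- rmvn_fixture(100, 5, seed = 29)
  X[17, 3] <- X[17, 3] + 20
  det <- detect_mcd(as_qc_df(X), seed = 3)
  expect_true(det$result$flag[17])
  tc <- top_contributions(det, top = 1)
  expect_identical(tc$variable[tc$id == "P017"], "v3")
  # tidy/glance interfaces
  expect_identical(tidy(det), det$result)
  g <- glance(det)
  expect_identical(g$n_flagged, sum(det$result$flag))
  expect_identical(g$h, compute_h(100, 5, 0.8))
})

test_that("detection results are reproducible from data, params and seed", {
  co <- generate_cohort(cohort_spec(n = 60, n_pairs = 3, n_blocks = 1, seed = 2))
  prep <- qc_prepare(co$data)
  d1 <- detect_mcd(prep, seed = 10)
  d2 <- detect_mcd(prep, seed = 10)
  expect_identical(d1$result, d2$result)
  expect_identical(d1$threshold, d2$threshold)
})
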