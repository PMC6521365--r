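# Fast minimum covariance determinant (MCD) estimation, Mahalanobis-distance
# outlyingness with Monte-Carlo thresholds, and corr-max variable
# contributions.

#' Subset size for the MCD
#'
#' Computes the number of observations `h` retained by the MCD from the
#' robustness parameter `alpha`:
#' `h = floor(2*floor((n+p+1)/2) - n + 2*alpha*(n - floor((n+p+1)/2)))`.
#' `alpha = 0.5` gives the most robust (smallest) subset
#' `floor((n+p+1)/2)`; `alpha = 1` keeps all `n` observations.
#'
#' @param n Number of observations.
#' @param p Number of variables.
#' @param alpha Robustness parameter in `[0.5, 1]`; smaller values discard
#'   more observations (more robust, less efficient).
#' @return Integer subset size.
#' @examples
#' compute_h(161, 53, 0.8)
#' @export
compute_h <- function(n, p, alpha) {
  stopifnot(alpha >= 0.5, alpha <= 1)
  if (n <= p) {
    abort("MCD requires more observations than variables (n > p)")
  }
  hmin <- floor((n + p + 1) / 2)
  h <- floor(2 * hmin - n + 2 * alpha * (n - hmin))
  as.integer(h)
}

#' Mahalanobis distances
#'
#' Distance of each row of `X` from `mu` in the metric of `sigma`:
#' `m_i = sqrt((x_i - mu)' sigma^{-1} (x_i - mu))`, computed through the
#' Cholesky factor of `sigma` rather than an explicit inverse.
#'
#' @param X Numeric matrix (rows = observations).
#' @param mu Location vector, length `ncol(X)`.
#' @param sigma Positive-definite scatter matrix.
#' @return Nonnegative numeric vector of length `nrow(X)`.
#' @export
mahalanobis_distances <- function(X, mu, sigma) {
  X <- as.matrix(X)
  sigma <- as.matrix(sigma)
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) {
    d <- sqrt(diag(as.matrix(sigma)))
    d[d == 0] <- 1
    corr <- as.matrix(sigma) / outer(d, d)
    near <- which(abs(corr) > 0.999 & row(corr) < col(corr), arr.ind = TRUE)
    hint <- if (nrow(near)) {
      paste0("; near-collinear pairs: ",
             paste(apply(near, 1L, function(ij) {
               paste(colnames(X)[ij], collapse = "~")
             }), collapse = ", "))
    } else ""
    abort(paste0("scatter matrix is singular", hint))
  }
  Z <- forwardsolve(t(R), t(sweep(X, 2L, mu)))
  sqrt(colSums(Z^2))
}

#' One concentration step (C-step)
#'
#' From the current subset's mean and covariance, computes the Mahalanobis
#' distance of every observation and returns the indices of the `h` closest.
#' Each step cannot increase the subset covariance determinant, which is what
#' drives the fast-MCD search downhill.
#'
#' @param X Data matrix.
#' @param subset Integer indices of the current subset (at least `p + 1`).
#' @param h Target subset size; defaults to `length(subset)`.
#' @return Integer vector of `h` row indices (ties broken by row order).
#' @export
c_step <- function(X, subset, h = length(subset)) {
  X <- as.matrix(X)
  if (length(subset) < ncol(X) + 1L) {
    abort("subset must contain at least p + 1 observations")
  }
  est <- subset_mean_cov(X, subset)
  if (!is.finite(log_det_psd(est$sigma))) {
    abort("degenerate start: singular subset covariance", class = "qc_degenerate_start")
  }
  m <- mahalanobis_distances(X, est$mu, est$sigma)
  sort(order(m)[seq_len(h)])
}

#' MCD consistency factor
#'
#' Multiplier `c0` that rescales the covariance of the retained `h`-subset so
#' the estimator is consistent for the true covariance under multivariate
#' normality: `c0 = (h/n) / P(chi2_{p+2} <= q)` with
#' `q = qchisq(h/n, p)`. Equals 1 when nothing is trimmed (`h = n`) and
#' exceeds 1 otherwise, inflating the too-small trimmed covariance.
#'
#' @inheritParams compute_h
#' @param h Retained subset size.
#' @return Positive scalar.
#' @export
consistency_factor <- function(n, p, h) {
  stopifnot(h <= n, 2 * h >= n + p - 1)
  frac <- h / n
  if (frac >= 1) return(1)
  frac / pchisq(qchisq(frac, df = p), df = p + 2)
}

#' Fast-MCD robust location and scatter
#'
#' Searches for the `h`-observation subset whose covariance has minimal
#' determinant. Random `(p+1)`-subsets are concentrated with two C-steps
#' each; the most promising candidates are then iterated to their fixed
#' points, and the global minimum-determinant subset defines the estimator.
#' The returned covariance is the subset MLE covariance multiplied by the
#' consistency factor `c0`.
#'
#' @param X Numeric matrix, `n > p`.
#' @param alpha Robustness parameter in `[0.5, 1]`.
#' @param n_starts Number of random `(p+1)`-starts (default 500).
#' @param max_subsets Upper cap on starts (default 100000).
#' @param seed Integer seed making the search reproducible.
#' @param n_keep Number of best candidates iterated to convergence.
#' @return A `qc_mcd_estimator`: list with `mu` (robust mean), `sigma`
#'   (c0-scaled robust covariance), `sigma_raw`, `h`, `alpha`, `c0`,
#'   `subset` (the h retained row indices), `log_det` and `det`
#'   (determinant of the raw subset covariance).
#' @export
fast_mcd <- function(X, alpha = 0.8, n_starts = 500L, max_subsets = 100000L,
                     seed = 1L, n_keep = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  h <- compute_h(n, p, alpha)
  n_starts <- min(as.integer(n_starts), as.integer(max_subsets))

  if (h == n) {
    subset <- seq_len(n)
    est <- subset_mean_cov(X, subset)
    return(new_mcd_estimator(est, subset, n, p, h, alpha))
  }

  concentrate <- function(subset, steps = Inf) {
    i <- 0
    repeat {
      new_subset <- c_step(X, subset, h = h)
      i <- i + 1
      if (identical(new_subset, subset) || i >= steps) return(new_subset)
      subset <- new_subset
    }
  }

  candidates <- withr::with_seed(seed, {
    out <- vector("list", n_starts)
    kept <- 0L
    for (s in seq_len(n_starts)) {
      subset <- NULL
      for (try in 1:25) {
        start <- sample.int(n, p + 1L)
        subset <- tryCatch(
          concentrate(start, steps = 3L),
          qc_degenerate_start = function(e) NULL
        )
        if (!is.null(subset)) break
      }
      if (!is.null(subset)) {
        kept <- kept + 1L
        out[[kept]] <- subset
      }
    }
    out[seq_len(kept)]
  })
  if (!length(candidates)) {
    abort("data rank-deficient: every random start gave a singular subset covariance")
  }

  lds <- vapply(candidates, function(s) log_det_psd(subset_mean_cov(X, s)$sigma),
                numeric(1))
  keep <- order(lds)[seq_len(min(n_keep, length(candidates)))]

  best <- NULL; best_ld <- Inf
  for (k in keep) {
    subset <- concentrate(candidates[[k]])
    ld <- log_det_psd(subset_mean_cov(X, subset)$sigma)
    if (ld < best_ld) {
      best <- subset; best_ld <- ld
    }
  }
  est <- subset_mean_cov(X, best)
  new_mcd_estimator(est, best, n, p, h, alpha)
}

new_mcd_estimator <- function(est, subset, n, p, h, alpha) {
  c0 <- consistency_factor(n, p, h)
  structure(
    list(
      mu = est$mu,
      sigma = c0 * est$sigma,
      sigma_raw = est$sigma,
      h = h, alpha = alpha, c0 = c0,
      subset = as.integer(subset),
      log_det = log_det_psd(est$sigma),
      det = det(est$sigma)
    ),
    class = "qc_mcd_estimator"
  )
}

#' @export
print.qc_mcd_estimator <- function(x, ...) {
  cat(sprintf(
    "<qc_mcd_estimator> h = %d, alpha = %.2f, c0 = %.4f, log det = %.4f\n",
    x$h, x$alpha, x$c0, x$log_det
  ))
  invisible(x)
}

#' Robust Mahalanobis distance outlyingness
#'
#' Maps distances to `[0, 1)` via `r = 1 - 1/(1 + m)`, a strictly increasing
#' transform that makes thresholds comparable across datasets.
#'
#' @param m Nonnegative distances.
#' @return Values in `[0, 1)`.
#' @export
outlyingness <- function(m) {
  if (any(m < 0)) abort("distances must be nonnegative")
  1 - 1 / (1 + m)
}

#' Monte-Carlo outlyingness threshold
#'
#' Simulates `n_sims` multivariate normal samples of size `n` from the robust
#' location/scatter, computes every simulated observation's outlyingness
#' against the same estimates, pools all `n_sims * n` values and returns
#' their `eps` empirical percentile. Under the null, observed outlyingness
#' above this threshold is expected for roughly a `1 - eps` fraction of
#' clean observations.
#'
#' @param estimator A `qc_mcd_estimator` (or any list with `mu`, `sigma`).
#' @param n Sample size per simulation.
#' @param eps Percentile in (0, 1), e.g. 0.99.
#' @param n_sims Number of simulated samples (default 100).
#' @param seed Integer seed.
#' @param pool Pool all simulated values (default) or take the percentile
#'   within each simulated sample and average.
#' @return Scalar threshold in `[0, 1)`.
#' @export
simulate_threshold <- function(estimator, n, eps = 0.99, n_sims = 100L,
                               seed = 1L, pool = TRUE) {
  stopifnot(eps > 0, eps < 1, n_sims >= 1)
  mu <- estimator$mu
  sigma <- as.matrix(estimator$sigma)
  p <- length(mu)
  withr::with_seed(seed, {
    per_sim <- lapply(seq_len(n_sims), function(s) {
      Z <- matrix(MASS::mvrnorm(n, mu = mu, Sigma = sigma), ncol = p)
      r <- outlyingness(mahalanobis_distances(Z, mu, sigma))
      if (pool) r else quantile(r, eps, names = FALSE)
    })
    vals <- unlist(per_sim)
    if (pool) quantile(vals, eps, names = FALSE) else mean(vals)
  })
}

#' Corr-max variable contributions
#'
#' Partitions each observation's squared robust Mahalanobis distance into
#' `p` per-variable terms. With `D = diag(1/sqrt(diag(sigma)))`, the
#' transformation `C = (D sigma D)^{-1/2} D` (symmetric matrix square root)
#' gives per-row contributions `w_i = C (x_i - mu)` satisfying
#' `sum_j w_ij^2 = m_i^2`. Among all such orthogonal partitions this one
#' maximizes the correlation between each variable and its contribution
#' column, so large `|w_ij|` point at the variables that drive the distance.
#'
#' @param X Data matrix.
#' @param estimator A `qc_mcd_estimator` (or list with `mu`, `sigma`).
#' @return `n x p` contribution matrix.
#' @export
corr_max_contributions <- function(X, estimator) {
  X <- as.matrix(X)
  mu <- estimator$mu
  sigma <- as.matrix(estimator$sigma)
  d <- diag(sigma)
  if (any(d <= 0)) abort("scatter matrix has nonpositive diagonal")
  Dm <- 1 / sqrt(d)
  corr <- sigma * outer(Dm, Dm)
  C <- inv_sqrt_sym(corr) %*% diag(Dm, nrow = length(Dm))
  W <- sweep(X, 2L, mu) %*% t(C)
  dimnames(W) <- dimnames(X)
  W
}

#' MCD outlier detection
#'
#' The full MCD pipeline: fast-MCD robust estimation, Mahalanobis distances
#' and their `[0,1)` outlyingness transform, a pooled Monte-Carlo percentile
#' threshold, and corr-max contributions naming the variables behind each
#' flag. Constant (zero-variance) variables are dropped from the estimation
#' with a warning since they make the covariance singular.
#'
#' @param prepared A `qc_prepared` object (or a data frame, which is
#'   prepared unadjusted first).
#' @param alpha Robustness parameter (study default 0.8).
#' @param eps Threshold percentile (study default 0.99).
#' @param n_sims Simulated null samples for the threshold (default 100).
#' @param n_starts Random starts for the fast-MCD search.
#' @param seed Integer seed controlling both search and threshold simulation.
#' @param pool Pooled (default) vs per-sample percentile thresholding.
#' @return A `qc_mcd` object with a per-participant `result` tibble
#'   (`id`, `distance`, `outlyingness`, `flag`), the `threshold`,
#'   `estimator`, `contributions` matrix and call parameters.
#' @export
detect_mcd <- function(prepared, alpha = 0.8, eps = 0.99, n_sims = 100L,
                       n_starts = 500L, seed = 1L, pool = TRUE) {
  if (is.data.frame(prepared)) prepared <- qc_prepare(prepared)
  stopifnot(inherits(prepared, "qc_prepared"))
  X <- qc_as_matrix(prepared$data)
  if (any(prepared$constant)) {
    warn(paste0(
      "dropping constant variables from MCD estimation: ",
      paste(names(prepared$constant)[prepared$constant], collapse = ", ")
    ))
    X <- X[, !prepared$constant, drop = FALSE]
  }
  est <- fast_mcd(X, alpha = alpha, n_starts = n_starts,
                  seed = derive_seed(seed, "mcd_search"))
  m <- mahalanobis_distances(X, est$mu, est$sigma)
  r <- outlyingness(m)
  thr <- simulate_threshold(est, n = nrow(X), eps = eps, n_sims = n_sims,
                            seed = derive_seed(seed, "threshold"),
                            pool = pool)
  flags <- r > thr
  W <- corr_max_contributions(X, est)
  structure(
    list(
      result = tibble::tibble(
        id = rownames(X), distance = m, outlyingness = r, flag = flags
      ),
      threshold = thr,
      estimator = est,
      contributions = W,
      params = list(alpha = alpha, eps = eps, n_sims = n_sims,
                    n_starts = n_starts, seed = seed, pool = pool,
                    adjusted = prepared$adjusted),
      method = "mcd"
    ),
    class = c("qc_mcd", "qc_detection")
  )
}

#' Ranked contributing variables for flagged participants
#'
#' @param x A `qc_mcd` or `qc_rpca` object.
#' @param top How many variables to keep per participant (default all).
#' @return Tibble `id`, `rank`, `variable`, `value` (corr-max term or sparse
#'   entry), for flagged participants only.
#' @export
top_contributions <- function(x, top = Inf) {
  UseMethod("top_contributions")
}

#' @export
top_contributions.qc_mcd <- function(x, top = Inf) {
  flagged <- x$result$id[x$result$flag]
  W <- x$contributions
  purrr::map_dfr(flagged, function(id) {
    w <- W[id, ]
    ord <- order(abs(w), decreasing = TRUE)
    k <- min(top, length(ord))
    tibble::tibble(
      id = id, rank = seq_len(k),
      variable = colnames(W)[ord[seq_len(k)]],
      value = unname(w[ord[seq_len(k)]])
    )
  })
}

#' @export
print.qc_detection <- function(x, ...) {
  cat(sprintf(
    "<qc_%s> %d of %d participants flagged (threshold %.4f%s)\n",
    x$method, sum(x$result$flag), nrow(x$result), x$threshold,
    if (isTRUE(x$params$adjusted)) ", covariate-adjusted" else ""
  ))
  invisible(x)
}
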