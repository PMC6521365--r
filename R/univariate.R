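# Per-variable comparators: the exact univariate MCD and 1.5*IQR boxplot
# fences. These measure what a variable-at-a-time screen would catch, for
# comparison with the multivariate detectors.

#' Univariate MCD outlier detection
#'
#' The one-variable specialization of the MCD. Because the
#' minimum-variance `h`-subset of a univariate sample is contiguous in sort
#' order, the exact estimator is found by scanning all `n - h + 1` windows of
#' length `h` over the sorted values and keeping the minimum-variance window.
#' The robust mean and `c0`-corrected variance give standardized distances
#' `|x - mu| / sigma`, mapped through the `[0,1)` outlyingness transform and
#' thresholded against pooled normal simulations (the 1-D case of
#' [simulate_threshold()]).
#'
#' @param x Numeric vector (no missing values).
#' @param alpha Robustness parameter, shared with the multivariate MCD.
#' @param eps Threshold percentile.
#' @param n_sims Simulated samples for the threshold.
#' @param seed Integer seed.
#' @return A `qc_umcd` object: list with `center`, `spread` (robust sd),
#'   `lower`, `upper` (the non-outlying range implied by the threshold),
#'   `threshold`, `flags`, `outlyingness`, `excluded` and `reason`.
#' @export
umcd_detect <- function(x, alpha = 0.8, eps = 0.99, n_sims = 100L, seed = 1L) {
  stopifnot(is.numeric(x), !anyNA(x), length(x) > 1)
  n <- length(x)
  h <- compute_h(n, 1L, alpha)
  ord <- order(x)
  xs <- x[ord]
  # minimum-variance contiguous window, MLE (1/h) variance
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  win_sum <- cs[h:n] - c(0, cs)[1:(n - h + 1)]
  win_sum2 <- cs2[h:n] - c(0, cs2)[1:(n - h + 1)]
  win_var <- win_sum2 / h - (win_sum / h)^2
  best <- which.min(win_var)
  subset <- sort(ord[best:(best + h - 1)])
  mu <- win_sum[best] / h
  c0 <- consistency_factor(n, 1L, h)
  v <- c0 * max(win_var[best], 0)
  if (v <= .Machine$double.eps) {
    return(structure(
      list(
        method = "umcd", center = mu, spread = 0,
        lower = NA_real_, upper = NA_real_, threshold = NA_real_,
        flags = rep(FALSE, n), outlyingness = rep(NA_real_, n),
        subset = subset, h = h, c0 = c0,
        excluded = TRUE,
        reason = "zero robust variance: all values in the concentrated subset are equal"
      ),
      class = "qc_umcd"
    ))
  }
  sigma <- sqrt(v)
  est <- list(mu = mu, sigma = matrix(v, 1, 1))
  # same derived threshold seed as the multivariate pipeline, so the p = 1
  # reduction is exact given a shared top-level seed
  thr <- simulate_threshold(est, n = n, eps = eps, n_sims = n_sims,
                            seed = derive_seed(seed, "threshold"))
  r <- outlyingness(abs(x - mu) / sigma)
  flags <- r > thr
  # invert r > thr into the distance bound |x - mu| / sigma > thr/(1-thr)
  m_thr <- thr / (1 - thr)
  structure(
    list(
      method = "umcd", center = mu, spread = sigma,
      lower = mu - m_thr * sigma, upper = mu + m_thr * sigma,
      threshold = thr, flags = flags, outlyingness = r,
      subset = subset, h = h, c0 = c0,
      excluded = FALSE, reason = NA_character_
    ),
    class = "qc_umcd"
  )
}

#' @export
print.qc_umcd <- function(x, ...) {
  if (x$excluded) {
    cat("<qc_umcd> excluded:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<qc_umcd> center %.3f, spread %.3f, range [%.3f, %.3f], %d flagged\n",
      x$center, x$spread, x$lower, x$upper, sum(x$flags)
    ))
  }
  invisible(x)
}

#' Boxplot-fence outlier detection
#'
#' Flags values strictly beyond the Tukey fences `Q1 - 1.5*IQR` and
#' `Q3 + 1.5*IQR`. Quartiles use linear interpolation of order statistics
#' (type-7 quantiles); the convention is recorded in the output because
#' fence positions depend on it.
#'
#' @param x Numeric vector, length at least 4.
#' @param k Fence multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()].
#' @return A `qc_boxplot` object: list with `q1`, `q3`, `iqr`, `lower`,
#'   `upper`, `flags`, `quantile_type`.
#' @export
boxplot_detect <- function(x, k = 1.5, type = 7) {
  stopifnot(is.numeric(x), !anyNA(x), length(x) >= 4)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = type)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  structure(
    list(
      method = "boxplot", q1 = q[1], q3 = q[2], iqr = iqr,
      lower = lower, upper = upper,
      flags = x < lower | x > upper,
      quantile_type = type
    ),
    class = "qc_boxplot"
  )
}

#' Run a univariate detector over every variable
#'
#' Applies [umcd_detect()] or [boxplot_detect()] to each measurement column
#' of a prepared dataset and collects bounds and flags in tidy form.
#'
#' @inheritParams detect_mcd
#' @param method `"umcd"` or `"boxplot"`.
#' @param ... Passed to the per-variable detector.
#' @return A `qc_univariate` object with `summary` (one row per variable:
#'   bounds, centers, exclusions, flag counts), `flags` (tibble `id`,
#'   `variable`, `value` for every flagged cell) and `details` (per-variable
#'   detector objects).
#' @export
detect_univariate <- function(prepared, method = c("umcd", "boxplot"), ...) {
  if (is.data.frame(prepared)) prepared <- qc_prepare(prepared)
  stopifnot(inherits(prepared, "qc_prepared"))
  method <- match.arg(method)
  X <- qc_as_matrix(prepared$data)
  fit_one <- function(j) {
    xj <- X[, j]
    if (method == "umcd") {
      if (prepared$constant[j]) {
        structure(list(
          method = "umcd", center = mean(xj), spread = 0,
          lower = NA_real_, upper = NA_real_, threshold = NA_real_,
          flags = rep(FALSE, nrow(X)), outlyingness = rep(NA_real_, nrow(X)),
          excluded = TRUE, reason = "constant variable"
        ), class = "qc_umcd")
      } else {
        umcd_detect(xj, ...)
      }
    } else {
      boxplot_detect(xj, ...)
    }
  }
  details <- lapply(seq_len(ncol(X)), fit_one)
  names(details) <- colnames(X)
  summary <- purrr::imap_dfr(details, function(d, v) {
    tibble::tibble(
      variable = v, method = method,
      center = if (method == "umcd") d$center else (d$q1 + d$q3) / 2,
      lower = d$lower, upper = d$upper,
      excluded = isTRUE(d$excluded),
      reason = if (isTRUE(d$excluded)) d$reason else NA_character_,
      n_flagged = sum(d$flags)
    )
  })
  flags <- purrr::imap_dfr(details, function(d, v) {
    idx <- which(d$flags)
    tibble::tibble(id = rownames(X)[idx], variable = v, value = X[idx, v])
  })
  structure(
    list(summary = summary, flags = flags, details = details,
         method = method, adjusted = prepared$adjusted),
    class = "qc_univariate"
  )
}

#' @export
print.qc_univariate <- function(x, ...) {
  cat(sprintf(
    "<qc_univariate:%s> %d variables, %d flagged cells across %d participants\n",
    x$method, nrow(x$summary), nrow(x$flags),
    length(unique(x$flags$id))
  ))
  invisible(x)
}
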