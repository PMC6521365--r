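# Internal helpers shared across detectors.

# Coerce a participants-by-variables data frame (first column = participant id)
# into a numeric matrix with rownames. Everything user-facing passes through
# here, so the id-column convention is enforced in one place.
qc_as_matrix <- function(data, id_col = 1L) {
  stopifnot(is.data.frame(data), ncol(data) >= 2L)
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    abort("participant ids must be unique")
  }
  vals <- data[, -id_col, drop = FALSE]
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num)) {
    abort(paste0(
      "non-numeric measurement columns: ",
      paste(names(vals)[not_num], collapse = ", ")
    ))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

qc_as_tibble <- function(m, id_name = "id") {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, id = rownames(m), .before = 1)
  names(out)[1] <- id_name
  out
}

# Subset mean and MLE (1/k) covariance, the convention used throughout the
# MCD code so that subset determinants are comparable across subset sizes.
subset_mean_cov <- function(X, idx) {
  Xs <- X[idx, , drop = FALSE]
  mu <- colMeans(Xs)
  Xc <- sweep(Xs, 2L, mu)
  sigma <- crossprod(Xc) / nrow(Xs)
  list(mu = mu, sigma = sigma)
}

# log-determinant via Cholesky; -Inf signals a (numerically) singular matrix.
log_det_psd <- function(sigma) {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  2 * sum(log(diag(R)))
}

# Symmetric inverse square root by eigendecomposition.
inv_sqrt_sym <- function(M, tol = 1e-12) {
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values < tol * max(e$values, 1))) {
    abort("matrix is not positive definite")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Draw a sub-seed below 2^31 deterministically from a parent seed and a label.
derive_seed <- function(seed, label) {
  withr::with_seed(seed + sum(utf8ToInt(label)), {
    sample.int(.Machine$integer.max - 1L, 1L)
  })
}
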