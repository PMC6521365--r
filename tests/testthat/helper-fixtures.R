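# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no stored data.

# small participants-by-variables data frame from a matrix
as_qc_df <- function(X, ids = sprintf("P%03d", seq_len(nrow(X)))) {
  colnames(X) <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  data.frame(id = ids, X, check.names = FALSE)
}

`%||%` <- rlang::`%||%`

# multivariate normal sample with a random correlated covariance
rmvn_fixture <- function(n, p, seed, contaminate = 0L, shift = 8) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p), p)
    sigma <- crossprod(A) / p + diag(p) * 0.5
    X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
    if (contaminate > 0) {
      rows <- seq_len(contaminate)
      X[rows, ] <- X[rows, ] + shift
    }
    X
  })
}

# Brute-force MCD: minimum determinant over all h-subsets (MLE covariance,
# matching the package convention). Only feasible for tiny n.
brute_force_mcd_det <- function(X, h) {
  combs <- utils::combn(nrow(X), h)
  min(apply(combs, 2L, function(s) {
    Xs <- X[s, , drop = FALSE]
    Xc <- sweep(Xs, 2L, colMeans(Xs))
    det(crossprod(Xc) / h)
  }))
}

# Brute-force univariate MCD: minimum variance over all h-subsets.
brute_force_umcd_var <- function(x, h) {
  combs <- utils::combn(length(x), h)
  min(apply(combs, 2L, function(s) {
    xs <- x[s]
    mean(xs^2) - mean(xs)^2
  }))
}

# rank-r background plus optional spiked entries
lowrank_fixture <- function(n, p, r, seed, spikes = NULL, magnitude = 10) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(n * r), n, r) %*% matrix(rnorm(r * p), r, p)
    if (!is.null(spikes)) {
      for (k in seq_len(nrow(spikes))) {
        L[spikes[k, 1], spikes[k, 2]] <- L[spikes[k, 1], spikes[k, 2]] +
          magnitude * sample(c(-1, 1), 1)
      }
    }
    L
  })
}
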