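# Robust principal component analysis: low-rank + sparse decomposition with a
# sparsity-target outer loop, orthogonal-distance outlyingness and S-based
# contributions.

#' Singular value soft-thresholding
#'
#' Shrinks every singular value of `M` by `t` (floored at zero) and
#' reconstructs. The result has nuclear norm no larger than the input's and
#' is the proximal operator of the nuclear norm — the low-rank update inside
#' principal component pursuit.
#'
#' @param M Numeric matrix.
#' @param t Nonnegative threshold.
#' @return Matrix of the same shape.
#' @export
singular_value_soft_threshold <- function(M, t) {
  stopifnot(t >= 0)
  if (t == 0) return(M)
  sv <- svd(M)
  d <- pmax(sv$d - t, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M), dimnames = dimnames(M)))
  out <- sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
  dimnames(out) <- dimnames(M)
  out
}

soft_threshold <- function(M, t) {
  sign(M) * pmax(abs(M) - t, 0)
}

#' Low-rank + sparse decomposition at a fixed lambda
#'
#' Solves the principal-component-pursuit program
#' `min ||L||_* + lambda ||S||_1  s.t.  X = L + S`
#' by the inexact augmented-Lagrangian iteration: alternate singular-value
#' soft-thresholding (updating the low-rank part `L`) with elementwise
#' soft-thresholding of the residual (updating the sparse part `S`), plus a
#' dual update that drives the reconstruction gap `X - L - S` to zero.
#'
#' @param X Numeric matrix with finite entries.
#' @param lam Positive sparsity weight; larger values give a sparser `S`.
#' @param tol Convergence tolerance on the max-entry reconstruction gap;
#'   default `1e-7 * ||X||_F`.
#' @param max_iter Iteration cap (default 500).
#' @return A `qc_rpca_decomposition`: list with `L`, `S`, `lambda`,
#'   `iterations`, `gap` (max-entry `|X - L - S|`), `converged`,
#'   `sparsity` (fraction of nonzero entries of `S`) and `rank_L`.
#' @export
rpca_decompose <- function(X, lam, tol = NULL, max_iter = 500L) {
  X <- as.matrix(X)
  stopifnot(all(is.finite(X)), lam > 0)
  normF <- sqrt(sum(X^2))
  tol <- tol %||% (1e-7 * max(normF, .Machine$double.eps))
  if (normF == 0) {
    return(new_rpca_decomposition(X, X, lam, 0L, 0, TRUE))
  }
  norm2 <- svd(X, nu = 0, nv = 0)$d[1]
  mu <- 1.25 / norm2
  mu_bar <- mu * 1e7
  rho <- 1.5
  Y <- X / max(norm2, max(abs(X)) / lam)
  S <- matrix(0, nrow(X), ncol(X))
  L <- S
  gap <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L <- singular_value_soft_threshold(X - S + Y / mu, 1 / mu)
    S <- soft_threshold(X - L + Y / mu, lam / mu)
    Z <- X - L - S
    gap <- max(abs(Z))
    if (gap <= tol) break
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
  }
  if (gap > tol) {
    warn(sprintf(
      "RPCA did not reach tol %.3g in %d iterations (gap %.3g)", tol, it, gap
    ))
  }
  dimnames(L) <- dimnames(S) <- dimnames(X)
  new_rpca_decomposition(L, S, lam, it, gap, gap <= tol)
}

new_rpca_decomposition <- function(L, S, lam, it, gap, converged) {
  structure(
    list(
      L = L, S = S, lambda = lam,
      iterations = it, gap = gap, converged = converged,
      sparsity = mean(S != 0),
      rank_L = qr(L)$rank
    ),
    class = "qc_rpca_decomposition"
  )
}

#' @export
print.qc_rpca_decomposition <- function(x, ...) {
  cat(sprintf(
    "<qc_rpca_decomposition> lambda = %.4g, rank(L) = %d, nnz(S) = %.2f%%, gap = %.2g\n",
    x$lambda, x$rank_L, 100 * x$sparsity, x$gap
  ))
  invisible(x)
}

#' Sparsity-targeted RPCA
#'
#' Repeats the fixed-lambda decomposition, moving `lambda` geometrically,
#' until the fraction of nonzero entries of `S` drops below the sparsity
#' target `tau`. The search starts at `lam0 = 1/sqrt(max(n, p))`, the
#' customary default weight; whenever the sparse part is still too dense the
#' l1 weight is strengthened by the factor `1/decay` and the decomposition is
#' rerun. A decomposition already meeting the target is returned immediately.
#'
#' @inheritParams rpca_decompose
#' @param tau Sparsity target in (0, 1): maximum allowed fraction of nonzero
#'   entries of `S` (study default 0.05).
#' @param lam0 Starting lambda; default `1/sqrt(max(n, p))`.
#' @param decay Geometric step in (0, 1); each outer loop multiplies lambda
#'   by `1/decay` (default 0.9, i.e. an ~11% strengthening per loop).
#' @param max_outer Cap on outer loops before giving up with diagnostics.
#' @return A `qc_rpca_decomposition` whose `sparsity < tau`, with the extra
#'   fields `n_outer` and `lambda_path`.
#' @export
rpca_with_sparsity_target <- function(X, tau = 0.05, lam0 = NULL, decay = 0.9,
                                      tol = NULL, max_iter = 500L,
                                      max_outer = 200L) {
  X <- as.matrix(X)
  stopifnot(tau > 0, tau <= 1, decay > 0, decay < 1)
  lam <- lam0 %||% (1 / sqrt(max(dim(X))))
  path <- numeric(0)
  for (k in seq_len(max_outer)) {
    dec <- rpca_decompose(X, lam, tol = tol, max_iter = max_iter)
    path <- c(path, lam)
    if (dec$sparsity < tau || tau >= 1) {
      dec$n_outer <- k
      dec$lambda_path <- path
      return(dec)
    }
    lam <- lam / decay
  }
  abort(sprintf(
    paste0(
      "sparsity target tau = %.3g not reached after %d lambda steps ",
      "(last lambda %.4g, sparsity %.3g)"
    ),
    tau, max_outer, lam, dec$sparsity
  ))
}

#' Orthogonal distances between decomposition layers
#'
#' Per participant (row): `o_xs = sum_j (x_ij - s_ij)^2`, the squared
#' distance between the observed data and the sparse part, and
#' `o_ls = sum_j (l_ij - s_ij)^2` between the low-rank and sparse parts.
#' Their ratio `o_ls / o_xs` is 1 for rows perfectly explained by the
#' low-rank structure (where `x = l`) and drifts away from 1 for rows whose
#' sparse entries absorb real deviation.
#'
#' @param X,L,S Matrices of identical shape.
#' @return Tibble with `o_xs`, `o_ls`, `ratio` (convention: ratio 1 when both
#'   distances are 0).
#' @export
orthogonal_distances <- function(X, L, S) {
  X <- as.matrix(X); L <- as.matrix(L); S <- as.matrix(S)
  stopifnot(all(dim(X) == dim(L)), all(dim(X) == dim(S)))
  o_xs <- rowSums((X - S)^2)
  o_ls <- rowSums((L - S)^2)
  ratio <- ifelse(o_xs == 0 & o_ls == 0, 1, o_ls / o_xs)
  tibble::tibble(o_xs = o_xs, o_ls = o_ls, ratio = ratio)
}

#' RPCA outlier detection
#'
#' The full RPCA pipeline: sparsity-targeted low-rank + sparse decomposition,
#' orthogonal distances, and a percentile rule on the deviation of the
#' distance ratio from 1. Rows whose `|ratio - 1|` reaches the `eps`
#' empirical percentile (type-7 quantile, inclusive at the threshold) are
#' flagged; each flagged row's nonzero sparse entries, ranked by absolute
#' magnitude, name its contributing variables.
#'
#' @inheritParams detect_mcd
#' @param tau Sparsity target (study default 0.05).
#' @param eps Percentile for the flagging rule (study default 0.90).
#' @param decay Lambda step factor of the outer loop.
#' @param orientation Which ratio deviates: `"ls_over_xs"` (default) uses
#'   `o_ls/o_xs`, `"xs_over_ls"` the reciprocal.
#' @return A `qc_rpca` object with a per-participant `result` tibble (`id`,
#'   `o_xs`, `o_ls`, `ratio`, `deviation`, `flag`), the `threshold`, the
#'   `decomposition` and call parameters.
#' @export
detect_rpca <- function(prepared, tau = 0.05, eps = 0.90, decay = 0.9,
                        orientation = c("ls_over_xs", "xs_over_ls")) {
  if (is.data.frame(prepared)) prepared <- qc_prepare(prepared)
  stopifnot(inherits(prepared, "qc_prepared"))
  orientation <- match.arg(orientation)
  X <- qc_as_matrix(prepared$data)
  dec <- rpca_with_sparsity_target(X, tau = tau, decay = decay)
  od <- orthogonal_distances(X, dec$L, dec$S)
  ratio <- if (orientation == "ls_over_xs") od$ratio else {
    ifelse(od$o_ls == 0 & od$o_xs == 0, 1, od$o_xs / od$o_ls)
  }
  deviation <- abs(ratio - 1)
  thr <- quantile(deviation, eps, names = FALSE, type = 7)
  flags <- deviation >= thr & deviation > 0
  structure(
    list(
      result = tibble::tibble(
        id = rownames(X), o_xs = od$o_xs, o_ls = od$o_ls,
        ratio = ratio, deviation = deviation, flag = flags
      ),
      threshold = thr,
      decomposition = dec,
      params = list(tau = tau, eps = eps, decay = decay,
                    orientation = orientation,
                    adjusted = prepared$adjusted),
      method = "rpca"
    ),
    class = c("qc_rpca", "qc_detection")
  )
}

#' @export
top_contributions.qc_rpca <- function(x, top = Inf) {
  flagged <- x$result$id[x$result$flag]
  S <- x$decomposition$S
  purrr::map_dfr(flagged, function(id) {
    s <- S[id, ]
    nz <- which(s != 0)
    if (!length(nz)) {
      return(tibble::tibble(id = character(), rank = integer(),
                            variable = character(), value = numeric()))
    }
    ord <- nz[order(abs(s[nz]), decreasing = TRUE)]
    k <- min(top, length(ord))
    tibble::tibble(
      id = id, rank = seq_len(k),
      variable = colnames(S)[ord[seq_len(k)]],
      value = unname(s[ord[seq_len(k)]])
    )
  })
}
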