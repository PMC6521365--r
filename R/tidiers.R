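# broom-style tidiers for fitted/detection objects.

#' @describeIn detect_mcd Per-participant tibble of distances, outlyingness
#'   and flags.
#' @param x A `qc_mcd` object.
#' @param ... Unused.
#' @method tidy qc_mcd
#' @export
tidy.qc_mcd <- function(x, ...) {
  x$result
}

#' @describeIn detect_rpca Per-participant tibble of orthogonal distances,
#'   ratio deviations and flags.
#' @param x A `qc_rpca` object.
#' @param ... Unused.
#' @method tidy qc_rpca
#' @export
tidy.qc_rpca <- function(x, ...) {
  x$result
}

#' @describeIn detect_mcd One-row model summary (h, alpha, c0, threshold,
#'   flag counts).
#' @method glance qc_mcd
#' @export
glance.qc_mcd <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$result),
    p = ncol(x$contributions),
    h = x$estimator$h,
    alpha = x$params$alpha,
    c0 = x$estimator$c0,
    log_det = x$estimator$log_det,
    eps = x$params$eps,
    threshold = x$threshold,
    n_flagged = sum(x$result$flag),
    adjusted = isTRUE(x$params$adjusted)
  )
}

#' @describeIn detect_rpca One-row summary (lambda, rank, sparsity,
#'   threshold, flag counts).
#' @method glance qc_rpca
#' @export
glance.qc_rpca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$result),
    p = ncol(x$decomposition$S),
    lambda = x$decomposition$lambda,
    n_outer = x$decomposition$n_outer %||% NA_integer_,
    rank_l = x$decomposition$rank_L,
    sparsity = x$decomposition$sparsity,
    tau = x$params$tau,
    eps = x$params$eps,
    threshold = x$threshold,
    n_flagged = sum(x$result$flag),
    adjusted = isTRUE(x$params$adjusted)
  )
}

#' @describeIn detect_univariate Per-variable tibble of bounds, exclusions
#'   and flag counts.
#' @param x A `qc_univariate` object.
#' @param ... Unused.
#' @method tidy qc_univariate
#' @export
tidy.qc_univariate <- function(x, ...) {
  x$summary
}

#' @describeIn compile_outlier_list Per-participant tibble with methods,
#'   counts and listing status.
#' @param x A `qc_report` object.
#' @param ... Unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::mutate(
    x$participants,
    methods = purrr::map_chr(.data$flagged_by, paste, collapse = ";")
  )
}

#' @describeIn compile_outlier_list One-row summary of the report.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$participants),
    n_flagged_any = sum(x$participants$n_methods > 0),
    n_listed = sum(x$participants$listed),
    min_flags = x$min_flags,
    n_methods = length(x$methods)
  )
}
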