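#' Residualize study variables on age, sex, and education
#'
#' Replaces each measurement column with the least-squares residuals from a
#' full-factorial linear model on age, a binary sex indicator, and years of
#' education (intercept, three main effects, three two-way interactions and
#' the three-way interaction: eight design columns). The model is fitted per
#' variable on the rows where that variable is observed; missing entries stay
#' missing. Covariate adjustment removes expected demographic structure so
#' that the downstream outlier detectors respond to deviations from the
#' cohort's covariance pattern rather than to age or education gradients.
#'
#' @param data Data frame; first column participant id, remaining columns
#'   numeric measurements (may contain `NA`).
#' @param covariates Data frame with columns `id`, `age` (years), `sex`
#'   (binary), `education` (years), one row per participant in `data`.
#' @param sex_level Value of `sex` coded as 1 when `sex` is not already
#'   numeric 0/1 (default: the second sorted unique level).
#'
#' @return A tibble of the same shape as `data` whose measurement columns are
#'   residuals.
#' @export
adjust_covariates <- function(data, covariates, sex_level = NULL) {
  X <- qc_as_matrix(data)
  cov_t <- check_covariates(covariates, rownames(X), sex_level)
  D <- model.matrix(~ age * sex * education, data = cov_t)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    abort(paste0(
      "covariate design matrix is rank deficient; collinear terms: ",
      paste(bad, collapse = ", ")
    ))
  }
  res <- X
  for (j in seq_len(ncol(X))) {
    obs <- !is.na(X[, j])
    if (sum(obs) <= ncol(D)) {
      abort(paste0(
        "variable ", colnames(X)[j], " has too few observed values (",
        sum(obs), ") to fit the 8-term covariate model"
      ))
    }
    fit <- stats::lm.fit(D[obs, , drop = FALSE], X[obs, j])
    res[obs, j] <- fit$residuals
  }
  out <- qc_as_tibble(res, id_name = names(data)[1])
  out
}

check_covariates <- function(covariates, ids, sex_level = NULL) {
  stopifnot(is.data.frame(covariates))
  need <- c("age", "sex", "education")
  if (!all(need %in% names(covariates))) {
    abort("covariates must contain columns: id, age, sex, education")
  }
  id_col <- if ("id" %in% names(covariates)) "id" else names(covariates)[1]
  cids <- as.character(covariates[[id_col]])
  if (!setequal(cids, ids) || anyDuplicated(cids)) {
    missing_ids <- setdiff(ids, cids)
    abort(paste0(
      "covariate ids do not match data ids",
      if (length(missing_ids)) paste0("; missing: ",
        paste(utils::head(missing_ids, 5), collapse = ", "))
    ))
  }
  cov_t <- covariates[match(ids, cids), , drop = FALSE]
  bad <- !complete.cases(cov_t[, need])
  if (any(bad)) {
    abort(paste0(
      "missing covariate values for ids: ",
      paste(utils::head(ids[bad], 10), collapse = ", ")
    ))
  }
  sex <- cov_t$sex
  if (!is.numeric(sex) || !all(sex %in% c(0, 1))) {
    lev <- sort(unique(as.character(sex)))
    if (length(lev) > 2) abort("sex must be binary")
    sex_level <- sex_level %||% lev[length(lev)]
    sex <- as.numeric(as.character(sex) == as.character(sex_level))
  }
  data.frame(age = as.numeric(cov_t$age), sex = sex,
             education = as.numeric(cov_t$education))
}

#' Mean-impute missing measurements
#'
#' Fills each missing cell with the mean of that variable's observed values
#' and records the imputed positions. After standardization an imputed cell
#' sits exactly at 0, so it cannot by itself drive a univariate flag.
#'
#' @inheritParams adjust_covariates
#' @return List with `data` (completed tibble) and `mask` (logical matrix of
#'   imputed positions).
#' @export
impute_missing <- function(data) {
  X <- qc_as_matrix(data)
  mask <- is.na(X)
  all_missing <- colSums(!mask) == 0L
  if (any(all_missing)) {
    abort(paste0(
      "variables entirely missing: ",
      paste(colnames(X)[all_missing], collapse = ", ")
    ))
  }
  if (any(mask)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(mask) > 0L)) {
      X[mask[, j], j] <- mu[j]
    }
  }
  list(data = qc_as_tibble(X, id_name = names(data)[1]), mask = mask)
}

#' Standardize measurements to zero mean and unit standard deviation
#'
#' Centers and scales are computed from observed (non-missing) values only,
#' using the sample (n-1) standard deviation. Constant variables are centered,
#' given scale 1 and flagged with a warning; they carry no outlier signal but
#' are retained so that boxplot summaries can still display them.
#'
#' @inheritParams adjust_covariates
#' @return List with `data` (standardized tibble), `centers`, `scales`
#'   (named numeric vectors) and `constant` (logical vector).
#' @export
standardize <- function(data) {
  X <- qc_as_matrix(data)
  centers <- colMeans(X, na.rm = TRUE)
  scales <- apply(X, 2L, sd, na.rm = TRUE)
  constant <- !is.na(scales) & scales < .Machine$double.eps^0.5
  constant[is.na(scales)] <- TRUE
  if (any(constant)) {
    warn(paste0(
      "constant variables standardized with scale 1: ",
      paste(colnames(X)[constant], collapse = ", ")
    ))
    scales[constant] <- 1
  }
  Z <- sweep(sweep(X, 2L, centers), 2L, scales, "/")
  list(
    data = qc_as_tibble(Z, id_name = names(data)[1]),
    centers = centers, scales = scales, constant = constant
  )
}

#' Prepare a dataset for outlier detection
#'
#' Runs the full preparation chain: optional covariate residualization (on
#' observed values), mean imputation, then standardization. The result is the
#' complete, zero-mean, unit-variance matrix every detector consumes.
#'
#' @inheritParams adjust_covariates
#' @param covariates Optional covariate table; when supplied and
#'   `adjust = TRUE` the variables are residualized first.
#' @param adjust Whether to residualize on the covariates.
#' @return A `qc_prepared` object: list with `data` (standardized tibble,
#'   id first), `mask` (imputed positions), `centers`, `scales`, `constant`,
#'   `adjusted`.
#' @export
qc_prepare <- function(data, covariates = NULL, adjust = !is.null(covariates),
                       sex_level = NULL) {
  if (adjust) {
    if (is.null(covariates)) abort("adjust = TRUE requires covariates")
    data <- adjust_covariates(data, covariates, sex_level = sex_level)
  }
  imp <- impute_missing(data)
  std <- standardize(imp$data)
  structure(
    list(
      data = std$data, mask = imp$mask,
      centers = std$centers, scales = std$scales,
      constant = std$constant, adjusted = adjust
    ),
    class = "qc_prepared"
  )
}

#' @export
print.qc_prepared <- function(x, ...) {
  m <- qc_as_matrix(x$data)
  cat(sprintf(
    "<qc_prepared> %d participants x %d variables (%s)\n",
    nrow(m), ncol(m), if (x$adjusted) "covariate-adjusted" else "unadjusted"
  ))
  cat(sprintf("  imputed cells: %d; constant variables: %d\n",
              sum(x$mask), sum(x$constant)))
  invisible(x)
}

#' Build adjusted and unadjusted prepared variants
#'
#' The evaluation process runs every multivariate detector on both the
#' covariate-adjusted and the unadjusted data; this helper produces the pair.
#' Without a covariate table only the unadjusted variant is returned.
#'
#' @inheritParams qc_prepare
#' @return Named list of `qc_prepared` objects: `adjusted` (when covariates
#'   are given) and `unadjusted`.
#' @export
prepare_variants <- function(data, covariates = NULL, sex_level = NULL) {
  out <- list(unadjusted = qc_prepare(data, adjust = FALSE))
  if (!is.null(covariates)) {
    out <- c(
      list(adjusted = qc_prepare(data, covariates, adjust = TRUE,
                                 sex_level = sex_level)),
      out
    )
  }
  out
}

# Serialize the preprocessing log (centers, scales, constant columns,
# imputation counts) for run records.
#' Preprocessing log as JSON
#'
#' @param prepared A `qc_prepared` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
preprocessing_log <- function(prepared, path = NULL) {
  stopifnot(inherits(prepared, "qc_prepared"))
  log <- list(
    adjusted = prepared$adjusted,
    centers = as.list(prepared$centers),
    scales = as.list(prepared$scales),
    constant_variables = names(prepared$constant)[prepared$constant],
    n_imputed = sum(prepared$mask),
    imputed_by_variable = as.list(colSums(prepared$mask))
  )
  json <- jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
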