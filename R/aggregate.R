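# Cross-method compilation of the verification list, the iterate-until-static
# evaluation loop, and parameter sensitivity sweeps.

#' Compile the cross-method outlier list
#'
#' Combines the four multivariate runs (MCD and RPCA, each adjusted and
#' unadjusted) into the single list handed over for verification. A
#' participant is listed when flagged by at least `min_flags` of the methods
#' (default 2 of 4): flags recurring across methods indicate more generally
#' deviant observations. Contributing variables are merged across methods by
#' interleaving each method's own ranking (rank 1 of every method first),
#' ties at a rank broken by absolute contribution value; per-method
#' provenance is kept.
#'
#' @param results Named list of `qc_mcd` / `qc_rpca` objects, e.g.
#'   `list(mcd_adj = ..., mcd_unadj = ..., rpca_adj = ..., rpca_unadj = ...)`.
#'   All must cover the identical participant set.
#' @param min_flags Minimum number of flagging methods for listing.
#' @param top Contributing variables retained per method when merging.
#' @return A `qc_report` object with `participants` (tibble: `id`,
#'   `flagged_by` list-column, `n_methods`, `listed`), `contributions`
#'   (tibble: `id`, `method`, `rank`, `variable`, `value`, `merged_rank`) and
#'   `min_flags`.
#' @export
compile_outlier_list <- function(results, min_flags = 2L, top = 5L) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  id_sets <- lapply(results, function(r) sort(r$result$id))
  if (length(unique(id_sets)) != 1L) {
    abort("detector results cover different participant sets")
  }
  ids <- results[[1]]$result$id
  flag_tbl <- purrr::imap_dfr(results, function(r, nm) {
    tibble::tibble(id = r$result$id, method = nm, flag = r$result$flag)
  })
  per_part <- flag_tbl |>
    dplyr::filter(.data$flag) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      flagged_by = list(sort(.data$method)),
      n_methods = dplyr::n(), .groups = "drop"
    )
  participants <- tibble::tibble(id = ids) |>
    dplyr::left_join(per_part, by = "id") |>
    dplyr::mutate(
      flagged_by = purrr::map(.data$flagged_by, ~ .x %||% character()),
      n_methods = dplyr::coalesce(.data$n_methods, 0L),
      listed = .data$n_methods >= min_flags
    )
  contribs <- purrr::imap_dfr(results, function(r, nm) {
    tc <- top_contributions(r, top = top)
    if (nrow(tc)) tc$method <- nm
    tc
  })
  listed_ids <- participants$id[participants$listed]
  contribs <- contribs |>
    dplyr::filter(.data$id %in% listed_ids) |>
    dplyr::arrange(.data$id, .data$rank, dplyr::desc(abs(.data$value))) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(merged_rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("id", "method", "rank", "variable", "value", "merged_rank")
  structure(
    list(participants = participants, contributions = contribs,
         min_flags = min_flags, methods = names(results)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d of %d participants listed (>= %d of %d methods)\n",
    sum(x$participants$listed), nrow(x$participants),
    x$min_flags, length(x$methods)
  ))
  invisible(x)
}

#' Listed participant ids
#'
#' @param report A `qc_report`.
#' @return Character vector of ids meeting the listing rule.
#' @export
listed_ids <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  report$participants$id[report$participants$listed]
}

apply_corrections <- function(data, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0L) {
    return(list(data = data, applied = corrections_tbl()))
  }
  stopifnot(all(c("id", "variable", "corrected_value") %in% names(corrections)))
  applied <- corrections_tbl()
  id_col <- names(data)[1]
  for (k in seq_len(nrow(corrections))) {
    cid <- as.character(corrections$id[k])
    cvar <- as.character(corrections$variable[k])
    row <- which(as.character(data[[id_col]]) == cid)
    if (length(row) != 1L || !cvar %in% names(data)) {
      abort(sprintf("correction %d targets unknown id/variable (%s, %s)",
                    k, cid, cvar))
    }
    old <- data[[cvar]][row]
    new <- corrections$corrected_value[k]
    data[[cvar]][row] <- new
    applied <- dplyr::bind_rows(applied, tibble::tibble(
      id = cid, variable = cvar, old = old, new = new
    ))
  }
  list(data = data, applied = applied)
}

corrections_tbl <- function() {
  tibble::tibble(id = character(), variable = character(),
                 old = numeric(), new = numeric())
}

#' One iteration of the data quality evaluation process
#'
#' Applies externally verified corrections (if any), prepares the adjusted
#' and unadjusted variants, runs both multivariate detectors on each, and
#' compiles the cross-method list. The process has converged when no
#' correction was applied this iteration (the dataset fingerprint is
#' unchanged) and the listed set equals the previous iteration's. Correction
#' decisions are a human verification step: the tool only applies what it is
#' given, never auto-corrects.
#'
#' @param data Raw participants-by-variables data frame (id first).
#' @param covariates Optional covariate table (enables the adjusted variants).
#' @param corrections Optional tibble/data frame with columns `id`,
#'   `variable`, `corrected_value` — the verified errors to fix before this
#'   iteration's detection pass.
#' @param prior The previous iteration's `qc_iteration` (or `NULL` for the
#'   first pass).
#' @param alpha,eps_mcd,n_sims,tau,eps_rpca,min_flags Detection parameters
#'   (study defaults).
#' @param seed Integer seed. By default every iteration reuses the same
#'   derived sub-seed, so that on unchanged data the detectors return the
#'   identical flag set and the convergence check compares datasets, not
#'   Monte-Carlo noise; set `reseed_each_iteration = TRUE` to redraw the
#'   simulation seed every pass.
#' @param reseed_each_iteration Redraw the detector seed each iteration
#'   (default `FALSE`).
#' @return A `qc_iteration`: list with `iteration`, `data` (post-correction),
#'   `fingerprint`, `report`, `detections`, `corrections_applied`,
#'   `converged`.
#' @export
run_iteration <- function(data, covariates = NULL, corrections = NULL,
                          prior = NULL, alpha = 0.8, eps_mcd = 0.99,
                          n_sims = 100L, tau = 0.05, eps_rpca = 0.90,
                          min_flags = 2L, seed = 1L,
                          reseed_each_iteration = FALSE) {
  iteration <- if (is.null(prior)) 1L else prior$iteration + 1L
  corr <- apply_corrections(data, corrections)
  data <- corr$data
  fingerprint <- rlang::hash(data)
  iter_seed <- if (reseed_each_iteration) {
    derive_seed(seed, paste0("iteration", iteration))
  } else {
    derive_seed(seed, "iteration")
  }
  variants <- prepare_variants(data, covariates)
  detections <- list()
  for (v in names(variants)) {
    suffix <- if (v == "adjusted") "adj" else "unadj"
    detections[[paste0("mcd_", suffix)]] <- detect_mcd(
      variants[[v]], alpha = alpha, eps = eps_mcd, n_sims = n_sims,
      seed = iter_seed
    )
    detections[[paste0("rpca_", suffix)]] <- detect_rpca(
      variants[[v]], tau = tau, eps = eps_rpca
    )
  }
  report <- compile_outlier_list(detections, min_flags = min_flags)
  same_list <- !is.null(prior) &&
    setequal(listed_ids(report), listed_ids(prior$report))
  structure(
    list(
      iteration = iteration, data = data, fingerprint = fingerprint,
      report = report, detections = detections,
      corrections_applied = corr$applied,
      converged = nrow(corr$applied) == 0L && same_list,
      seed = iter_seed
    ),
    class = "qc_iteration"
  )
}

#' @export
print.qc_iteration <- function(x, ...) {
  cat(sprintf(
    "<qc_iteration %d> %d listed, %d corrections applied, converged: %s\n",
    x$iteration, length(listed_ids(x$report)),
    nrow(x$corrections_applied), x$converged
  ))
  invisible(x)
}

#' Parameter sensitivity sweep
#'
#' Reruns detection over a grid of the MCD robustness parameter `alpha` and
#' the RPCA percentile `eps_rpca`, recording how many participants each
#' method flags and how large the overlaps are. Used to understand how
#' threshold choices trade verification burden against sensitivity.
#'
#' @inheritParams run_iteration
#' @param alphas Numeric vector of `alpha` values.
#' @param eps_rpca_values Numeric vector of `eps_rpca` values.
#' @return Tidy tibble: one row per grid point and variant with columns
#'   `alpha`, `eps_rpca`, `variant`, `h`, `n_flagged_mcd`, `n_flagged_rpca`,
#'   `n_overlap`, `n_listed` (>= `min_flags` within the grid point's four
#'   runs when both variants exist, else the two runs).
#' @export
parameter_sweep <- function(data, covariates = NULL, alphas = 0.8,
                            eps_rpca_values = 0.90, eps_mcd = 0.99,
                            n_sims = 100L, tau = 0.05, min_flags = 2L,
                            seed = 1L) {
  stopifnot(length(alphas) >= 1, length(eps_rpca_values) >= 1)
  variants <- prepare_variants(data, covariates)
  n <- nrow(data)
  p_used <- vapply(variants, function(v) sum(!v$constant), integer(1))
  grid <- tidyr::expand_grid(alpha = alphas, eps_rpca = eps_rpca_values)
  purrr::pmap_dfr(grid, function(alpha, eps_rpca) {
    runs <- list()
    rows <- purrr::imap_dfr(variants, function(v, nm) {
      suffix <- if (nm == "adjusted") "adj" else "unadj"
      mcd <- detect_mcd(v, alpha = alpha, eps = eps_mcd, n_sims = n_sims,
                        seed = seed)
      rpca <- detect_rpca(v, tau = tau, eps = eps_rpca)
      runs[[paste0("mcd_", suffix)]] <<- mcd
      runs[[paste0("rpca_", suffix)]] <<- rpca
      tibble::tibble(
        alpha = alpha, eps_rpca = eps_rpca, variant = nm,
        h = mcd$estimator$h,
        n_flagged_mcd = sum(mcd$result$flag),
        n_flagged_rpca = sum(rpca$result$flag),
        n_overlap = sum(mcd$result$flag & rpca$result$flag)
      )
    })
    report <- compile_outlier_list(runs, min_flags = min_flags)
    rows$n_listed <- length(listed_ids(report))
    rows
  })
}

#' Write a verification report to CSV and JSON
#'
#' @param report A `qc_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param top Contributions per participant in the CSV.
#' @return The CSV tibble, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL, top = 5L) {
  stopifnot(inherits(report, "qc_report"))
  listed <- dplyr::filter(report$participants, .data$listed)
  csv <- listed |>
    dplyr::mutate(
      methods = purrr::map_chr(.data$flagged_by, paste, collapse = ";"),
      top_contributions = purrr::map_chr(.data$id, function(i) {
        cc <- dplyr::filter(report$contributions, .data$id == i)
        cc <- utils::head(cc, top)
        paste(sprintf("%s(%s)", cc$variable, cc$method), collapse = ";")
      })
    ) |>
    dplyr::select("id", "n_methods", "methods", "top_contributions")
  if (!is.null(csv_path)) utils::write.csv(csv, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- purrr::map(seq_len(nrow(listed)), function(k) {
      i <- listed$id[k]
      cc <- dplyr::filter(report$contributions, .data$id == i)
      list(
        id = i, n_methods = listed$n_methods[k],
        methods = listed$flagged_by[[k]],
        contributions = purrr::map(seq_len(nrow(cc)), function(j) {
          list(variable = cc$variable[j], method = cc$method[j],
               value = cc$value[j])
        })
      )
    })
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}
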