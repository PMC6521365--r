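# Synthetic cohort generation and ground-truth error injection. The
# generator emulates the statistical structure of neuropsychology- and
# gait-style study tables: strongly correlated raw/transformed score pairs,
# blocks of correlated task variables, and covariate-dependent means. The
# injector plants the three error mechanisms encountered in practice so that
# detector sensitivity can be scored against a known error log.

#' Specification of a synthetic cohort
#'
#' @param n Number of participants (default 161).
#' @param n_pairs Number of raw/transformed variable pairs (default 8). The
#'   transformed member is a monotone (linear) function of the raw member
#'   plus noise calibrated to the target correlation.
#' @param pair_correlation Target within-pair correlation (default 0.9).
#' @param n_blocks Number of task blocks of mutually correlated variables,
#'   e.g. per-walk gait summaries (default 2).
#' @param block_size Variables per block (default 6).
#' @param block_correlation Within-block correlation (default 0.8).
#' @param covariate_effects List with numeric `age`, `sex`, `education`
#'   coefficients applied to every variable mean, on the standardized
#'   variable scale per unit of centered covariate.
#' @param noise_sd Residual standard deviation of each raw/block variable on
#'   the standardized scale (before the variable's own location/scale are
#'   applied).
#' @param pair_raw_mean,pair_raw_sd Location and scale of raw pair scores
#'   (defaults 30 and 5, a raw-test-score scale).
#' @param block_mean,block_sd Location and scale of block variables
#'   (defaults 60 and 3, a per-walk gait-summary scale with a ~5%
#'   coefficient of variation). The nonzero
#'   location is what makes multiplicative miscount errors visible: a
#'   `(s±1)/s` rescaling shifts every block variable by a coherent fraction
#'   of its mean.
#' @param age_mean,age_sd,age_range Age distribution: normal, truncated.
#' @param education_mean,education_sd,education_min Education distribution.
#' @param male_fraction Bernoulli probability of `sex = 1`.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 161L, n_pairs = 8L, pair_correlation = 0.9,
                        n_blocks = 2L, block_size = 6L,
                        block_correlation = 0.8,
                        covariate_effects = list(age = -0.03, sex = 0.4,
                                                 education = 0.05),
                        noise_sd = 1,
                        pair_raw_mean = 30, pair_raw_sd = 5,
                        block_mean = 60, block_sd = 3,
                        age_mean = 68.72, age_sd = 7.42,
                        age_range = c(55, 85),
                        education_mean = 14.61, education_sd = 2.92,
                        education_min = 6,
                        male_fraction = 110 / 161,
                        seed = 1L) {
  stopifnot(n >= 2, n_pairs >= 0, n_blocks >= 0,
            pair_correlation > 0, pair_correlation < 1,
            block_correlation > 0, block_correlation < 1,
            noise_sd >= 0)
  structure(
    list(
      n = as.integer(n), n_pairs = as.integer(n_pairs),
      pair_correlation = pair_correlation,
      n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
      block_correlation = block_correlation,
      covariate_effects = covariate_effects, noise_sd = noise_sd,
      pair_raw_mean = pair_raw_mean, pair_raw_sd = pair_raw_sd,
      block_mean = block_mean, block_sd = block_sd,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      education_mean = education_mean, education_sd = education_sd,
      education_min = education_min,
      male_fraction = male_fraction, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  # inverse-CDF truncation keeps the draw count (and thus the RNG stream)
  # independent of the truncation bounds
  u <- runif(n)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# sd of a normal(mean, s) truncated to [lower, upper]
truncnorm_sd <- function(s, mean, lower, upper) {
  a <- (lower - mean) / s
  b <- (upper - mean) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  delta <- (pa - pb) / Z
  s * sqrt(1 + (apa - bpb) / Z - delta^2)
}

# parent sd such that the truncated draw has the target observed sd
trunc_parent_sd <- function(target_sd, mean, lower, upper) {
  if (truncnorm_sd(target_sd, mean, lower, upper) >= target_sd * 0.999) {
    return(target_sd)
  }
  stats::uniroot(
    function(s) truncnorm_sd(s, mean, lower, upper) - target_sd,
    interval = c(target_sd, 10 * target_sd), tol = 1e-8
  )$root
}

#' Generate a synthetic cohort
#'
#' Draws covariates (truncated-normal age and education, Bernoulli sex),
#' then builds `2*n_pairs + n_blocks*block_size` measurement variables:
#' each raw/pair variable is a linear function of the centered covariates
#' plus Gaussian noise; the transformed member of a pair is a monotone
#' linear map of its raw member plus noise sized so the within-pair
#' correlation hits the target; block variables share a latent factor giving
#' the target within-block correlation. Deterministic per seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `qc_cohort` list: `data` (tibble, `id` first), `covariates`
#'   (tibble `id`, `age`, `sex`, `education`), `pairs` (tibble `raw`,
#'   `transformed`, `slope`, `intercept`), `blocks` (named list of variable
#'   names), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    ids <- sprintf("P%03d", seq_len(n))
    # parent sds are inflated so the *observed* (post-truncation) sds match
    # the targets
    age_parent_sd <- trunc_parent_sd(spec$age_sd, spec$age_mean,
                                     spec$age_range[1], spec$age_range[2])
    edu_parent_sd <- trunc_parent_sd(spec$education_sd, spec$education_mean,
                                     spec$education_min, Inf)
    age <- rtruncnorm(n, spec$age_mean, age_parent_sd,
                      spec$age_range[1], spec$age_range[2])
    education <- rtruncnorm(n, spec$education_mean, edu_parent_sd,
                            lower = spec$education_min)
    sex <- stats::rbinom(n, 1L, spec$male_fraction)
    eff <- spec$covariate_effects
    cov_signal <- eff$age * (age - spec$age_mean) +
      eff$sex * (sex - spec$male_fraction) +
      eff$education * (education - spec$education_mean)

    cols <- list()
    pairs <- tibble::tibble(raw = character(), transformed = character(),
                            slope = numeric(), intercept = numeric())
    r <- spec$pair_correlation
    for (k in seq_len(spec$n_pairs)) {
      raw_name <- sprintf("pair%02d_raw", k)
      tr_name <- sprintf("pair%02d_tr", k)
      raw <- spec$pair_raw_mean +
        spec$pair_raw_sd * (cov_signal + rnorm(n, 0, spec$noise_sd))
      # transformed = slope*raw + intercept + e, sd(e) chosen so that
      # cor(raw, transformed) = r: r^2 = var(slope*raw)/var(transformed)
      slope <- 2
      intercept <- 10
      sd_raw <- max(sd(raw), .Machine$double.eps)
      sd_e <- abs(slope) * sd_raw * sqrt(1 / r^2 - 1)
      tr <- slope * raw + intercept + rnorm(n, 0, sd_e)
      cols[[raw_name]] <- raw
      cols[[tr_name]] <- tr
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        raw = raw_name, transformed = tr_name,
        slope = slope, intercept = intercept
      ))
    }
    blocks <- list()
    rho <- spec$block_correlation
    for (b in seq_len(spec$n_blocks)) {
      latent <- rnorm(n)
      nm <- sprintf("block%d_v%d", b, seq_len(spec$block_size))
      for (j in seq_len(spec$block_size)) {
        # equicorrelated construction: sqrt(rho)*latent + sqrt(1-rho)*noise,
        # scaled by noise_sd, plus the covariate signal
        z <- sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n)
        cols[[nm[j]]] <- spec$block_mean +
          spec$block_sd * (cov_signal + spec$noise_sd * z)
      }
      blocks[[sprintf("block%d", b)]] <- nm
    }
    data <- tibble::as_tibble(cols)
    data <- tibble::add_column(data, id = ids, .before = 1)
    structure(
      list(
        data = data,
        covariates = tibble::tibble(id = ids, age = age, sex = sex,
                                    education = education),
        pairs = pairs, blocks = blocks, spec = spec
      ),
      class = "qc_cohort"
    )
  })
}

#' @export
print.qc_cohort <- function(x, ...) {
  cat(sprintf(
    "<qc_cohort> %d participants, %d variables (%d pairs, %d blocks)\n",
    nrow(x$data), ncol(x$data) - 1L, x$spec$n_pairs, x$spec$n_blocks
  ))
  invisible(x)
}

empty_error_log <- function() {
  tibble::tibble(id = character(), variable = character(),
                 mechanism = character(), original = numeric(),
                 corrupted = numeric())
}

#' Inject ground-truth errors into a cohort
#'
#' Corrupts `k` distinct participants, one error event each, drawn from three
#' mechanisms:
#' \describe{
#'   \item{transcription}{a cell is replaced by another participant's value
#'     on the same variable (a database recording slip);}
#'   \item{transform_miscalc}{the transformed member of a raw/transformed
#'     pair is shifted so the cell stays inside that variable's boxplot
#'     fences yet breaks the pair relationship (its pair residual exceeds
#'     about 4 residual standard deviations) — invisible univariately,
#'     visible bivariately;}
#'   \item{block_miscount}{all variables of one block are rescaled by
#'     `(s ± 1)/s` for a plausible event count `s`, emulating a processing
#'     script miscounting steps and distorting every derived measure of the
#'     walk.}
#' }
#' When the inside-the-fences constraint of `transform_miscalc` cannot be
#' met within bounded retries the entry is logged with mechanism `"gross"`
#' and placed just outside the fences.
#'
#' @param cohort A `qc_cohort` from [generate_cohort()].
#' @param k Number of participants to corrupt (`k <= n`).
#' @param mechanisms Named weights over
#'   `c("transcription", "transform_miscalc", "block_miscount")`.
#' @param residual_sds Target pair-residual magnitude, in residual-sd units,
#'   for `transform_miscalc` (default 6; retries shrink toward a floor of 4
#'   when the fences leave no room).
#' @param step_counts Plausible event counts for `block_miscount`
#'   (default 12:24 steps per walk).
#' @param seed Integer seed.
#' @return List with `data` (corrupted tibble) and `log` (tibble: `id`,
#'   `variable`, `mechanism`, `original`, `corrupted`).
#' @export
inject_errors <- function(cohort, k,
                          mechanisms = c(transcription = 1,
                                         transform_miscalc = 1,
                                         block_miscount = 1),
                          residual_sds = 6,
                          step_counts = 12:24,
                          seed = 1L) {
  stopifnot(inherits(cohort, "qc_cohort"))
  data <- cohort$data
  n <- nrow(data)
  stopifnot(k >= 0, k <= n)
  if (k == 0) return(list(data = data, log = empty_error_log()))
  mech_names <- c("transcription", "transform_miscalc", "block_miscount")
  w <- setNames(rep(0, 3), mech_names)
  w[names(mechanisms)] <- mechanisms
  avail <- mech_names[w > 0]
  if ("transform_miscalc" %in% avail && nrow(cohort$pairs) == 0)
    avail <- setdiff(avail, "transform_miscalc")
  if ("block_miscount" %in% avail && length(cohort$blocks) == 0)
    avail <- setdiff(avail, "block_miscount")
  if (!length(avail)) abort("no applicable error mechanism for this cohort")

  withr::with_seed(seed, {
    victims <- sample.int(n, k)
    log <- empty_error_log()
    for (i in victims) {
      mech <- sample(avail, 1L, prob = w[avail])
      entry <- switch(mech,
        transcription = inject_transcription(data, i),
        transform_miscalc = inject_transform_miscalc(data, cohort$pairs, i,
                                                     residual_sds),
        block_miscount = inject_block_miscount(data, cohort$blocks, i,
                                               step_counts)
      )
      data <- entry$data
      log <- dplyr::bind_rows(log, entry$log)
    }
    list(data = data, log = log)
  })
}

inject_transcription <- function(data, i) {
  vars <- names(data)[-1]
  v <- sample(vars, 1L)
  old <- data[[v]][i]
  donor_pool <- setdiff(which(data[[v]] != old), i)
  if (!length(donor_pool)) donor_pool <- setdiff(seq_len(nrow(data)), i)
  donor <- if (length(donor_pool) == 1L) donor_pool else sample(donor_pool, 1L)
  new <- data[[v]][donor]
  if (new == old) new <- old + sd(data[[v]])
  data[[v]][i] <- new
  list(data = data, log = tibble::tibble(
    id = data$id[i], variable = v, mechanism = "transcription",
    original = old, corrupted = new
  ))
}

inject_transform_miscalc <- function(data, pairs, i, residual_sds = 6,
                                     max_tries = 20L, floor_sds = 4) {
  pk <- sample.int(nrow(pairs), 1L)
  raw <- data[[pairs$raw[pk]]]
  trv <- pairs$transformed[pk]
  tr <- data[[trv]]
  # estimate the pair relationship from the data itself (excluding row i)
  fit <- stats::lm.fit(cbind(1, raw[-i]), tr[-i])
  ab <- unname(fit$coefficients)
  sd_e <- sd(fit$residuals)
  fitted_i <- ab[1] + ab[2] * raw[i]
  old <- tr[i]
  # a candidate must sit inside the fences of the column as it will exist
  # after the substitution (with a small margin), so later fence
  # recomputation on the corrupted data cannot flag it
  inside <- function(cand) {
    tmp <- tr
    tmp[i] <- cand
    f <- boxplot_detect(tmp)
    margin <- 0.03 * (f$upper - f$lower)
    cand > f$lower + margin && cand < f$upper - margin
  }
  target <- NA_real_
  mech <- "transform_miscalc"
  mult <- residual_sds
  for (t in seq_len(max_tries)) {
    side <- sample(c(-1, 1), 1L)
    for (s in c(side, -side)) {
      cand <- fitted_i + s * mult * sd_e
      if (cand != old && inside(cand)) {
        target <- cand
        break
      }
    }
    if (!is.na(target)) break
    mult <- max(floor_sds, mult * 0.9)
  }
  if (is.na(target)) {
    mech <- "gross"
    f <- boxplot_detect(tr)
    target <- f$upper + 0.05 * (f$upper - f$lower + 1)
  }
  data[[trv]][i] <- target
  list(data = data, log = tibble::tibble(
    id = data$id[i], variable = trv, mechanism = mech,
    original = old, corrupted = target
  ))
}

inject_block_miscount <- function(data, blocks, i, step_counts) {
  b <- sample(names(blocks), 1L)
  vars <- blocks[[b]]
  s <- if (length(step_counts) == 1L) step_counts else sample(step_counts, 1L)
  factor <- (s + sample(c(-1L, 1L), 1L)) / s
  old <- vapply(vars, function(v) data[[v]][i], numeric(1))
  # derived task measures depend on the event count directly (counts, rates)
  # or inversely (per-event averages); a miscount therefore scales half the
  # block by (s±1)/s and the other half by its reciprocal, which is what
  # breaks the within-block correlation structure
  expo <- ifelse(seq_along(vars) %% 2L == 1L, 1, -1)
  new <- old * factor^expo
  same <- new == old
  new[same] <- old[same] + 1 / s  # zero cells still change under a miscount
  for (j in seq_along(vars)) data[[vars[j]]][i] <- new[j]
  list(data = data, log = tibble::tibble(
    id = data$id[i], variable = vars, mechanism = "block_miscount",
    original = unname(old), corrupted = unname(new)
  ))
}

#' Score detection against the ground-truth error log
#'
#' @param report A `qc_report` (or a single `qc_mcd`/`qc_rpca` detection,
#'   whose flags are treated as the listing).
#' @param log Error log from [inject_errors()].
#' @param n Total number of participants (taken from the report when absent).
#' @param contributions Optional contributions tibble (`id`, `variable`,
#'   `merged_rank` or `rank`) for the top-3 hit-rate; defaults to the
#'   report's own.
#' @param top Window for the contribution hit-rate (default 3).
#' @return One-row tibble: `n_injected`, `n_listed`, `n_hit`, `sensitivity`
#'   (erroneous participants listed / injected), `burden` (listed / n),
#'   `contribution_hit_rate` (share of detected erroneous participants whose
#'   erroneous variable appears in the top-`top` contributions; `NA` when no
#'   detections or no contributions available).
#' @export
score_detection <- function(report, log, n = NULL, contributions = NULL,
                            top = 3L) {
  if (inherits(report, "qc_detection")) {
    listed <- report$result$id[report$result$flag]
    n <- n %||% nrow(report$result)
    contributions <- contributions %||% top_contributions(report)
    if (nrow(contributions)) contributions$merged_rank <- contributions$rank
  } else {
    stopifnot(inherits(report, "qc_report"))
    listed <- listed_ids(report)
    n <- n %||% nrow(report$participants)
    contributions <- contributions %||% report$contributions
  }
  injected <- unique(log$id)
  hit <- intersect(injected, listed)
  hit_rate <- NA_real_
  if (length(hit) && nrow(contributions)) {
    rank_col <- if ("merged_rank" %in% names(contributions)) "merged_rank" else "rank"
    ok <- vapply(hit, function(i) {
      bad_vars <- log$variable[log$id == i]
      cc <- contributions[contributions$id == i, ]
      # per-method top window when per-method ranks are available
      if ("method" %in% names(cc) && "rank" %in% names(cc)) {
        any(cc$variable[cc$rank <= top] %in% bad_vars)
      } else {
        any(cc$variable[cc[[rank_col]] <= top] %in% bad_vars)
      }
    }, logical(1))
    hit_rate <- mean(ok)
  }
  tibble::tibble(
    n_injected = length(injected),
    n_listed = length(listed),
    n_hit = length(hit),
    sensitivity = if (length(injected)) length(hit) / length(injected) else NA_real_,
    burden = length(listed) / n,
    contribution_hit_rate = hit_rate
  )
}
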