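# Diagnostic plots: why was this participant flagged?

#' Scatterplot of contributing variables for a flagged participant
#'
#' Plots all participants on two variables (by default the flagged
#' participant's top-2 contributing variables) and marks the participant of
#' interest with a crossed circle. An optional third variable is rendered as
#' a colour gradient. This is the view that exposes pair-breaking errors:
#' a point that is typical on each axis individually but far off the
#' regression band of the bivariate cloud.
#'
#' @param detection A `qc_mcd` or `qc_rpca` object.
#' @param prepared The `qc_prepared` data the detection was run on.
#' @param id Flagged participant id.
#' @param x,y Variable names; default the participant's top-2 contributions.
#' @param z Optional third variable shown as colour.
#' @return A ggplot object.
#' @export
contribution_scatter <- function(detection, prepared, id,
                                 x = NULL, y = NULL, z = NULL) {
  stopifnot(inherits(detection, "qc_detection"))
  if (is.data.frame(prepared)) prepared <- qc_prepare(prepared)
  res <- detection$result
  if (!id %in% res$id) abort(sprintf("unknown participant id '%s'", id))
  if (!res$flag[res$id == id]) {
    abort(sprintf(
      "participant '%s' is not flagged; choose variables explicitly with x/y and a flagged id",
      id
    ))
  }
  if (is.null(x) || is.null(y)) {
    tc <- top_contributions(detection, top = 2L)
    tc <- tc[tc$id == id, ]
    if (nrow(tc) < 2) {
      abort("fewer than two contributing variables; supply x and y")
    }
    x <- x %||% tc$variable[1]
    y <- y %||% tc$variable[2]
  }
  df <- prepared$data
  for (v in c(x, y, z)) {
    if (!v %in% names(df)) abort(sprintf("variable '%s' not in dataset", v))
  }
  id_col <- names(df)[1]
  df$.__flagged <- df[[id_col]] == id
  state <- if (isTRUE(prepared$adjusted)) "adjusted" else "unadjusted"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data[[y]]))
  if (!is.null(z)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[z]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2, colour = "grey30")
  }
  p +
    ggplot2::geom_point(
      data = df[df$.__flagged, , drop = FALSE],
      shape = 13, size = 5, stroke = 1, colour = "red"
    ) +
    ggplot2::labs(
      x = paste0(x, " (", state, ")"),
      y = paste0(y, " (", state, ")"),
      title = sprintf("Participant %s (%s)", id, toupper(detection$method))
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of a variable with the univariate-MCD range overlaid
#'
#' Standard Tukey boxplot of one variable with the non-outlying range
#' identified by the univariate MCD drawn as bracket-style interval markers,
#' and optionally highlighted cells (e.g. values at which an error was
#' identified) as crossed circles. When the variable was excluded from the
#' univariate MCD (zero robust variance) the interval is omitted and the
#' reason annotated.
#'
#' @param prepared A `qc_prepared` object (or data frame).
#' @param variable Variable name.
#' @param umcd Optional `qc_umcd` for that variable; computed when absent.
#' @param highlight_ids Participant ids whose cells to mark.
#' @param ... Passed to [umcd_detect()] when `umcd` is absent.
#' @return A ggplot object.
#' @export
boxplot_with_ranges <- function(prepared, variable, umcd = NULL,
                                highlight_ids = character(), ...) {
  if (is.data.frame(prepared)) prepared <- qc_prepare(prepared)
  df <- prepared$data
  if (!variable %in% names(df)) {
    abort(sprintf("variable '%s' not in dataset", variable))
  }
  xv <- df[[variable]]
  id_col <- names(df)[1]
  umcd <- umcd %||% (if (sd(xv) > 0) umcd_detect(xv, ...) else NULL)
  plot_df <- tibble::tibble(value = xv, id = df[[id_col]])
  p <- ggplot2::ggplot(plot_df, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.35, outlier.shape = 1) +
    ggplot2::labs(x = variable, y = "standardized value") +
    ggplot2::theme_minimal()
  if (!is.null(umcd) && !umcd$excluded) {
    rng <- tibble::tibble(y = c(umcd$lower, umcd$upper))
    p <- p + ggplot2::geom_errorbar(
      data = rng,
      ggplot2::aes(x = "", ymin = .data$y, ymax = .data$y),
      width = 0.55, colour = "blue", linewidth = 0.7, inherit.aes = FALSE
    ) +
      ggplot2::annotate("text", x = 1.4, y = umcd$upper,
                        label = "uMCD range", colour = "blue", size = 3)
  } else {
    p <- p + ggplot2::labs(
      subtitle = "uMCD interval omitted (zero robust variance)"
    )
  }
  if (length(highlight_ids)) {
    hl <- plot_df[plot_df$id %in% highlight_ids, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = hl, ggplot2::aes(x = "", y = .data$value),
      shape = 13, size = 4, colour = "red", inherit.aes = FALSE
    )
  }
  p
}

#' @method autoplot qc_detection
#' @export
autoplot.qc_detection <- function(object, ...) {
  df <- object$result
  score <- if (object$method == "mcd") "outlyingness" else "deviation"
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data[[score]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag), size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(
      x = "participant index", y = score,
      title = sprintf("%s detection (threshold %.4f)",
                      toupper(object$method), object$threshold)
    ) +
    ggplot2::theme_minimal()
}
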