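#' Plot a simulated trajectory
#'
#' Faceted time courses of the requested model variables; the TIR1:IAA
#' panel shows the pre-hydrolysis baseline as a dashed reference line.
#'
#' @param object An `i3g_trajectory`.
#' @param vars Variables to show (default `tir1_iaa` and `iaa`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.i3g_trajectory <- function(object,
                                    vars = c("tir1_iaa", "iaa"), ...) {
  vars <- match.arg(vars, choices = state_vars, several.ok = TRUE)
  long <- tidy.i3g_trajectory(object)
  long <- long[long$species %in% vars, ]
  long$species <- factor(long$species, levels = vars)
  base <- attr(object, "baseline")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time, y = .data$concentration)) +
    ggplot2::geom_line(colour = "#1b6ca8") +
    ggplot2::facet_wrap(~species, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time after hydrolysis onset (min)",
                  y = "concentration (uM)") +
    ggplot2::theme_minimal()
  if (!is.null(base)) {
    ref <- tibble(species = factor(vars, levels = vars),
                  baseline = vapply(vars, function(v) base[[v]], numeric(1)))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$baseline),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a sweep result
#'
#' For a two-axis sweep (the MYR x I3G grid) draws a tile heatmap of
#' `metric`; for a one-axis sweep, a line-and-point plot of `metric`
#' against the axis (log-scaled for fold axes).
#'
#' @param object An `i3g_sweep`.
#' @param metric Metric column to display (default `"drop_amplitude"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.i3g_sweep <- function(object, metric = "drop_amplitude", ...) {
  stopifnot(metric %in% names(object))
  axes <- attr(object, "axes")
  df <- as_tibble(object)
  if (length(axes) == 2L) {
    return(
      ggplot2::ggplot(df, ggplot2::aes(
        x = factor(.data[[axes[1]]]), y = factor(.data[[axes[2]]]),
        fill = .data[[metric]])) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c() +
        ggplot2::labs(x = axes[1], y = axes[2], fill = metric) +
        ggplot2::theme_minimal()
    )
  }
  ax <- axes[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax]], y = .data[[metric]]))
  if (is.numeric(df[[ax]])) {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
    if (ax == "fold") p <- p + ggplot2::scale_x_log10()
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = ax, y = metric) + ggplot2::theme_minimal()
}

#' @rdname autoplot.i3g_sweep
#' @param sweep An `i3g_sweep` with `myr_fold` and `i3g_fold` axes.
#' @export
plot_heatmap <- function(sweep, metric = "drop_amplitude") {
  stopifnot(inherits(sweep, "i3g_sweep"),
            length(attr(sweep, "axes")) == 2L)
  autoplot.i3g_sweep(sweep, metric = metric)
}

#' @importFrom rlang .data
NULL
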