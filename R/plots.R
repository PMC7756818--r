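#' Plot element transects
#'
#' Concentration against the layer coordinate (if registered) or distance,
#' one panel per element, optionally faceted by specimen.
#'
#' @param data Transect tibble, raw or registered.
#' @param x_var Abscissa column; defaults to `ell` when present, else
#'   `distance_um`.
#' @return A ggplot object.
#' @export
plot_transect <- function(data, x_var = NULL) {
  if (is.null(x_var)) x_var <- if ("ell" %in% names(data)) "ell" else "distance_um"
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[x_var]], y = .data$conc_ppm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = if (x_var == "ell") "Growth layer coordinate (L1 ... D5)" else
        "Distance along transect (μm)",
      y = "Concentration (ppm)"
    ) +
    ggplot2::theme_minimal()
  facets <- intersect(c("element", "specimen_id"), names(data))
  if (length(facets)) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free_y")
  }
  if (x_var == "ell") {
    p <- p + ggplot2::geom_vline(xintercept = 0:10, linetype = "dotted",
                                 colour = "grey70")
  }
  p
}

#' Plot a breakpoint fit over its data
#'
#' @param object A `breakpoint_fit`.
#' @param x,y The data the model was fit to.
#' @param ... Unused.
#' @return A ggplot object with the data, the fitted piecewise-linear
#'   model and vertical lines at the breakpoint(s).
#' @method autoplot breakpoint_fit
#' @export
autoplot.breakpoint_fit <- function(object, x, y, ...) {
  df <- tibble::tibble(x = x, y = y)
  grid_x <- sort(unique(c(seq(min(x), max(x), length.out = 200), object$psi)))
  fit_df <- tibble::tibble(x = grid_x, y = predict(object, grid_x))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(data = fit_df, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "Growth layer coordinate", y = "Concentration (ppm)") +
    ggplot2::theme_minimal()
  if (object$n_breakpoints > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$psi, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot cumulative weaning distributions
#'
#' Step curves of the percentage of estimable animals weaned by the end of
#' each year of life, by element and method.
#'
#' @param cumulative A tibble from [cumulative_weaning_distribution()].
#' @return A ggplot object.
#' @export
plot_cumulative_weaning <- function(cumulative) {
  aes_args <- ggplot2::aes(x = .data$year, y = .data$pct_weaned_by)
  p <- ggplot2::ggplot(cumulative, aes_args)
  group_cols <- intersect(c("element", "method"), names(cumulative))
  if (length(group_cols)) {
    cumulative$series <- do.call(paste, c(cumulative[group_cols], sep = " / "))
    p <- ggplot2::ggplot(
      cumulative,
      ggplot2::aes(x = .data$year, y = .data$pct_weaned_by,
                   colour = .data$series)
    )
  }
  p +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Year of life", y = "% weaned by end of year",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
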