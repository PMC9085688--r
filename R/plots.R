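# Diagnostic plots.

#' Plot a landscape window
#'
#' Land-use parcels filled by class, linear elements as paths, optional
#' population nodes.
#'
#' @param window An [landscape_window()].
#' @param nodes Optional node tibble with `x`, `y`.
#' @return A ggplot object.
#' @export
plot_window <- function(window, nodes = NULL) {
  pd <- purrr::imap(window$parcels$geometry, function(g, i)
    tibble::tibble(x = g[, 1], y = g[, 2], id = i,
                   class = window$parcels$class[i]))
  pd <- dplyr::bind_rows(pd)
  ld <- purrr::imap(window$lines$geometry, function(g, i)
    tibble::tibble(x = g[, 1], y = g[, 2], id = i,
                   class = window$lines$class[i]))
  p <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$id, fill = .data$class),
                          colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_brewer(palette = "Set3") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = window$window_id, x = "x (m)", y = "y (m)")
  if (length(ld) > 0)
    p <- p + ggplot2::geom_path(
      data = dplyr::bind_rows(ld),
      ggplot2::aes(group = .data$id, colour = .data$class), linewidth = 0.4)
  if (!is.null(nodes))
    p <- p + ggplot2::geom_point(data = nodes, shape = 21, size = 3,
                                 fill = "white")
  p
}

#' Coefficient plot for a mixed-model fit
#'
#' @param object An `lg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lg_fit
#' @export
autoplot.lg_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "standardized coefficient", y = NULL)
}

#' Importance and averaged-coefficient plot for an averaged model
#'
#' @param object An `lg_avg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lg_avg
#' @export
autoplot.lg_avg <- function(object, ...) {
  co <- object$coefficients
  co <- co[co$term != "(Intercept)", ]
  co$reported <- co$importance >= object$importance_cutoff
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$importance))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error,
      colour = .data$reported)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey65"),
                                 name = "importance ≥ cutoff") +
    ggplot2::labs(x = "full-average standardized coefficient", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data .env
#' @keywords internal
NULL
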