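#' Heatmap of group-mean clonal expansion
#'
#' Subtype x group tile plot of mean expansion values (the heatmap companion
#' of [summarize_expansion()]). Raw means are shown without rescaling.
#'
#' @param object An `expansion_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expansion_summary
#' @export
autoplot.expansion_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$subtype,
                               fill = .data$mean_expansion)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_expansion)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1),
                                 name = "mean\nexpansion") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Clonal expansion by subtype and group") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.expansion_summary
#' @export
plot_expansion_heatmap <- function(object, ...) {
  autoplot.expansion_summary(object, ...)
}

#' Clonal transition network plot
#'
#' Subtypes on a circle; one edge per subtype pair and group, thickness
#' proportional to the group-mean transition value, with edges exclusive to
#' one group highlighted by color.
#'
#' @param object A [transition_network()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_network
#' @export
autoplot.transition_network <- function(object, ...) {
  groups <- attr(object, "groups")
  nodes <- sort(unique(c(object$subtype_a, object$subtype_b)))
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[seq_along(nodes)]
  layout <- tibble::tibble(subtype = nodes, x = cos(theta), y = sin(theta))
  long <- tidyr::pivot_longer(object,
                              cols = tidyr::starts_with("weight_"),
                              names_to = "group", names_prefix = "weight_",
                              values_to = "weight")
  long <- long[long$weight > 0, , drop = FALSE]
  long <- dplyr::left_join(long, layout, by = c(subtype_a = "subtype")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout, by = c(subtype_b = "subtype")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  long$highlight <- !is.na(long$exclusive_to) &
    long$exclusive_to == long$group
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = long,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = .data$weight,
                                       color = .data$highlight)) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$subtype), size = 3.2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey55",
                                           `TRUE` = "firebrick"),
                                labels = c(`FALSE` = "shared",
                                           `TRUE` = "group-exclusive"),
                                name = NULL) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5), name = "mean transition") +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Clonal transitions between subtypes")
}

#' @rdname autoplot.transition_network
#' @export
plot_transition_network <- function(object, ...) {
  autoplot.transition_network(object, ...)
}

#' Cells retained per QC stage
#'
#' @param object A `qc_report` from [run_qc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("stage", "cells_after")])
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$cells_after)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "cells retained",
                  title = "Quality-control attrition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35,
                                                       hjust = 1))
}
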