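#' Plot outlines
#'
#' Draws the closed outlines of one or more specimens with a fixed aspect
#' ratio, faceted or overlaid.
#'
#' @param outlines Outline tibble.
#' @param overlay If `TRUE`, overlay outlines coloured by specimen; otherwise
#'   facet.
#' @return A ggplot object.
#' @export
plot_outlines <- function(outlines, overlay = FALSE) {
  closed <- dplyr::bind_rows(
    outlines,
    outlines |> group_by(.data$specimen_id) |>
      dplyr::slice(1) |> ungroup() |> mutate(point = Inf))
  closed <- dplyr::arrange(closed, .data$specimen_id, .data$point)
  p <- ggplot2::ggplot(closed, ggplot2::aes(.data$x, .data$y,
                                            group = .data$specimen_id))
  p <- if (overlay) {
    p + ggplot2::geom_path(ggplot2::aes(colour = .data$specimen_id),
                           show.legend = FALSE)
  } else {
    p + ggplot2::geom_path() +
      ggplot2::facet_wrap(ggplot2::vars(.data$specimen_id))
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Score scatter of a PCA
#' @param object A `pip_pca`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pip_pca
#' @export
autoplot.pip_pca <- function(object, components = c(1, 2), ...) {
  cols <- paste0("PC", components)
  df <- object$scores
  lab <- sprintf("%s (%.1f%%)", cols, 100 * object$var_frac[components])
  aes <- if ("group" %in% names(df)) {
    ggplot2::aes(.data[[cols[1]]], .data[[cols[2]]], colour = .data$group)
  } else {
    ggplot2::aes(.data[[cols[1]]], .data[[cols[2]]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "group") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cross-validated confusion matrix
#' @param object A `pip_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pip_cv
#' @export
autoplot.pip_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true_group,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted group", y = "true group",
                  fill = "row %",
                  subtitle = sprintf("%.1f%% cross-validated correct",
                                     round_half_away(object$overall, 1))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of an unknown-group allocation
#' @param object A `pip_allocation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pip_allocation
#' @export
autoplot.pip_allocation <- function(object, ...) {
  df <- object$table
  df$group <- factor(df$group, levels = df$group)
  sub <- if (is.na(object$p_min)) "maximum-posterior allocation" else
    sprintf("posterior threshold p >= %.2f", object$p_min)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of unknown specimens", subtitle = sub) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the headline result of a run bundle
#' @param object A `pip_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pip_run
#' @export
autoplot.pip_run <- function(object, ...) {
  if (!is.null(object$threshold)) return(autoplot(object$threshold))
  if (!is.null(object$cv)) return(autoplot(object$cv))
  if (!is.null(object$pca)) return(autoplot(object$pca))
  abort("nothing to plot in this bundle")
}
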