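# ggplot2 views of trees and deformation tables.

#' Plot a centerline tree in an anatomical view
#'
#' Projects every branch polyline into the chosen view plane (axial x-y,
#' coronal x-z as seen from the front, sagittal y-z).
#'
#' @param object A [centerline_tree()].
#' @param view `"coronal"`, `"axial"` or `"sagittal"`.
#' @param colour Line colour, or `NULL` to colour by branch label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centerline_tree <- function(object, view = c("coronal", "axial",
                                                      "sagittal"),
                                     colour = NULL, ...) {
  view <- match.arg(view)
  axes <- switch(view, axial = c("x", "y"), coronal = c("x", "z"),
                 sagittal = c("y", "z"))
  df <- tidyr::unnest(
    dplyr::mutate(object$branches,
                  pts = purrr::map(.data$points, ~ tibble::as_tibble(
                    as.data.frame(.x))),
                  points = NULL),
    "pts")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[axes[1]]], y = .data[[axes[2]]],
    group = .data$id,
    colour = if (is.null(colour)) .data$label else NULL)) +
    ggplot2::geom_path(linewidth = 0.7,
                       colour = if (is.null(colour)) NULL else colour) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(axes[1], " (mm)"), y = paste0(axes[2], " (mm)"),
                  colour = "branch",
                  title = paste(view, "view")) +
    ggplot2::theme_minimal()
  p
}

#' Plot a deformation table
#'
#' Lollipop panels of the independent per-view angular deltas, the length
#' delta and the displacement norm per branch.
#'
#' @param object An [independent_deformations()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deformation_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "branch_label",
                  "dtheta_axial_deg", "dtheta_coronal_deg",
                  "dtheta_sagittal_deg", "dlength_mm", "d_norm_mm"),
    -"branch_label", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$branch_label)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-branch independent deformations") +
    ggplot2::theme_minimal()
}

#' Overlay two trees in one view
#'
#' Convenience comparison plot (e.g. collapsed vs modeled).
#'
#' @param a,b [centerline_tree()] objects.
#' @param names Labels for the two trees in the legend.
#' @inheritParams autoplot.centerline_tree
#' @return A ggplot object.
#' @export
plot_tree_pair <- function(a, b, names = c("a", "b"),
                           view = c("coronal", "axial", "sagittal")) {
  view <- match.arg(view)
  axes <- switch(view, axial = c("x", "y"), coronal = c("x", "z"),
                 sagittal = c("y", "z"))
  one <- function(tree, nm) {
    tidyr::unnest(
      dplyr::mutate(tree$branches,
                    pts = purrr::map(.data$points, ~ tibble::as_tibble(
                      as.data.frame(.x))),
                    points = NULL, tree = nm),
      "pts")
  }
  df <- dplyr::bind_rows(one(a, names[1]), one(b, names[2]))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[axes[1]]], y = .data[[axes[2]]],
    group = interaction(.data$tree, .data$id), colour = .data$tree)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(axes[1], " (mm)"), y = paste0(axes[2], " (mm)"),
                  colour = NULL, title = paste(view, "view")) +
    ggplot2::theme_minimal()
}
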