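# autoplot methods for volumetric results.

#' Axial-slice plot of a reconstructed image
#'
#' @param object A `dot_mua_image`.
#' @param z_mm Depths (mm) of the axial slices to show; default four slices
#'   through the brain.
#' @param col Image column (lag/condition index) to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dot_mua_image
#' @export
autoplot.dot_mua_image <- function(object, z_mm = NULL, col = 1, ...) {
  vs <- object$voxel_size_mm
  vol <- image_volume(object, col, fill = NA)
  if (is.null(z_mm)) {
    zr <- range(arrayInd(object$voxel_index, object$grid_shape)[, 3])
    z_mm <- round(seq(zr[1], zr[2], length.out = 4)) * vs - vs / 2
  }
  df <- purrr::map_dfr(z_mm, function(z) {
    k <- pmin(pmax(round(z / vs + 0.5), 1), object$grid_shape[3])
    sl <- vol[, , k]
    tibble::tibble(
      x_mm = rep((seq_len(nrow(sl)) - 0.5) * vs, times = ncol(sl)),
      y_mm = rep((seq_len(ncol(sl)) - 0.5) * vs, each = nrow(sl)),
      value = as.vector(sl),
      slice = paste0("z = ", round((k - 0.5) * vs), " mm")
    )
  })
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$value)),
                  ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95", high = "orange") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = if (identical(object$unit, "uM")) "dHbT (uM)" else "dmua (1/mm)") +
    ggplot2::theme_minimal()
}

#' Stimulus schedule plot
#' @param object A `dot_schedule`.
#' @param ... Unused.
#' @method autoplot dot_schedule
#' @export
autoplot.dot_schedule <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$onset_s,
                                   xmax = .data$onset_s + .data$duration_s,
                                   ymin = 0, ymax = 1,
                                   fill = .data$condition)) +
    ggplot2::geom_rect() +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "condition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
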