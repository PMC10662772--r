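raster_df <- function(pixels) {
  gray <- if (is_rgb(pixels)) luminance(pixels) else pixels
  tibble(
    x = rep(0:(ncol(gray) - 1L), each = nrow(gray)),
    y = rep(0:(nrow(gray) - 1L), times = ncol(gray)),
    intensity = as.vector(gray)
  )
}

#' Plot a page with detection boxes overlaid
#'
#' Shows the page raster (luminance) with detection rectangles; useful for
#' eyeballing detector behaviour on fixture pages.
#'
#' @param page A [page_raster()].
#' @param boxes Box tibble (expanded or not); optional.
#' @return A ggplot object.
#' @export
plot_detections <- function(page, boxes = NULL) {
  df <- raster_df(page$pixels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(
        xmin = .data$x0, xmax = .data$x1, ymin = .data$y0, ymax = .data$y1
      ),
      inherit.aes = FALSE, fill = NA, colour = "red", linewidth = 0.4
    )
  }
  p
}

#' Plot a mask map's labeled components
#'
#' Colors each connected component and annotates it with its truncated PR
#' and verdict when the component tibble has been classified.
#'
#' @param mask A [mask_map()].
#' @param components Optional classified tibble from [classify_components()].
#' @return A ggplot object.
#' @export
plot_mask_components <- function(mask, components = NULL) {
  if (is.null(components)) components <- label_components(mask)
  lab <- attr(components, "label_matrix")
  df <- tibble(
    x = rep(0:(ncol(lab) - 1L), each = nrow(lab)),
    y = rep(0:(nrow(lab) - 1L), times = ncol(lab)),
    label = as.vector(lab)
  )
  df <- df[df$label > 0L, ]
  df$label <- factor(df$label)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "component")
  if (!is.null(components$verdict) && !all(is.na(components$verdict))) {
    ann <- dplyr::mutate(components,
      cx = (.data$x0 + .data$x1) / 2, cy = (.data$y0 + .data$y1) / 2,
      txt = sprintf("PR %.3f\n%s", .data$pr_reported, .data$verdict)
    )
    p <- p + ggplot2::geom_text(
      data = ann,
      ggplot2::aes(x = .data$cx, y = .data$cy, label = .data$txt),
      inherit.aes = FALSE, size = 3
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a mask map
#'
#' @param object A [mask_map()].
#' @param ... Passed to [plot_mask_components()].
#' @return A ggplot object.
#' @export
autoplot.mask_map <- function(object, ...) plot_mask_components(object, ...)

#' Autoplot an extraction result
#'
#' @param object An `extraction_result`.
#' @param ... Unused.
#' @return A ggplot object showing the clean structure image.
#' @export
autoplot.extraction_result <- function(object, ...) {
  df <- raster_df(object$image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
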