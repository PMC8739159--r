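#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_path geom_point
#'   geom_segment coord_polar coord_equal labs theme_minimal
#' @export
ggplot2::autoplot

#' Rose plot of an angular histogram
#'
#' @param object An `angular_histogram` from [rose_histogram()].
#' @param ... Unused.
#' @return A ggplot object (polar bar chart of net migration directions).
#' @export
autoplot.angular_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_mid_deg, y = .data$count)) +
    geom_col(width = 360 / nrow(object), fill = "steelblue",
             colour = "grey30", linewidth = 0.2) +
    coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, by = 30)) +
    labs(x = "net migration direction (deg)", y = "tracks") +
    theme_minimal()
}

#' Plot nucleus tracks
#'
#' @param tracks Track tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param edge Optional [wound_edge()] drawn as a dashed line with its
#'   inward normal.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, edge = NULL) {
  p <- ggplot(tracks, aes(.data$x_um, .data$y_um,
                          group = .data$track_id)) +
    geom_path(alpha = 0.6, colour = "steelblue") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
  if (!is.null(edge)) {
    span <- max(diff(range(tracks$x_um)), diff(range(tracks$y_um)))
    a <- edge$point - span * edge$e
    b <- edge$point + span * edge$e
    p <- p + ggplot2::annotate("segment", x = a[1], y = a[2],
                               xend = b[1], yend = b[2],
                               linetype = "dashed") +
      ggplot2::annotate("segment", x = edge$point[1], y = edge$point[2],
                        xend = edge$point[1] + 0.1 * span * edge$n[1],
                        yend = edge$point[2] + 0.1 * span * edge$n[2],
                        arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm")),
                        colour = "firebrick")
  }
  p
}

#' Plot a monolayer polarity scene
#'
#' Nuclei as points, nucleus-to-Golgi polarity vectors as segments, and the
#' wound edge as a dashed line.
#'
#' @param object A `polarity_scene`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polarity_scene <- function(object, ...) {
  cells <- object$cells
  edge <- object$edge
  span <- max(object$config$field_um)
  a <- edge$point - span * edge$e
  b <- edge$point + span * edge$e
  ggplot(cells) +
    geom_segment(aes(x = .data$nx_um, y = .data$ny_um,
                     xend = .data$gx_um, yend = .data$gy_um),
                 colour = "firebrick",
                 arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    geom_point(aes(.data$nx_um, .data$ny_um), colour = "navy", size = 1) +
    ggplot2::annotate("segment", x = a[1], y = a[2], xend = b[1],
                      yend = b[2], linetype = "dashed") +
    coord_equal(xlim = c(0, object$config$field_um[1]),
                ylim = c(0, object$config$field_um[2])) +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Plot a vascular-front scene
#'
#' @param object A `front_scene`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.front_scene <- function(object, ...) {
  ggplot(object$front, aes(.data$x_um, .data$y_um)) +
    geom_path(linetype = "dashed") +
    geom_segment(data = object$tips,
                 aes(x = .data$x_um, y = .data$y_um,
                     xend = .data$x_um + 15 * .data$dir_x,
                     yend = .data$y_um + 15 * .data$dir_y),
                 colour = "firebrick",
                 arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    geom_point(data = object$tips, aes(.data$x_um, .data$y_um),
               colour = "navy") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Plot a retinal vessel mask
#'
#' @param object A `vessel_mask`.
#' @param ... Unused.
#' @return A ggplot object (raster of retina, vessels, avascular area).
#' @export
autoplot.vessel_mask <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$vessel)),
                           j = seq_len(ncol(object$vessel)))
  df$class <- "background"
  df$class[object$retina[cbind(df$i, df$j)]] <- "avascular"
  df$class[object$vessel[cbind(df$i, df$j)]] <- "vessel"
  ggplot(df, aes(.data$i, .data$j, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(background = "white",
                                          avascular = "grey85",
                                          vessel = "firebrick")) +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
}
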