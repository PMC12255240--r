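#' Plot a trial's force and moment channels
#'
#' @param object A `knee_trial` tibble.
#' @param channels Channels to display.
#' @param ... Unused.
#' @return A ggplot object (channels faceted over time).
#' @export
autoplot.knee_trial <- function(object,
                                channels = c("fz", "fy", "knee_flex_moment",
                                             "knee_add_moment"), ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("time", channels)],
                              -"time", names_to = "channel")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a joint load series
#'
#' Scaled medial contact force (BW) and knee moments (BW Ht) over time.
#' @param object A `joint_load_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_load_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("time", "mjcf_bw", "kam_bwht", "kfm_bwht")],
    -"time", names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "scaled load")
}

#' Plot a stitched ultrasound panorama
#'
#' @param object A `stitch_result`.
#' @param landmarks Optional landmark list overlaid as points.
#' @param ... Unused.
#' @return A ggplot object (raster of the panorama).
#' @export
autoplot.stitch_result <- function(object, landmarks = NULL, ...) {
  img <- object$panorama
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$intensity <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(landmarks)) {
    lm <- tibble(x = vapply(landmarks, `[`, numeric(1), 1),
                 y = vapply(landmarks, `[`, numeric(1), 2))
    p <- p + ggplot2::geom_point(data = lm, ggplot2::aes(x = .data$x, y = .data$y),
                                 inherit.aes = FALSE, colour = "red", shape = 3)
  }
  p
}
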