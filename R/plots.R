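#' Space-time plot of a cable record
#'
#' Raster of V(x, t) for 1D records (the classic space-time diagram on
#' which conduction and block at the border are read off), or a snapshot
#' sequence summary for 2D records.
#'
#' @param object a `space_time_record` with frames.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.space_time_record <- function(object, ...) {
  if (is.null(object$frames))
    abort("record has no frames; rerun with `frame_stride > 0`")
  geom <- object$geometry
  if (geom$ny == 1) {
    df <- tibble(
      x = rep((0:(geom$nx - 1)) * geom$h, times = ncol(object$frames)),
      t = rep(object$frame_times, each = geom$nx),
      V = as.vector(object$frames))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$t,
                                     fill = .data$V)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::geom_vline(xintercept = geom$border_x, linetype = "dashed",
                          colour = "white") +
      ggplot2::labs(x = "x (mm)", y = "time (ms)", fill = "V (mV)") +
      ggplot2::theme_minimal()
  } else {
    ks <- unique(round(seq(1, ncol(object$frames), length.out = 6)))
    df <- purrr::map_dfr(ks, function(k)
      tibble(x = rep((0:(geom$nx - 1)) * geom$h, times = geom$ny),
             y = rep((0:(geom$ny - 1)) * geom$h, each = geom$nx),
             V = object$frames[, k],
             t = sprintf("%g ms", object$frame_times[k])))
    df$t <- factor(df$t, levels = unique(df$t))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$V)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~t) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "V (mV)") +
      ggplot2::theme_minimal()
  }
}

#' Plot an APD restitution curve
#'
#' @param data a [restitution_curve()] tibble (optionally several bound
#'   together with a `label` column).
#' @return a ggplot object.
#' @export
plot_restitution <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$period,
                                          y = .data$apd90))
  if ("label" %in% names(data))
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  else p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  p + ggplot2::labs(x = "pacing period (ms)", y = "APD90 (ms)") +
    ggplot2::theme_minimal()
}
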