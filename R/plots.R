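#' Plot template topographies
#'
#' Point-based topographic maps of each template class on the montage's
#' head-plane coordinates (x = right, y = anterior), faceted by class.
#'
#' @param object an [ms_templates()].
#' @param montage electrode coordinates; defaults to [default_montage()]
#'   restricted to the template channels.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ms_templates <- function(object, montage = NULL, ...) {
  if (is.null(montage)) {
    montage <- montage_coords(default_montage(), object$channels)
  } else {
    montage <- montage_coords(montage, object$channels)
  }
  df <- tidy(object)
  df <- dplyr::left_join(df, montage, by = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white",
                                    high = "red") +
    ggplot2::facet_wrap(~class) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "a.u.", title = "Microstate templates")
}

#' Plot a GFP series with selected peaks
#'
#' @param object a `gfp_series` from [compute_gfp()].
#' @param peaks optional `gfp_peaks` from [select_gfp_peaks()] to overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gfp_series <- function(object, peaks = NULL, ...) {
  df <- tibble::tibble(time = (seq_along(object$values) - 1) / object$srate,
                       gfp = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$gfp)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "GFP (µV)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    pk <- tibble::tibble(time = (peaks$indices - 1) / peaks$srate,
                         gfp = object$values[peaks$indices])
    p <- p + ggplot2::geom_point(data = pk, colour = "red", size = 1)
  }
  p
}

#' Plot microstate parameters by class
#'
#' Bar panels of duration, coverage and occurrence per microstate class.
#'
#' @param object an `ms_params` from [compute_params()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ms_params <- function(object, ...) {
  df <- tidyr::pivot_longer(object$stats,
                            c("duration", "coverage", "occurrence"),
                            names_to = "parameter", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_name, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "class", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a microstate label sequence
#'
#' Colored segment ribbon over time; an optional GFP series is drawn above.
#'
#' @param object an [ms_labels()].
#' @param gfp optional `gfp_series` to overlay as a line.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ms_labels <- function(object, gfp = NULL, ...) {
  segs <- segments_of(object)
  segs$t0 <- (segs$start - 1) / object$srate
  segs$t1 <- segs$end / object$srate
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$t0, xmax = .data$t1,
                                    ymin = 0, ymax = 1,
                                    fill = .data$class_name)) +
    ggplot2::labs(x = "time (s)", fill = "class", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(gfp)) {
    gdf <- tibble::tibble(time = (seq_along(gfp$values) - 1) / gfp$srate,
                          v = gfp$values / max(gfp$values))
    p <- p + ggplot2::geom_line(data = gdf,
                                ggplot2::aes(x = .data$time, y = .data$v),
                                linewidth = 0.3)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
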