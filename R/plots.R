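# ggplot2 views of the result objects.

#' Plot per-class profile distributions
#'
#' Median line with the IQR as a ribbon and Tukey whiskers as a lighter
#' ribbon, per channel and growth stage — the box-plot-style summary of the
#' relative intensity along the long axis (left = brighter pole after
#' orientation).
#'
#' @param object A `profile_set` from [aggregate_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.profile_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$whisker_lo, ymax = .data$whisker_hi,
                                      fill = .data$channel), alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3,
                                      fill = .data$channel), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median, color = .data$channel)) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "position along long axis (fraction)",
                  y = "relative intensity") +
    ggplot2::theme_minimal()
}

#' Plot single-cell profiles as spaghetti lines
#'
#' @param profiles Pooled profile tibble (from `run_pipeline()$profiles`).
#' @param value_col Value column (default `"rel_intensity"`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, value_col = "rel_intensity") {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$position, y = .data[[value_col]],
                               group = interaction(.data$frame, .data$id, .data$channel),
                               color = .data$channel)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "position along long axis (fraction)",
                  y = "relative intensity") +
    ggplot2::theme_minimal()
}

#' Show a rendered scene channel with ground-truth boxes
#'
#' @param scene_render A `bact_scene`.
#' @param channel Channel name (default `"phase"`).
#' @return A ggplot object.
#' @export
plot_scene <- function(scene_render, channel = "phase") {
  img <- scene_render$frame[[channel]]
  if (is.null(img)) stop("no channel '", channel, "' in scene", call. = FALSE)
  df <- expand.grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$value <- as.vector(img)
  boxes <- scene_render$truth$boxes
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_rect(data = boxes, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    color = .data$label),
                       fill = NA, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
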