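#' Plot a TANOVA time course
#'
#' Observed global dissimilarity over time, with pointwise-significant
#' samples highlighted.
#'
#' @param object A `tanova_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tanova_result
#' @export
autoplot.tanova_result <- function(object, ...) {
  df <- tidy(object)
  df$significant <- df$p_value < object$alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$statistic)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        color = "firebrick", size = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "global dissimilarity (µV)",
                  title = sprintf("TANOVA: %s", object$effect),
                  subtitle = sprintf("%d permutations; red: p < %.2g",
                                     object$n_perm, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot GDS-corrected significance windows
#'
#' Shades every run of pointwise-significant samples and marks the runs
#' that survive the duration threshold.
#'
#' @param object A `gds_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gds_result
#' @export
autoplot.gds_result <- function(object, ...) {
  runs <- object$runs
  base <- ggplot2::ggplot() +
    ggplot2::xlim(range(object$times_ms)) +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = sprintf("GDS: %s", object$effect),
                  subtitle = sprintf("duration threshold %d samples (%.0f ms)",
                                     object$duration_threshold_samples,
                                     object$duration_threshold_ms)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (nrow(runs) == 0) return(base)
  runs$status <- ifelse(runs$surviving, "surviving", "not surviving")
  base +
    ggplot2::geom_rect(data = runs,
                       ggplot2::aes(xmin = .data$onset_ms, xmax = .data$offset_ms,
                                    ymin = 0, ymax = 1, fill = .data$status),
                       alpha = 0.7) +
    ggplot2::scale_fill_manual(values = c(surviving = "firebrick",
                                          `not surviving` = "grey70"))
}

#' Plot a scalp topography
#'
#' Basic topographic map: electrodes on the unit disc colored by voltage,
#' with a head outline.
#'
#' @param map Named channel vector (uV).
#' @param montage Montage tibble matching the map's channels.
#' @param label Plot title.
#' @return A ggplot object.
#' @export
plot_topography <- function(map, montage, label = NULL) {
  montage <- validate_montage(montage)
  df <- dplyr::mutate(montage, value = as.numeric(map[montage$channel]))
  theta <- seq(0, 2 * pi, length.out = 181)
  circle <- tibble::tibble(x = cos(theta), y = sin(theta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circle, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$value), size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2,
                       vjust = -1.4) +
    ggplot2::scale_color_gradient2(low = "navy", mid = "white",
                                   high = "firebrick", name = "µV") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = label, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
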