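# ggplot2 displays for the main result types.

#' Plot a colony image (optionally with its mask outline)
#'
#' @param x A `colony_image`, `colony_sim` or intensity matrix.
#' @param show_mask Overlay mask pixels when available.
#' @return A ggplot.
#' @export
plot_colony <- function(x, show_mask = TRUE) {
  ci <- as_colony_image(x)
  df <- tidyr::expand_grid(row = seq_len(nrow(ci$intensity)),
                           col = seq_len(ncol(ci$intensity)))
  df$intensity <- as.vector(ci$intensity)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "intensity")
  if (show_mask && !is.null(ci$mask) && any(ci$mask)) {
    md <- as.data.frame(which(ci$mask, arr.ind = TRUE))
    names(md) <- c("row", "col")
    p <- p + ggplot2::geom_point(data = md, colour = "red", size = 0.1,
                                 alpha = 0.4)
  }
  p
}

#' @export
autoplot.profile_fit <- function(object, ...) {
  df <- tibble::tibble(x = seq_along(object$profile),
                       profile = object$profile,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$profile), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "column (px)", y = "mean intensity",
                  title = sprintf("Gaussian fit: sigma = %.2f px",
                                  object$sigma))
}

#' @export
autoplot.clone_scores <- function(object, ci_threshold = 5, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::arrange(df, .data$ci)
  df$clone_id <- factor(df$clone_id, levels = df$clone_id)
  df$significant <- !is.na(df$p_vs_control) & df$p_vs_control <= 0.05
  ggplot2::ggplot(df, ggplot2::aes(.data$clone_id, .data$ci,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = ci_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Compactness Index (C.I.)",
                  fill = "p <= 0.05")
}

#' @export
autoplot.angle_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$bin_start + attr(object, "bin_width") / 2,
                               .data$frequency)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.95) +
    ggplot2::labs(x = "acute angle (degrees)", y = "frequency")
}

#' @export
autoplot.standard_curve <- function(object, ...) {
  df <- object$standards
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$cells), .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "log10(cells)", y = "Ct",
                  title = sprintf("slope %.3f, R^2 %.4f",
                                  object$slope, object$r_squared))
}

#' Plot cell tracks
#'
#' @param tracks Track tibble (`track_id`, `t`, `x`, `y`).
#' @return A ggplot of the paths, one colour per track.
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(tracks, ggplot2::aes(.data$x, .data$y,
                                       group = .data$track_id,
                                       colour = .data$track_id)) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
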