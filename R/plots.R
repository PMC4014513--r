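# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a similarity matrix with the matched diagonals
#'
#' Raster of the calibrated similarity matrix (tutor frames on the
#' vertical axis, pupil frames on the horizontal), with each tutor
#' syllable's matched diagonal overlaid.
#'
#' @param object An `si_match` produced with `keep_matrices = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot si_match
#' @export
autoplot.si_match <- function(object, ...) {
  if (is.null(object$matrices)) {
    stop("match was scored with keep_matrices = FALSE; re-run score_pair()",
         call. = FALSE)
  }
  S <- object$matrices$S
  df <- tidyr::expand_grid(tutor_ms = seq_len(nrow(S)),
                           pupil_ms = seq_len(ncol(S)))
  df$similarity <- as.numeric(S[cbind(df$tutor_ms, df$pupil_ms)])
  segs <- dplyr::mutate(object$syllables,
                        x = .data$j1, xend = .data$j2,
                        y = .data$s_frame, yend = .data$e_frame)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pupil_ms, y = .data$tutor_ms)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$similarity)) +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend),
      color = "red", linewidth = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "pupil time (ms)", y = "tutor time (ms)",
                  title = sprintf("acoustic %.2f | sequence %s | SI %.2f",
                                  object$acoustic,
                                  ifelse(is.na(object$sequence), "NA",
                                         sprintf("%.2f", object$sequence)),
                                  object$si)) +
    ggplot2::theme_minimal()
}

#' Plot feature tracks of a song
#'
#' @param features A feature tibble from [song_features()].
#' @param features_to_show Which features to facet (default all six).
#' @return A ggplot with one facet per feature over time.
#' @export
plot_features <- function(features, features_to_show = SI_FEATURES) {
  long <- tidyr::pivot_longer(
    features[, c("time_ms", intersect(features_to_show, names(features)))],
    -"time_ms", names_to = "feature", values_to = "value")
  long$feature <- factor(long$feature, levels = SI_FEATURES)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~feature, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-bird self- vs cross-similarity
#'
#' @param results A tibble from [self_cross_experiment()].
#' @return A ggplot of self vs cross SI per bird with the identity line.
#' @export
plot_contrast <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(.data$cross_si, .data$self_si,
                               label = .data$bird_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "cross-similarity (SI)", y = "self-similarity (SI)") +
    ggplot2::theme_minimal()
}
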