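#' Plot methods
#'
#' ggplot2 autoplot() methods for the package's result objects.
#'
#' @param object The object.
#' @param ... Unused.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.morf_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$step, .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "perturbation step", y = "accuracy",
                  title = paste0("Accuracy under ", object$order,
                                 "-order region replacement")) +
    ggplot2::ylim(0, 1)
}

#' Compare MoRF curves against the random baseline
#'
#' @param curves Named list of `morf_result`s.
#' @param baseline Optional random-order `morf_result`.
#' @return A ggplot.
#' @export
plot_morf_comparison <- function(curves, baseline = NULL) {
  df <- dplyr::bind_rows(lapply(names(curves), function(nm)
    dplyr::mutate(tidy(curves[[nm]]), method = nm)))
  if (!is.null(baseline))
    df <- dplyr::bind_rows(df, dplyr::mutate(tidy(baseline),
                                             method = "random"))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$accuracy,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "perturbation step", y = "accuracy")
}

#' @rdname plots
#' @export
autoplot.relevance_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$channel, .data$frame,
                                 fill = .data$relevance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("Relevance (%s, class %s)", object$rule,
                                  object$target_class),
                  x = "channel", y = "frame")
}

#' @rdname plots
#' @export
autoplot.sa_curve <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$frame, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = paste0("spatial average (", object$source, ")"))
}

#' Signal and relevance SA curves with event bands
#'
#' Overlays the spatially averaged signal, the relevance SA and the
#' detected cycle boundaries -- the standard reading view for peak-to-event
#' assignment.
#'
#' @param signal_sa,relevance_sa `sa_curve`s of the same window.
#' @param segmentation Optional [segment_cycles()] result.
#' @return A ggplot.
#' @export
plot_sa_overlay <- function(signal_sa, relevance_sa, segmentation = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tidy(signal_sa), curve = "signal",
                  value = .data$value / max(abs(.data$value))),
    dplyr::mutate(tidy(relevance_sa), curve = "relevance",
                  value = .data$value / max(abs(.data$value))))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$value,
                                        colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "normalized spatial average")
  if (!is.null(segmentation) && length(segmentation$cycle_boundaries))
    p <- p + ggplot2::geom_vline(xintercept = segmentation$cycle_boundaries,
                                 linetype = "dashed", alpha = 0.5)
  p
}

#' @rdname plots
#' @export
autoplot.gait_confusion <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$pred, .data$true,
                                 fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true")
}
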