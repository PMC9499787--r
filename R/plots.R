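# ggplot2 displays for the main result types.

#' Plot a pulse record
#'
#' @param object A `pulse_record`.
#' @param ... Unused.
#' @return A ggplot of pressure against time.
#' @export
autoplot.pulse_record <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time (s)", y = "Pressure (Pa)",
      title = attr(object, "source_id") %||% NULL,
      subtitle = attr(object, "label") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot detected fiducial points on a record
#'
#' @param record A (denoised, baseline-subtracted) `pulse_record`.
#' @param fiducials A `fiducial_points` for the same record; detected fresh
#'   when omitted.
#' @return A ggplot with the five fiducial point families marked.
#' @export
plot_fiducials <- function(record, fiducials = detect_fiducials(record)) {
  pts <- tidyr::pivot_longer(
    as_tibble(fiducials)[, c("beat", "b", "c", "e", "f", "g")],
    cols = c("b", "c", "e", "f", "g"),
    names_to = "point", values_to = "index"
  )
  pts <- pts[!is.na(pts$index), ]
  pts$time <- record$time[pts$index]
  pts$pressure <- record$pressure[pts$index]
  autoplot(record) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$time, y = .data$pressure, colour = .data$point),
      size = 2
    ) +
    ggplot2::labs(colour = "Fiducial")
}

#' Plot an IMF decomposition
#'
#' @param object An `imf_set`.
#' @param fs Sampling rate used for the time axis (samples when omitted).
#' @param ... Unused.
#' @return A faceted ggplot, one panel per IMF plus the residue.
#' @export
autoplot.imf_set <- function(object, fs = NULL, ...) {
  df <- tidy(object)
  df$x <- if (is.null(fs)) df$sample else df$sample / fs
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = if (is.null(fs)) "Sample" else "Time (s)", y = "Pa") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param object A `pulse_cnn`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and training accuracy.
#' @export
autoplot.pulse_cnn <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot heat map (rows = predicted, columns = true).
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
    fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "True class", y = "Predicted class", fill = "Count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
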