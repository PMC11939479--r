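#' Training-curve plot for a fitted model
#'
#' Loss, MAE, MSE and R-squared per epoch (train and, when available, test),
#' one panel per metric family.
#'
#' @param object a `landmark_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.landmark_fit <- function(object, ...) {
  long <- tidy(object)
  long$family <- sub("^(train|test)_", "", long$metric)
  long$split <- ifelse(grepl("^test_", long$metric), "test",
                       ifelse(grepl("^train_", long$metric), "train",
                              "train"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Group %d: %s head, %s loss",
                      object$config$group, object$config$head,
                      object$config$loss),
      x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay landmarks on an image
#'
#' Ground-truth and (optionally) predicted landmark positions over the
#' image, coloured by landmark group. Predictions are drawn as open circles
#' connected to their ground-truth points.
#'
#' @param image array `(h, w, 3)`, values 0--255.
#' @param landmarks a pixel-frame [landmark_set()] (ground truth).
#' @param predicted optional second [landmark_set()] (predictions).
#' @return A ggplot object.
#' @export
plot_landmarks <- function(image, landmarks, predicted = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  ras <- grDevices::as.raster(image / 255)
  df <- tibble::as_tibble(landmarks)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotation_raster(ras, xmin = -0.5, xmax = w - 0.5,
                               ymin = -(h - 0.5), ymax = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = -.data$y, colour = .data$group),
                        size = 1.4) +
    ggplot2::coord_fixed(xlim = c(-0.5, w - 0.5), ylim = c(-(h - 0.5), 0.5),
                         expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, colour = "group") +
    ggplot2::theme_void()
  if (!is.null(predicted)) {
    dp <- tibble::as_tibble(predicted)
    dp$x_true <- df$x; dp$y_true <- df$y
    gg <- gg +
      ggplot2::geom_segment(data = dp,
                            ggplot2::aes(x = .data$x_true, y = -.data$y_true,
                                         xend = .data$x, yend = -.data$y),
                            linewidth = 0.3, colour = "white") +
      ggplot2::geom_point(data = dp,
                          ggplot2::aes(y = -.data$y), shape = 1,
                          size = 1.8, colour = "white")
  }
  gg
}

#' R-squared comparison plot across experiment groups
#'
#' @param report tibble from [experiment_report()].
#' @return A ggplot object.
#' @export
plot_group_r2 <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = factor(.data$group), y = .data$test_r2,
                               fill = .data$head)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "experiment group", y = expression(R^2),
                  fill = "head") +
    ggplot2::theme_minimal()
}
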