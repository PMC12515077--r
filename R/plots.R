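#' @exportS3Method ggplot2::autoplot
autoplot.stat_map <- function(object, slices = NULL, ...) {
  stopifnot(!is.null(object$grid_dims))
  df <- tidy(object)
  if (is.null(slices)) {
    slices <- unique(round(seq(1, object$grid_dims[3], length.out = 6)))
  }
  df <- dplyr::filter(df, .data$z %in% slices)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "grey95",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("t map (df = ", round(object$df, 1), ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.erd_map <- function(object, channel = object$channel_names[1], ...) {
  ci <- match(channel, object$channel_names)
  df <- tidyr::expand_grid(f = seq_along(object$freqs),
                           t = seq_along(object$times)) |>
    dplyr::mutate(
      freq = object$freqs[.data$f], time = object$times[.data$t],
      erd = as.vector(t(object$values[ci, , ])),
      valid = as.vector(t(object$valid)))
  ggplot2::ggplot(dplyr::filter(df, .data$valid),
                  ggplot2::aes(.data$time, .data$freq, fill = .data$erd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "grey95",
                                  high = "firebrick",
                                  name = "ERD (%)") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", title = channel) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.erd_bold_fit <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$erd_percent, .data$roi_mean_t)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "firebrick") +
    ggplot2::labs(
      x = "contralateral high-alpha ERD (%)",
      y = "ROI mean t",
      title = sprintf("r = %.2f, p = %.3g, n = %d", object$r,
                      object$p_value, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot design-matrix regressor columns over time
#'
#' @param design A `design_matrix` or labeled numeric matrix.
#' @param columns Columns to show (defaults to the shared EEG/condition
#'   columns).
#' @param tr_s Repetition time used for the time axis.
#' @return A ggplot object.
#' @export
plot_regressors <- function(design, columns = NULL, tr_s = 2) {
  X <- if (inherits(design, "design_matrix")) design$X else design
  if (is.null(columns)) {
    columns <- if (inherits(design, "design_matrix")) design$eeg_labels
    else colnames(X)
  }
  df <- tibble::as_tibble(X[, columns, drop = FALSE]) |>
    dplyr::mutate(time = (dplyr::row_number() - 1) * tr_s) |>
    tidyr::pivot_longer(-"time", names_to = "regressor")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~regressor, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
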