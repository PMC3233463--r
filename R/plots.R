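#' Observed versus predicted activity plot
#'
#' Scatter of predicted against observed pIC50, training and test sets
#' distinguished, with the identity line.
#'
#' @param run A `qsar_run`.
#' @return A ggplot object.
#' @export
plot_predictions <- function(run) {
  df <- run$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$role, shape = .data$role)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Observed pIC50", y = "Predicted pIC50",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_predictions
#' @param object A `qsar_run`.
#' @param ... Unused.
#' @export
autoplot.qsar_run <- function(object, ...) plot_predictions(object)

#' Cross-validated q2 versus component count
#'
#' The overfitting audit: the leave-one-out q2 profile with the selected
#' component count marked.
#'
#' @param run A `qsar_run`, or the `profile` tibble from
#'   [select_components()].
#' @return A ggplot object.
#' @export
plot_q2_profile <- function(run) {
  prof <- if (inherits(run, "qsar_run")) run$q2_profile else run
  sel <- if (inherits(run, "qsar_run")) run$internal$pcs else NA_integer_
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$pcs, y = .data$q2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Latent components", y = expression(q^2)) +
    ggplot2::theme_minimal()
  if (!is.na(sel))
    p <- p + ggplot2::geom_vline(xintercept = sel, linetype = 3)
  p
}

#' y-randomization histogram
#'
#' Distribution of scrambled-response q2 values; the unscrambled model's q2
#' can be overlaid for contrast.
#'
#' @param x A `y_randomization` result.
#' @param q2_real Optional unscrambled q2 to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.y_randomization <- function(x, q2_real = NULL, ...) {
  df <- tibble::tibble(q2 = x$q2_values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q2)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = expression(scrambled ~ q^2), y = "Count") +
    ggplot2::theme_minimal()
  if (!is.null(q2_real))
    p <- p + ggplot2::geom_vline(xintercept = q2_real, colour = "red")
  p
}

#' Lattice slice of a StDev*Coeff contour field
#'
#' Tile map of one z-plane of the contour field, favoured regions positive
#' (filled towards green), disfavoured negative (towards yellow/red).
#'
#' @param contour_set A `contour_set`.
#' @param iz z-plane index (default: the plane with the largest absolute
#'   value).
#' @return A ggplot object.
#' @export
plot_contour_slice <- function(contour_set, iz = NULL) {
  g <- contour_set$grid
  arr <- array(contour_set$values, dim = g$dims)
  if (is.null(iz)) iz <- which.max(apply(abs(arr), 3, max))
  sl <- arr[, , iz]
  df <- tidyr::expand_grid(iy = seq_len(g$dims[2]), ix = seq_len(g$dims[1]))
  df$x <- g$origin[1] + (df$ix - 1) * g$spacing
  df$y <- g$origin[2] + (df$iy - 1) * g$spacing
  df$value <- as.vector(sl)[df$ix + (df$iy - 1) * g$dims[1]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "goldenrod3", mid = "white",
                                  high = "forestgreen") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s StDev*Coeff, z-plane %d",
                                  contour_set$kind, iz),
                  x = "x (A)", y = "y (A)", fill = "StDev*Coeff") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
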