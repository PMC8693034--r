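#' Tidiers and plots for training results and predictions
#'
#' `tidy()` on a `geom_training` returns the per-epoch loss history in
#' long form; `glance()` returns a one-row model summary.  `tidy()` on
#' a `geometry_prediction` returns one row per residue pair with the
#' contact probability and the TBM fusion weight.  `autoplot()`
#' methods draw the training curves and the predicted contact map.
#'
#' @param x A `geom_training` or `geometry_prediction` object.
#' @param ... Unused.
#' @return A tibble (tidiers) or a ggplot object (autoplot).
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.geom_training <- function(x, ...) {
  tidyr::pivot_longer(
    x$history, -"epoch",
    names_to = "split", values_to = "loss"
  ) |>
    dplyr::mutate(split = sub("_loss$", "", .data$split))
}

#' @rdname tidiers
#' @export
glance.geom_training <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    profile = x$net$cfg$profile,
    epochs = nrow(h),
    n_train = length(x$split$train),
    n_validation = length(x$split$validation),
    final_train_loss = h$train_loss[nrow(h)],
    final_validation_loss = h$validation_loss[nrow(h)],
    n_parameters = sum(vapply(x$net$params, length, numeric(1)))
  )
}

#' @rdname tidiers
#' @export
tidy.geometry_prediction <- function(x, ...) {
  cp <- contact_probability(x$posterior$dist)
  L <- nrow(cp)
  tibble::tibble(
    i = rep(seq_len(L), L),
    j = rep(seq_len(L), each = L),
    contact_probability = as.vector(cp),
    w_tbm = as.vector(x$fusion$w_tbm)
  ) |>
    dplyr::filter(.data$i < .data$j)
}

#' @rdname tidiers
#' @export
autoplot.geom_training <- function(x, ...) {
  ggplot2::ggplot(
    tidy(x),
    ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$split)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "epoch", y = "cross-entropy loss", colour = NULL,
      title = "Geometry network training"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.geometry_prediction <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$i, y = .data$j,
                    fill = .data$contact_probability)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "residue i", y = "residue j", fill = "P(contact)",
      title = "Predicted contact probability"
    ) +
    ggplot2::theme_minimal()
}
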