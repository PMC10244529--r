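# ggplot2 visualisations: training curves and per-head spatial attention
# gates.

#' Plot training curves
#'
#' Loss components and dev MAE per epoch.
#'
#' @param object An `hmhn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmhn_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble(epoch = h$epoch, value = h$l_sum, series = "L_sum"),
    tibble(epoch = h$epoch, value = h$l_mse, series = "L_mse"),
    tibble(epoch = h$epoch, value = h$l_att, series = "L_att"),
    tibble(epoch = h$epoch, value = h$dev_mae, series = "dev MAE"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training losses and dev MAE") +
    ggplot2::theme_minimal()
}

#' Per-head spatial attention gates for one image
#'
#' Runs the model in eval mode on a single image and returns the sigmoid
#' spatial gate of every cross-attention head over the backbone feature
#' grid, in long (tidy) form.
#'
#' @param fit An `hmhn_fit` or `hmhn_model` (cross-attention enabled).
#' @param image An image path or an `(H, W, 3)` array in \[0, 1\].
#' @return Tibble of class `hmhn_attention` with `head`, `row`, `col`,
#'   `gate`.
#' @export
attention_maps <- function(fit, image) {
  model <- if (inherits(fit, "hmhn_fit")) fit$model else fit
  if (is.null(model$mab))
    abort("attention_maps requires the cross-attention stage (use_mab)")
  sz <- model$config$image_size
  x <- if (is.character(image)) preprocess_image(image, sz) else image
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  fwd <- model_forward(model, x, train = FALSE)
  maps <- lapply(seq_along(fwd$spatial_gates), function(i) {
    g <- fwd$spatial_gates[[i]][, , 1, 1]
    d <- dim(g)
    tibble(head = i, row = rep(seq_len(d[1]), d[2]),
           col = rep(seq_len(d[2]), each = d[1]), gate = as.vector(g))
  })
  out <- dplyr::bind_rows(maps)
  class(out) <- c("hmhn_attention", class(out))
  out
}

#' Plot spatial attention gates
#'
#' @param object A tibble from [attention_maps()].
#' @param ... Unused.
#' @return A ggplot object (one raster panel per head).
#' @export
autoplot.hmhn_attention <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$gate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_wrap(~head, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "gate",
                  title = "Spatial attention gates") +
    ggplot2::theme_minimal()
}
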