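# ggplot2 visualisations for fitted models, evaluations and heatmaps.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text scale_fill_gradient labs theme_minimal facet_wrap
#'   scale_fill_viridis_c coord_fixed annotation_raster
NULL

#' Plot training history
#'
#' Training loss and validation macro accuracy per epoch.
#'
#' @param object a `wha_fit`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.wha_fit <- function(object, ...) {
  h <- object$history
  long <- rbind(
    tibble::tibble(epoch = h$epoch, metric = "train loss",
                   value = h$train_loss),
    tibble::tibble(epoch = h$epoch, metric = "val macro accuracy",
                   value = h$val_macro_acc)
  )
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object a `wha_confusion`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.wha_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "pred", "n")
  ggplot(df, aes(x = .data$pred, y = .data$true, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "true") +
    coord_fixed() +
    theme_minimal()
}

#' Plot a Grad-CAM heatmap, optionally over its source image
#'
#' @param object a `wha_heatmap`
#' @param image optional `(H,W,3)` array to underlay
#' @param alpha heatmap opacity when overlaid
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.wha_heatmap <- function(object, image = NULL, alpha = 0.5, ...) {
  m <- unclass(object)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  p <- ggplot(df, aes(x = .data$col, y = -.data$row))
  if (!is.null(image)) {
    p <- p + annotation_raster(grDevices::as.raster(image),
                               xmin = 0.5, xmax = ncol(m) + 0.5,
                               ymin = -nrow(m) - 0.5, ymax = -0.5)
    p <- p + geom_tile(aes(fill = .data$value), alpha = alpha)
  } else {
    p <- p + geom_tile(aes(fill = .data$value))
  }
  p + scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = paste("Grad-CAM:", attr(object, "heat_class"))) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
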