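#' Plot helpers
#'
#' ggplot2-based views of the package's result types: `plot_label_map()`
#' renders a mask in its palette colors (unlabeled in white),
#' `plot_superpixels()` draws segment ids as a discrete raster, and
#' `plot_metrics()` shows per-class precision/recall/F-score bars.
#' ggplot2 is only suggested; these helpers error informatively without
#' it.
#'
#' @param mask a `label_map`.
#' @param palette a [tissue_palette()]; defaults to the mask's own.
#' @return a ggplot object.
#' @export
plot_label_map <- function(mask, palette = attr(mask, "palette")) {
  require_ggplot()
  df <- mask_df(mask)
  df$name <- c("unlabeled", palette$name)[df$value + 1L]
  cols <- c(unlabeled = "#FFFFFF",
            stats::setNames(grDevices::rgb(palette$r, palette$g, palette$b,
                                           maxColorValue = 255),
                            palette$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$name)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, name = "tissue") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname plot_label_map
#' @param sp a `superpixel_map`.
#' @export
plot_superpixels <- function(sp) {
  require_ggplot()
  df <- mask_df(sp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @rdname plot_label_map
#' @param metrics a tibble from [class_metrics()] or [metrics_report()].
#' @export
plot_metrics <- function(metrics) {
  require_ggplot()
  long <- do.call(rbind, lapply(c("precision", "recall", "fscore"),
    function(v) data.frame(class = metrics$class, metric = v,
                           value = metrics[[v]],
                           aggregation = if ("aggregation" %in% names(metrics))
                             metrics$aggregation else "pooled")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                          fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL)
  if (length(unique(long$aggregation)) > 1)
    p <- p + ggplot2::facet_wrap(~aggregation)
  p
}

mask_df <- function(m) {
  data.frame(row = as.vector(row(m)), col = as.vector(col(m)),
             value = as.vector(unclass(m)))
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plot helpers", call. = FALSE)
}
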