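#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a curvature-by-angular-position tuning heatmap
#'
#' @param object A [tuning_heatmap()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tuning_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$angle, y = .data$curvature,
                                       fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "angular position (deg, ccw from right)",
                  y = "boundary curvature (1/px)", fill = "mean rate") +
    ggplot2::theme_minimal()
}

#' Plot rank-ordered single-cell information curves
#'
#' Overlays the rank-ordered per-cell maximum information for one or more
#' conditions (e.g. untrained vs trained), the standard display of how many
#' cells reach the `log2(p)` ceiling.
#'
#' @param ... Named [single_cell_information()] tibbles, e.g.
#'   `plot_information_curves(untrained = i0, trained = i1)`.
#' @param max_bits Optional horizontal reference line (e.g. `log2(p)`).
#' @return A ggplot.
#' @export
plot_information_curves <- function(..., max_bits = NULL) {
  curves <- purrr::imap_dfr(list(...), function(info, nm) {
    crv <- information_curve(info)
    crv$condition <- nm
    crv
  })
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$rank, y = .data$info,
                                    color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cell rank", y = "information (bits)",
                  color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(max_bits)) {
    p <- p + ggplot2::geom_hline(yintercept = max_bits, linetype = "dashed")
  }
  p
}

#' Plot a rendered stimulus
#'
#' @param object A `rendered_stimulus`.
#' @param ... Unused.
#' @return A ggplot raster of the retina.
#' @export
autoplot.rendered_stimulus <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object)) - 1L,
                           x = seq_len(ncol(object)) - 1L)
  df$value <- as.vector(t(unclass_image(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a backtraced receptive field
#'
#' Sums the effective Gabor-input weights over kernels (optionally keeping
#' only the strongest fraction) and shows them on the retina — the overlay
#' used to visualize what a cell has learned to respond to.
#'
#' @param rf A [backtrace_receptive_field()] array.
#' @param top_fraction Keep only effective weights above this quantile
#'   (default 0.99, i.e. the top 1%); `0` keeps everything.
#' @return A ggplot.
#' @export
plot_receptive_field <- function(rf, top_fraction = 0.99) {
  m <- apply(unclass(rf), c(1, 2), sum)
  if (top_fraction > 0) {
    thr <- stats::quantile(m[m > 0], top_fraction, names = FALSE)
    m[m < thr] <- 0
  }
  df <- tidyr::expand_grid(y = seq_len(nrow(m)) - 1L,
                           x = seq_len(ncol(m)) - 1L)
  df$weight <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "effective\nweight") +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
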