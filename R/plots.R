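# ggplot2 visualisations for contours, diagrams and evaluation results.

#' @method autoplot cellph_contour
#' @export
autoplot.cellph_contour <- function(object, ...) {
  df <- tibble(x = c(object$x, object$x[1L]), y = c(object$y, object$y[1L]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = contour_id(object),
                  x = contour_unit(object), y = contour_unit(object))
}

#' @method autoplot cellph_diagram
#' @export
autoplot.cellph_diagram <- function(object, ...) {
  df <- tidy(object)
  lim <- range(c(df$birth, df$death))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$birth, y = .data$death)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_count(alpha = 0.8) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(title = diagram_id(object), x = "birth", y = "death",
                  size = "multiplicity")
}

#' @method autoplot cellph_roc
#' @export
autoplot.cellph_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f, pAUC10 = %.3f",
                                  object$auc, object$pauc10))
}

#' @method autoplot cellph_mds
#' @export
autoplot.cellph_mds <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  if (!is.null(labels)) df$group <- as.character(labels[df$id])
  expl <- object$explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::labs(
      x = sprintf("dim 1 (%.1f%%)", 100 * expl[1L]),
      y = if (length(expl) >= 2L) sprintf("dim 2 (%.1f%%)", 100 * expl[2L])
      else "dim 2"
    )
  if (is.null(labels)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' @method autoplot cellph_sensitivity
#' @export
autoplot.cellph_sensitivity <- function(object, ...) {
  d <- object$delta
  ggplot2::ggplot(d, ggplot2::aes(x = .data$s, y = .data$delta_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$delta_mean - .data$delta_sd,
      ymax = .data$delta_mean + .data$delta_sd
    ), alpha = 0.3) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "noise level s", y = "relative RMS change of D")
}

#' Heat map of a distance matrix
#'
#' @param m Distance matrix with dimnames.
#' @return A ggplot object.
#' @export
plot_distance_heatmap <- function(m) {
  df <- tidyr::expand_grid(from = rownames(m), to = colnames(m))
  df$distance <- as.vector(t(m))
  df$from <- factor(df$from, levels = rownames(m))
  df$to <- factor(df$to, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   axis.ticks = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL)
}
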