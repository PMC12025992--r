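#' Pseudocolor plot of a laryngotopographic map
#'
#' @param object an `ltg_map`.
#' @param what `"amplitude"` or `"phase"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ltg_map
#' @export
autoplot.ltg_map <- function(object, what = c("amplitude", "phase"), ...) {
  what <- match.arg(what)
  m <- if (what == "amplitude") object$amplitude else object$phase_deg
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = if (what == "amplitude")
      sprintf("|A| @ %.0f Hz", object$f0) else "phase (°)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Mean bootstrap ROC curve with its pointwise percentile band
#'
#' @param object an `roc_boot`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot roc_boot
#' @export
autoplot.roc_boot <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$tpr_lo,
                                      ymax = .data$tpr_hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, shape = 4, size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC %.2f (95%% CI %.2f–%.2f), B = %d",
                      object$auc, object$auc_ci[1], object$auc_ci[2],
                      object$b)
    ) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a cross-validated classifier report
#'
#' @param object a `classifier_report`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n(%.0f%%)", .data$count, .data$pct))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100), name = "% of row") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = sprintf("%s, %d-fold CV", object$task, object$k))
}

#' Kymogram at one axis position
#'
#' Time-by-lateral-position intensity image of the stack row nearest
#' `position_pct` %FL, the classic single-line kymographic view.
#'
#' @param stack a [frame_stack()].
#' @param partition a `glottis_partition`.
#' @param position_pct axis position in %FL (posterior to anterior).
#' @return A ggplot.
#' @export
plot_kymogram <- function(stack, partition, position_pct = 50) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(partition, "glottis_partition"))
  len <- length(partition$rows)
  row <- partition$rows[1L + round(position_pct / 100 * (len - 1L))]
  img <- stack$frames[, row, ] # T x W
  df <- tidyr::expand_grid(frame = seq_len(nrow(img)),
                           col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$frame, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$col,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "frame", y = "lateral position (px)",
                  title = sprintf("kymogram @ %.0f %%FL", position_pct)) +
    ggplot2::theme_minimal()
}
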