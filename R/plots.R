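#' Plot SRM chromatograms
#'
#' Light and heavy traces of each peptide, one panel per peptide x
#' channel, colored by product ion.
#'
#' @param chromatograms Long chromatogram tibble.
#' @param samples Optional subset of sample ids to draw.
#' @return A ggplot object.
#' @export
plot_chromatograms <- function(chromatograms, samples = NULL) {
  d <- chromatograms
  if (!is.null(samples)) d <- d[d$sample_id %in% samples, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$intensity,
                                  colour = factor(.data$product_mz))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(sample_id + channel ~ peptide_id, scales = "free") +
    ggplot2::labs(x = "retention time (min)", y = "intensity (counts)",
                  colour = "product m/z") +
    ggplot2::theme_minimal()
}

#' @rdname fit_calibration
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  d <- object$back_calc
  line <- tibble(
    nominal = exp(seq(log(min(d$nominal)), log(max(d$nominal)),
                      length.out = 50))
  )
  line$ratio <- object$intercept + object$slope * line$nominal
  ggplot2::ggplot(d, ggplot2::aes(.data$nominal, .data$ratio)) +
    ggplot2::geom_line(data = line, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted), size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = sprintf("Calibration %s (weighting %s, r² = %.4f)",
                      object$peptide_id, object$weighting, object$r2),
      x = "nominal concentration (µg/mL)",
      y = "response ratio (light/heavy)", shape = "level accepted"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname roc_analysis
#' @method autoplot tdm_roc
#' @export
autoplot.tdm_roc <- function(object, ...) {
  pts <- object$roc_points[order(object$roc_points$fpr,
                                 object$roc_points$tpr), ]
  best <- tibble(fpr = 1 - object$specificity_pct / 100,
                 tpr = object$sensitivity_pct / 100)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::annotate("text", x = best$fpr + 0.03, y = best$tpr,
                      hjust = 0, size = 3,
                      label = sprintf("%.1f µg/mL", object$threshold)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("ROC of %s for clinical benefit (AUC %.2f)",
                      object$which, object$auc),
      x = "1 - specificity", y = "sensitivity"
    ) +
    ggplot2::theme_minimal()
}
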