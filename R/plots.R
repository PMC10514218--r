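# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_boxplot
#'   geom_abline geom_hline facet_grid facet_wrap labs scale_y_log10
#'   coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- tidy(object)
  pts <- pts[order(1 - pts$specificity, pts$sensitivity), ]
  ggplot(pts, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_point(size = 0.8) +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("AUC = %.3f [%.3f, %.3f]", object$auc,
                         object$ci_lower, object$ci_upper))
}

#' Plot subthreshold-extent distributions by group
#'
#' Boxplots of the per-subject subthreshold voxel counts by diagnostic
#' group, faceted by ROI and reference strategy, for one threshold/kernel.
#'
#' @param object A `zmatch_extents` tibble.
#' @param z_threshold,fwhm_mm Cell selectors (defaults: first present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zmatch_extents
#' @export
autoplot.zmatch_extents <- function(object, z_threshold = NULL,
                                    fwhm_mm = NULL, ...) {
  zt <- z_threshold %||% sort(unique(object$z_threshold), decreasing = TRUE)[1]
  fw <- fwhm_mm %||% min(object$fwhm_mm)
  d <- object[object$z_threshold == zt & object$fwhm_mm == fw, ]
  ggplot(d, aes(x = .data$group, y = .data$n_subthreshold + 1,
                fill = .data$group)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_grid(reference_type ~ roi) +
    scale_y_log10() +
    labs(x = NULL, y = "Subthreshold voxels + 1",
         title = sprintf("Z < %g, %g mm FWHM", zt, fw))
}

#' Plot an AUC grid
#'
#' AUC per evaluation cell, by Z-threshold and smoothing kernel, colored by
#' reference strategy and faceted by ROI.
#'
#' @param object A `zmatch_run` (or its `auc_grid` tibble).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zmatch_run
#' @export
autoplot.zmatch_run <- function(object, ...) {
  g <- object$auc_grid
  ggplot(g, aes(x = factor(.data$fwhm_mm), y = .data$auc,
                colour = .data$reference_type,
                group = .data$reference_type)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_point(size = 1) +
    facet_grid(z_threshold ~ roi) +
    labs(x = "Smoothing FWHM (mm)", y = "AUC", colour = "Reference")
}
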