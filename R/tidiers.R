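# broom-style tidiers for fitted objects.

#' Tidy an ROC result into curve points
#'
#' One row per candidate cut-off (midpoints between adjacent distinct
#' scores plus half-steps beyond the extremes), with the sensitivity and
#' specificity of the rule `score > cutoff -> positive`.
#'
#' @param x A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return Tibble with `cutoff, sensitivity, specificity, youden_j`.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  s <- sort(unique(x$scores))
  if (length(s) == 1) {
    cand <- c(s - 0.5, s + 0.5)
  } else {
    gaps <- diff(s)
    cand <- c(s[1] - gaps[1] / 2, (s[-1] + s[-length(s)]) / 2,
              s[length(s)] + gaps[length(gaps)] / 2)
  }
  sens <- vapply(cand, function(cc) mean(x$scores[x$positive] > cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(x$scores[!x$positive] <= cc), numeric(1))
  tibble(cutoff = cand, sensitivity = sens, specificity = spec,
         youden_j = sens + spec - 1)
}

#' One-row summary of an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return One-row tibble with AUC, DeLong CI, optimal cut-off and its
#'   operating characteristics.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         optimal_cutoff = x$optimal_cutoff, sensitivity = x$sensitivity,
         specificity = x$specificity, youden_j = x$youden_j,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a W-score model: voxel-wise coefficient summaries
#'
#' @param x A `wscore_model`.
#' @param mask_only Summarize only voxels inside the model's brain mask.
#' @param ... Unused.
#' @return Tibble with one row per term (`intercept`, `slope`, `resid_sd`)
#'   and the mean / SD / median of the voxel-wise values.
#' @method tidy wscore_model
#' @export
tidy.wscore_model <- function(x, mask_only = TRUE, ...) {
  keep <- if (mask_only) as.logical(x$mean_map$data > x$epsilon) else
    rep(TRUE, length(x$mean_map$data))
  summ <- function(v) {
    v <- as.numeric(v)[keep]
    c(mean(v), sd(v), median(v))
  }
  vals <- rbind(summ(x$intercept_map$data), summ(x$slope_map$data),
                summ(x$resid_sd_map$data))
  tibble(term = c("intercept", "slope", "resid_sd"),
         mean = vals[, 1], sd = vals[, 2], median = vals[, 3])
}

#' @method glance wscore_model
#' @export
glance.wscore_model <- function(x, ...) {
  tibble(n_members = length(x$member_ids), mean_age = x$mean_age,
         grid_id = x$grid_id)
}

#' Tidy a pipeline run: the AUC grid
#'
#' @param x A `zmatch_run`.
#' @param ... Unused.
#' @return The per-cell AUC grid tibble.
#' @method tidy zmatch_run
#' @export
tidy.zmatch_run <- function(x, ...) {
  x$auc_grid
}

#' @method glance zmatch_run
#' @export
glance.zmatch_run <- function(x, ...) {
  best <- x$auc_grid[which.max(x$auc_grid$auc), ]
  tibble(n_subjects = nrow(x$records), n_cells = nrow(x$auc_grid),
         n_skips = nrow(x$skips), best_auc = best$auc,
         best_reference = best$reference_type, best_roi = best$roi,
         best_z = best$z_threshold, best_fwhm = best$fwhm_mm)
}
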