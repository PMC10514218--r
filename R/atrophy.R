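# Z-map / W-map computation and subthreshold-voxel extent scoring.
#
# Z = (subject - reference mean) / reference SD, computed inside a brain
# mask (reference mean > epsilon). Voxels whose reference SD falls below a
# floor are excluded with NA sentinels and counted as flagged, so silent
# exclusions stay visible. The per-subject atrophy score for an ROI is the
# number of in-mask voxels with Z strictly below a negative threshold;
# smoothing, when requested, is applied to GM maps before Z computation,
# never to Z-maps.

new_zmap <- function(data, voxel_size, subject_id, reference, mask, flagged,
                     kind = "z") {
  structure(
    list(data = data, voxel_size = voxel_size,
         grid_id = grid_token(dim(data), voxel_size),
         subject_id = subject_id, reference = reference, mask = mask,
         flagged_voxels = flagged, kind = kind),
    class = "z_map"
  )
}

#' @export
print.z_map <- function(x, ...) {
  cat(sprintf("<%s_map %s: subject %s, %d in-mask voxels, %d flagged>\n",
              x$kind, x$grid_id, x$subject_id %||% "?", sum(x$mask$mask),
              x$flagged_voxels))
  invisible(x)
}

# Core standardization shared by Z- and W-maps: NA outside mask and at
# flagged (SD below floor) voxels.
standardize_field <- function(x, center, scale, mask, sd_floor) {
  valid <- mask & scale >= sd_floor
  z <- rep(NA_real_, length(x))
  z[valid] <- (x[valid] - center[valid]) / scale[valid]
  list(z = z, flagged = sum(mask & scale < sd_floor))
}

#' Compute a voxel-wise Z-map against a reference model
#'
#' @param vol Subject `gm_volume` (smoothed to the same kernel as the
#'   reference members, if smoothing is used).
#' @param ref A `reference_model` on the same grid.
#' @param sd_floor Minimum reference SD (concentration units); voxels below
#'   it are excluded and reported in `flagged_voxels`. Default 1e-4.
#' @param epsilon Brain-mask threshold on the reference mean map.
#' @param subject_id Optional id stored in the result.
#' @return A `z_map`: Z-statistics inside the mask, `NA` sentinels outside.
#' @export
compute_zmap <- function(vol, ref, sd_floor = 1e-4, epsilon = 0.05,
                         subject_id = NULL) {
  stopifnot(inherits(vol, "gm_volume"), inherits(ref, "reference_model"))
  check_same_grid(vol, ref$mean_map)
  if (sd_floor <= 0) stop_parameter("sd_floor must be > 0")
  mask <- make_brain_mask(ref$mean_map, epsilon)
  st <- standardize_field(as.numeric(vol$data), as.numeric(ref$mean_map$data),
                          as.numeric(ref$sd_map$data), as.logical(mask$mask),
                          sd_floor)
  new_zmap(array(st$z, dim(vol$data)), vol$voxel_size, subject_id,
           list(ref_type = ref$ref_type, k = ref$k,
                age_center = ref$age_center, half_width = ref$half_width,
                amyloid_filter = ref$amyloid_filter),
           mask, st$flagged, kind = "z")
}

#' Compute a voxel-wise W-map from a regression model
#'
#' `W = (observed - (intercept + slope * age)) / residual SD`, with the same
#' masking and SD-floor policy as [compute_zmap()]. With a slope of zero
#' everywhere this reduces exactly to a Z-map against the model's intercept
#' and residual SD.
#'
#' @param vol Subject `gm_volume`.
#' @param age Subject age in years.
#' @param model A `wscore_model` on the same grid.
#' @param sd_floor Minimum residual SD; lower voxels are flagged out.
#' @param subject_id Optional id stored in the result.
#' @return A `z_map` with `kind = "w"`.
#' @export
compute_wmap <- function(vol, age, model, sd_floor = 1e-4, subject_id = NULL) {
  stopifnot(inherits(vol, "gm_volume"), inherits(model, "wscore_model"))
  check_same_grid(vol, model$mean_map)
  if (sd_floor <= 0) stop_parameter("sd_floor must be > 0")
  mask <- make_brain_mask(model$mean_map, model$epsilon)
  pred <- as.numeric(model$intercept_map$data) +
    as.numeric(model$slope_map$data) * age
  st <- standardize_field(as.numeric(vol$data), pred,
                          as.numeric(model$resid_sd_map$data),
                          as.logical(mask$mask), sd_floor)
  new_zmap(array(st$z, dim(vol$data)), vol$voxel_size, subject_id,
           list(ref_type = "wscore", k = length(model$member_ids),
                mean_age = model$mean_age),
           mask, st$flagged, kind = "w")
}

#' Count subthreshold voxels in an ROI
#'
#' Counts in-mask, non-sentinel voxels with `Z < threshold` (strict) whose
#' atlas label belongs to the ROI; `"total"` uses the union of all nonzero
#' labels.
#'
#' @param zmap A `z_map`.
#' @param atlas An `roi_atlas` on the same grid.
#' @param roi ROI name from the atlas label table, or `"total"`.
#' @param threshold Negative Z threshold (e.g. -2.5, -3.5, -4.5).
#' @return Integer voxel count.
#' @export
count_subthreshold <- function(zmap, atlas, roi = "total", threshold = -3.5) {
  stopifnot(inherits(zmap, "z_map"), inherits(atlas, "roi_atlas"))
  check_same_grid(zmap, atlas)
  if (threshold >= 0) stop_parameter("threshold must be negative")
  idx <- atlas_roi_indices(atlas)
  if (!roi %in% names(idx)) {
    stop_parameter(sprintf("unknown ROI '%s'; available: %s", roi,
                           paste(names(idx), collapse = ", ")))
  }
  sum(zmap$data[idx[[roi]]] < threshold, na.rm = TRUE)
}

#' Reference strategy descriptor
#'
#' @param type `"standard"` (whole CN sample) or `"bracket"` (nearest-k CN
#'   within an age window).
#' @param half_width Bracket half-width in years (5 = 10-year bracket,
#'   2.5 = 5-year bracket); ignored for standard references.
#' @param amyloid_filter `"all"` or `"negative_only"`.
#' @param name Label used in output tables; defaults to e.g. `"standard"`,
#'   `"bracket_10y"`, `"bracket_5y_aneg"`.
#' @return A `reference_strategy` list.
#' @export
reference_strategy <- function(type = c("standard", "bracket"),
                               half_width = NA_real_,
                               amyloid_filter = c("all", "negative_only"),
                               name = NULL) {
  type <- match.arg(type)
  amyloid_filter <- match.arg(amyloid_filter)
  if (type == "bracket" && (!is.finite(half_width) || half_width <= 0)) {
    stop_parameter("bracket strategies need a positive half_width")
  }
  if (is.null(name)) {
    name <- if (type == "standard") "standard"
            else sprintf("bracket_%gy", 2 * half_width)
    if (amyloid_filter == "negative_only") name <- paste0(name, "_aneg")
  }
  structure(list(type = type, half_width = half_width,
                 amyloid_filter = amyloid_filter, name = name),
            class = "reference_strategy")
}

#' The three default reference strategies
#'
#' Standard whole-sample, 10-year bracket, and 5-year bracket references,
#' all without amyloid filtering.
#'
#' @return Named list of `reference_strategy` objects.
#' @export
default_strategies <- function() {
  s <- list(reference_strategy("standard"),
            reference_strategy("bracket", half_width = 5),
            reference_strategy("bracket", half_width = 2.5))
  names(s) <- vapply(s, `[[`, character(1), "name")
  s
}

# Score every subject of a (smoothed) cohort matrix under one strategy:
# per-subject Z vector -> subthreshold counts per ROI x threshold.
score_strategy_matrix <- function(M, records, roi_idx, dims, strategy,
                                  k = 20, exclude_self = FALSE,
                                  sd_floor = 1e-4, epsilon = 0.05,
                                  thresholds = c(-2.5, -3.5, -4.5),
                                  rois = names(roi_idx)) {
  cn <- eligible_cn(records, strategy$amyloid_filter)
  n_sub <- nrow(records)
  counts <- vector("list", n_sub)
  flagged <- integer(n_sub)
  skip <- list()
  base <- NULL
  base_ss <- NULL
  if (strategy$type == "standard") {
    base <- ref_stats(M[, cn$id, drop = FALSE])
    base_ss <- base$sd^2 * (base$n - 1)
  }

  for (i in seq_len(n_sub)) {
    id <- records$id[i]
    if (strategy$type == "standard") {
      st <- base
      if (exclude_self && id %in% cn$id) {
        # leave-one-out downdate of mean and sample SD:
        # m_{-i} = (n m - x_i)/(n-1), SS_{-i} = SS - n/(n-1) (x_i - m)^2
        n <- base$n
        x <- M[, id]
        m_i <- (n * base$mean - x) / (n - 1)
        ss_i <- pmax(base_ss - n / (n - 1) * (x - base$mean)^2, 0)
        st <- list(mean = m_i, sd = sqrt(ss_i / (n - 2)), n = n - 1)
      }
    } else {
      members <- tryCatch(
        select_bracket_members(cn, records$age[i], strategy$half_width, k,
                               exclude_id = if (exclude_self) id else NULL),
        zmatch_error_coverage = function(e) e
      )
      if (inherits(members, "error")) {
        skip[[length(skip) + 1]] <- tibble(
          subject_id = id, reference_type = strategy$name,
          reason = conditionMessage(members),
          target_age = members$target_age %||% records$age[i])
        next
      }
      st <- ref_stats(M[, members, drop = FALSE])
    }
    mask <- st$mean > epsilon
    valid <- mask & st$sd >= sd_floor
    flagged[i] <- sum(mask & st$sd < sd_floor)
    z <- (M[, i][valid] - st$mean[valid]) / st$sd[valid]
    zfull <- rep(NA_real_, nrow(M))
    zfull[valid] <- z
    cnt <- matrix(0L, length(rois), length(thresholds),
                  dimnames = list(rois, NULL))
    for (r in seq_along(rois)) {
      zr <- zfull[roi_idx[[rois[r]]]]
      for (t in seq_along(thresholds)) {
        cnt[r, t] <- sum(zr < thresholds[t], na.rm = TRUE)
      }
    }
    counts[[i]] <- cnt
  }
  list(counts = counts, flagged = flagged,
       skips = if (length(skip)) dplyr::bind_rows(skip) else
         tibble(subject_id = character(), reference_type = character(),
                reason = character(), target_age = numeric()))
}

#' Build the subthreshold-voxel extent table
#'
#' Runs the full factorial of reference strategies x smoothing kernels x
#' Z-thresholds x ROIs over a cohort. References are rebuilt from smoothed
#' member volumes for each kernel. Subjects without bracket coverage at a
#' given strategy are skipped and recorded (skips are data, not failures).
#'
#' @param cohort A `zmatch_cohort` with volumes.
#' @param strategies List of `reference_strategy` (default: standard,
#'   10-year bracket, 5-year bracket).
#' @param thresholds Negative Z thresholds; default -2.5, -3.5, -4.5.
#' @param kernels Smoothing FWHM in mm; default 0, 2, 4, 8.
#' @param rois ROI names; default all atlas ROIs plus `"total"`.
#' @param k Bracket member count.
#' @param exclude_self Leave the index subject out of its own reference.
#' @param sd_floor,epsilon Masking policy, see [compute_zmap()].
#' @return A tibble of class `zmatch_extents` with columns `subject_id,
#'   group, age, roi, z_threshold, fwhm_mm, reference_type, n_subthreshold,
#'   volume_mm3, flagged_voxels`; skipped subjects are attached as the
#'   `"skips"` attribute (see [skipped_subjects()]).
#' @export
build_extent_table <- function(cohort, strategies = default_strategies(),
                               thresholds = c(-2.5, -3.5, -4.5),
                               kernels = c(0, 2, 4, 8), rois = NULL,
                               k = 20, exclude_self = FALSE,
                               sd_floor = 1e-4, epsilon = 0.05) {
  stopifnot(inherits(cohort, "zmatch_cohort"))
  roi_idx <- atlas_roi_indices(cohort$atlas)
  rois <- rois %||% names(roi_idx)
  M0 <- cohort_matrix(cohort)
  dims <- dim(cohort$atlas$labels)
  vmm3 <- prod(cohort$spec$voxel_size)
  records <- cohort$records
  rows <- list()
  skips <- list()
  for (fwhm in kernels) {
    M <- if (fwhm == 0) M0 else {
      apply(M0, 2, function(col) {
        as.numeric(smooth_array(array(col, dims), cohort$spec$voxel_size,
                                fwhm_to_sigma(fwhm)))
      })
    }
    colnames(M) <- colnames(M0)
    for (strat in strategies) {
      sc <- score_strategy_matrix(M, records, roi_idx, dims, strat, k,
                                  exclude_self, sd_floor, epsilon,
                                  thresholds, rois)
      if (nrow(sc$skips) > 0) {
        skips[[length(skips) + 1]] <- dplyr::mutate(sc$skips, fwhm_mm = fwhm)
      }
      scored <- which(!vapply(sc$counts, is.null, logical(1)))
      for (i in scored) {
        cnt <- sc$counts[[i]]
        rows[[length(rows) + 1]] <- tibble(
          subject_id = records$id[i], group = records$group[i],
          age = records$age[i],
          roi = rep(rois, times = length(thresholds)),
          z_threshold = rep(thresholds, each = length(rois)),
          fwhm_mm = fwhm, reference_type = strat$name,
          n_subthreshold = as.integer(cnt),
          volume_mm3 = as.numeric(cnt) * vmm3,
          flagged_voxels = sc$flagged[i])
      }
    }
  }
  empty <- tibble(subject_id = character(), group = character(),
                  age = numeric(), roi = character(), z_threshold = numeric(),
                  fwhm_mm = numeric(), reference_type = character(),
                  n_subthreshold = integer(), volume_mm3 = numeric(),
                  flagged_voxels = integer())
  out <- dplyr::bind_rows(empty, rows)
  attr(out, "skips") <- if (length(skips)) dplyr::bind_rows(skips) else
    tibble(subject_id = character(), reference_type = character(),
           reason = character(), target_age = numeric(), fwhm_mm = numeric())
  class(out) <- c("zmatch_extents", class(out))
  out
}

#' Skipped-subject sidecar of an extent table
#'
#' @param extents A `zmatch_extents` tibble from [build_extent_table()].
#' @return Tibble of `(subject_id, reference_type, reason, target_age,
#'   fwhm_mm)` for subjects without reference coverage.
#' @export
skipped_subjects <- function(extents) {
  attr(extents, "skips") %||%
    tibble(subject_id = character(), reference_type = character(),
           reason = character(), target_age = numeric(), fwhm_mm = numeric())
}
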