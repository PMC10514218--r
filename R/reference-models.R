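# Normative reference construction.
#
# Three reference-group types are supported: the standard whole-CN-sample
# reference, age-bracket references (the k CN nearest in age to the index
# subject within a half-width window), and a regression-based W-score model.
# Each may be restricted to amyloid-negative CN. Bracket membership uses a
# strict window (|age - center| < half_width); nearest-k within the window
# keeps selection deterministic, with age ties broken by ascending id.

new_reference_model <- function(mean_map, sd_map, member_ids, ref_type,
                                age_center = NA_real_, half_width = NA_real_,
                                amyloid_filter = "all") {
  structure(
    list(mean_map = mean_map, sd_map = sd_map, member_ids = member_ids,
         ref_type = ref_type, age_center = age_center, half_width = half_width,
         k = length(member_ids), amyloid_filter = amyloid_filter,
         grid_id = mean_map$grid_id),
    class = "reference_model"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model %s: k=%d%s, amyloid=%s, %s>\n", x$ref_type, x$k,
              if (!is.na(x$age_center))
                sprintf(", center=%.1f y, half-width=%.1f y", x$age_center, x$half_width)
              else "",
              x$amyloid_filter, x$grid_id))
  invisible(x)
}

# Two-pass voxel-wise mean and sample SD (denominator n - 1) of a
# voxels x members matrix.
ref_stats <- function(M) {
  n <- ncol(M)
  m <- rowMeans(M)
  s <- sqrt(rowSums((M - m)^2) / (n - 1))
  list(mean = m, sd = s, n = n)
}

#' Select age-bracket reference members
#'
#' Returns the `k` CN ids nearest in age to `target_age` among those with
#' `|age - target_age| < half_width` (strict), after removing `exclude_id`.
#' Age ties are broken by ascending id so selection is reproducible.
#'
#' @param cn_records Data frame of CN subjects with columns `id`, `age`.
#' @param target_age Center of the bracket, years.
#' @param half_width Bracket half-width, years (> 0); 5 gives a 10-year
#'   bracket, 2.5 a 5-year bracket.
#' @param k Number of members (>= 2), default 20.
#' @param exclude_id Optional id removed before selection (leave-one-out).
#' @return Character vector of `k` member ids. If fewer than `k` CN are
#'   eligible a coverage error (class `zmatch_error_coverage`, carrying
#'   `target_age`) is signalled; callers skip the subject.
#' @export
select_bracket_members <- function(cn_records, target_age, half_width, k = 20,
                                   exclude_id = NULL) {
  if (k < 2) stop_parameter("k must be >= 2")
  if (half_width <= 0) stop_parameter("half_width must be > 0")
  rec <- cn_records[is.null(exclude_id) | cn_records$id != (exclude_id %||% ""), ]
  d <- abs(rec$age - target_age)
  rec <- rec[d < half_width, ]
  d <- d[d < half_width]
  if (nrow(rec) < k) {
    stop_coverage(sprintf(
      "only %d eligible CN within %.1f years of age %.1f (need %d)",
      nrow(rec), half_width, target_age, k), target_age = target_age)
  }
  ord <- order(d, rec$id)
  rec$id[ord][seq_len(k)]
}

#' Build a reference model from member volumes
#'
#' Voxel-wise arithmetic mean and sample SD (denominator n - 1) over the
#' member volumes; these are the maps a Z-statistic is computed against.
#'
#' @param volumes List of `gm_volume` (>= 2) on a common grid.
#' @param member_ids Character ids, parallel to `volumes`.
#' @param ref_type `"standard"` or `"bracket"`.
#' @param age_center,half_width Bracket provenance (years), `NA` for
#'   standard references.
#' @param amyloid_filter `"all"` or `"negative_only"` (provenance only).
#' @return A `reference_model`.
#' @export
build_reference <- function(volumes, member_ids = names(volumes),
                            ref_type = "standard",
                            age_center = NA_real_, half_width = NA_real_,
                            amyloid_filter = "all") {
  if (length(volumes) < 2) stop_parameter("a reference needs >= 2 member volumes")
  for (v in volumes[-1]) check_same_grid(volumes[[1]], v)
  M <- vapply(volumes, function(v) as.numeric(v$data),
              numeric(length(volumes[[1]]$data)))
  st <- ref_stats(M)
  vx <- volumes[[1]]$voxel_size
  d <- dim(volumes[[1]]$data)
  new_reference_model(gm_volume(array(st$mean, d), vx),
                      gm_volume(array(st$sd, d), vx),
                      member_ids %||% paste0("m", seq_along(volumes)),
                      ref_type, age_center, half_width, amyloid_filter)
}

# Eligible CN records under an amyloid filter.
eligible_cn <- function(records, amyloid_filter = c("all", "negative_only")) {
  amyloid_filter <- match.arg(amyloid_filter)
  cn <- records[records$group == "CN", ]
  if (amyloid_filter == "negative_only") cn <- cn[!cn$amyloid_positive, ]
  cn
}

#' Build the standard whole-sample reference
#'
#' Mean/SD over all eligible CN in the cohort (optionally amyloid-negative
#' only) — the conventional broad-age-range normative reference.
#'
#' @param cohort A `zmatch_cohort` with volumes.
#' @param amyloid_filter `"all"` or `"negative_only"`.
#' @return A `reference_model` with `ref_type = "standard"`.
#' @export
build_standard_reference <- function(cohort, amyloid_filter = "all") {
  cn <- eligible_cn(cohort$records, amyloid_filter)
  if (nrow(cn) < 2) stop_parameter("fewer than 2 eligible CN for a standard reference")
  build_reference(cohort$volumes[cn$id], cn$id, ref_type = "standard",
                  amyloid_filter = amyloid_filter)
}

#' Integer-age coverage range of a bracket strategy
#'
#' Scans integer target ages from `floor(min CN age)` to `ceil(max CN age)`
#' and returns the maximal contiguous run for which a bracket reference can
#' be built (enough CN within the window). Outside this range subjects must
#' be skipped.
#'
#' @param cn_records Data frame with `id`, `age` of the CN pool.
#' @param half_width Bracket half-width in years.
#' @param k Members required.
#' @return `c(min_age, max_age)` of the widest contiguous covered integer
#'   range, or `NULL` if no age is covered.
#' @export
coverage_ages <- function(cn_records, half_width, k = 20) {
  if (nrow(cn_records) < k) return(NULL)
  # scan extends half_width beyond the observed CN ages: a bracket centered
  # outside the observed range can still contain enough members
  ages <- floor(min(cn_records$age) - half_width):
    ceiling(max(cn_records$age) + half_width)
  ok <- vapply(ages, function(a) {
    tryCatch({
      select_bracket_members(cn_records, a, half_width, k)
      TRUE
    }, zmatch_error_coverage = function(e) FALSE)
  }, logical(1))
  if (!any(ok)) return(NULL)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  c(ages[starts[best]], ages[ends[best]])
}

#' Fit a voxel-wise W-score model on CN subjects
#'
#' Per-voxel ordinary least squares of GM concentration on age; the W-score
#' of a new subject is the residual from this model divided by the residual
#' SD (denominator n - 2). Adjusts for age under a linearity assumption —
#' precisely the assumption age-bracket references avoid.
#'
#' @param cn_volumes List of `gm_volume` for the CN sample (>= 3).
#' @param cn_ages Ages in years, parallel to `cn_volumes`; must vary.
#' @param member_ids Optional ids for provenance.
#' @param epsilon Mask threshold applied to the CN mean map.
#' @return A `wscore_model` with `intercept_map`, `slope_map`,
#'   `resid_sd_map`, `mean_map` (CN voxel mean, used for masking),
#'   `mean_age`, `member_ids`.
#' @export
fit_wscore_model <- function(cn_volumes, cn_ages, member_ids = names(cn_volumes),
                             epsilon = 0.05) {
  n <- length(cn_volumes)
  if (n < 3) stop_parameter("W-score model needs >= 3 CN subjects")
  if (length(cn_ages) != n) stop_parameter("cn_ages must match cn_volumes")
  if (sd(cn_ages) == 0) {
    stop_parameter("constant ages: age regression is rank-deficient")
  }
  for (v in cn_volumes[-1]) check_same_grid(cn_volumes[[1]], v)
  d <- dim(cn_volumes[[1]]$data)
  vx <- cn_volumes[[1]]$voxel_size
  M <- vapply(cn_volumes, function(v) as.numeric(v$data), numeric(prod(d)))
  X <- cbind(1, cn_ages)
  # p x 2 coefficient matrix: B = M X (X'X)^-1
  B <- M %*% X %*% solve(crossprod(X))
  resid <- M - B %*% t(X)
  rsd <- sqrt(rowSums(resid^2) / (n - 2))
  structure(
    list(intercept_map = gm_volume(array(B[, 1], d), vx),
         slope_map = gm_volume(array(B[, 2], d), vx),
         resid_sd_map = gm_volume(array(rsd, d), vx),
         mean_map = gm_volume(array(rowMeans(M), d), vx),
         mean_age = mean(cn_ages), member_ids = member_ids, epsilon = epsilon,
         grid_id = grid_token(d, vx)),
    class = "wscore_model"
  )
}

#' @export
print.wscore_model <- function(x, ...) {
  cat(sprintf("<wscore_model: %d CN, mean age %.1f y, %s>\n",
              length(x$member_ids), x$mean_age, x$grid_id))
  invisible(x)
}

#' Persist / load a reference model (NIfTI pair + JSON sidecar)
#'
#' @param ref A `reference_model`.
#' @param prefix Path prefix; writes `<prefix>_mean.nii.gz`,
#'   `<prefix>_sd.nii.gz`, `<prefix>.json`.
#' @return `prefix` invisibly (write) or a `reference_model` (read).
#' @export
write_reference <- function(ref, prefix) {
  write_volume(ref$mean_map, paste0(prefix, "_mean.nii.gz"))
  write_volume(ref$sd_map, paste0(prefix, "_sd.nii.gz"))
  meta <- list(member_ids = ref$member_ids, ref_type = ref$ref_type,
               age_center = ref$age_center, half_width = ref$half_width,
               amyloid_filter = ref$amyloid_filter)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_reference
#' @export
read_reference <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_reference_model(read_volume(paste0(prefix, "_mean.nii.gz")),
                      read_volume(paste0(prefix, "_sd.nii.gz")),
                      meta$member_ids, meta$ref_type,
                      meta$age_center %||% NA_real_,
                      meta$half_width %||% NA_real_,
                      meta$amyloid_filter)
}
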