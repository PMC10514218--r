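# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# ages roughly normal in the 60-90 range, ~24% amyloid-positive CN,
# nonlinear (quadratic) age-related GM decline, a subtle amyloid-related
# GM reduction in CN, focal MCI atrophy concentrated in medial-temporal and
# temporal regions, a lognormal between-subject global scale, and additive
# Gaussian voxel noise. It makes no attempt at anatomical realism: ROIs are
# rectangular blocks on a small grid.

ROI_NAMES <- c("MTL", "frontal", "temporal", "parietal", "occipital", "other_gm")

default_trajectory <- function() {
  tibble(
    roi   = ROI_NAMES,
    g0    = c(0.75, 0.85, 0.85, 0.85, 0.80, 0.80),
    r1    = rep(0.004, 6),
    r2    = rep(0.0004, 6),
    a_ref = rep(70, 6)
  )
}

default_amyloid_effect <- function() {
  c(MTL = 0.02, frontal = 0.01, temporal = 0.02, parietal = 0.01,
    occipital = 0.01, other_gm = 0.01)
}

default_mci_effect <- function() {
  c(MTL = 0.15, frontal = 0.05, temporal = 0.12, parietal = 0.05,
    occipital = 0.03, other_gm = 0.04)
}

#' Specification of a synthetic cohort
#'
#' Defaults mirror the scale of the clinical samples the package is designed
#' around: 141 CN and 91 MCI, CN ages 73.45 +/- 5.75 y, MCI ages
#' 70.84 +/- 7.50 y, 24% amyloid-positive CN and 46% amyloid-positive MCI.
#' GM trajectories decline quadratically with age; MCI atrophy is strongest
#' in MTL (15%) and temporal (12%) regions; the amyloid effect in CN is a
#' subtle 1-2% reduction.
#'
#' @param n_cn,n_mci Group sizes (>= 1).
#' @param age_cn,age_mci Numeric `c(mean, sd)` in years per group.
#' @param age_range Truncation range `c(min, max)` in years.
#' @param p_amyloid_pos_cn,p_amyloid_pos_mci Amyloid-positive probabilities.
#' @param trajectory Tibble with columns `roi, g0, r1, r2, a_ref` defining
#'   `g(age) = g0 * max(0, 1 - r1 (age - a_ref) - r2 (age - a_ref)^2)`.
#' @param amyloid_effect,mci_effect Named fractional GM reductions per ROI,
#'   in \[0, 1).
#' @param subject_sd Lognormal sdlog of the per-subject global scale.
#' @param voxel_sd Additive Gaussian voxel noise SD (concentration units).
#' @param grid_shape Integer length-3 grid (default 24^3, chosen small so a
#'   full factorial run stays fast).
#' @param voxel_size Voxel edge lengths in mm.
#' @param seed Integer RNG seed; cohorts are exactly reproducible per seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cn = 141, n_mci = 91,
                        age_cn = c(73.45, 5.75), age_mci = c(70.84, 7.50),
                        age_range = c(60, 90),
                        p_amyloid_pos_cn = 0.24, p_amyloid_pos_mci = 0.46,
                        trajectory = default_trajectory(),
                        amyloid_effect = default_amyloid_effect(),
                        mci_effect = default_mci_effect(),
                        subject_sd = 0.05, voxel_sd = 0.05,
                        grid_shape = c(24, 24, 24), voxel_size = c(2, 2, 2),
                        seed = 1L) {
  if (n_cn < 1 || n_mci < 1) stop_parameter("group sizes must be >= 1")
  for (p in c(p_amyloid_pos_cn, p_amyloid_pos_mci)) {
    if (p < 0 || p > 1) stop_parameter("amyloid probabilities must lie in [0, 1]")
  }
  if (any(amyloid_effect < 0) || any(amyloid_effect >= 1) ||
      any(mci_effect < 0) || any(mci_effect >= 1)) {
    stop_parameter("ROI effects must lie in [0, 1)")
  }
  if (subject_sd < 0 || voxel_sd < 0) stop_parameter("noise SDs must be >= 0")
  structure(
    list(n_cn = as.integer(n_cn), n_mci = as.integer(n_mci),
         age_cn = age_cn, age_mci = age_mci, age_range = age_range,
         p_amyloid_pos_cn = p_amyloid_pos_cn,
         p_amyloid_pos_mci = p_amyloid_pos_mci,
         trajectory = as_tibble(trajectory),
         amyloid_effect = amyloid_effect, mci_effect = mci_effect,
         subject_sd = subject_sd, voxel_sd = voxel_sd,
         grid_shape = as.integer(rep_len(grid_shape, 3L)),
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Deterministic block-layout ROI atlas
#'
#' Partitions the grid interior (a 2-voxel border is left as background)
#' into six disjoint rectangular blocks standing in for MTL, frontal,
#' temporal, parietal, occipital, and remaining gray matter. The layout is
#' a pure function of the grid, so identical inputs give identical atlases.
#'
#' @param grid_shape Integer length-3, each axis >= 16.
#' @param voxel_size Voxel edge lengths in mm.
#' @return An `roi_atlas` with six ROIs, each at least 27 voxels.
#' @export
generate_atlas <- function(grid_shape = c(24, 24, 24), voxel_size = c(2, 2, 2)) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 16L)) {
    stop_parameter("grid_shape must be >= 16 on every axis to host 6 ROI blocks")
  }
  d <- grid_shape
  border <- 2L
  # interior split: 2 slabs along x, 3 slabs along y, 1-voxel gaps
  split_axis <- function(n, parts) {
    usable <- n - 2L * border - (parts - 1L)
    len <- usable %/% parts
    starts <- border + 1L + (seq_len(parts) - 1L) * (len + 1L)
    lapply(starts, function(s) s:(s + len - 1L))
  }
  xs <- split_axis(d[1], 2L)
  ys <- split_axis(d[2], 3L)
  zr <- (border + 1L):(d[3] - border)
  labels <- array(0L, d)
  lab <- 0L
  for (i in 1:2) {
    for (j in 1:3) {
      lab <- lab + 1L
      labels[xs[[i]], ys[[j]], zr] <- lab
    }
  }
  atlas <- roi_atlas(labels, tibble(label = 1:6, name = ROI_NAMES), voxel_size)
  sizes <- vapply(atlas_roi_indices(atlas)[ROI_NAMES], length, integer(1))
  if (any(sizes < 27L)) {
    stop_parameter("grid too small: every ROI must contain >= 27 voxels")
  }
  atlas
}

#' Age trajectory of regional gray-matter level
#'
#' `g(age) = g0 * max(0, 1 - r1 (age - a_ref) - r2 (age - a_ref)^2)`.
#' The quadratic term makes decline accelerate with age, the behavior that
#' biases a single broad-age reference group.
#'
#' @param age Age in years (vectorized).
#' @param params List or one-row data frame with `g0, r1, r2, a_ref`.
#' @return Nonnegative GM scale; equals `g0` at the reference age.
#' @export
aging_trajectory <- function(age, params) {
  da <- age - params$a_ref
  params$g0 * pmax(0, 1 - params$r1 * da - params$r2 * da^2)
}

# Deterministic per-subject RNG seed derived from (cohort seed, subject id),
# so cohorts are extensible without reshuffling existing subjects.
subject_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 268435399
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate one subject's gray-matter volume
#'
#' Voxel value inside ROI `r`:
#' `g_r(age) * (1 - amyloid_effect_r * A) * (1 - mci_effect_r * M) * scale + noise`,
#' truncated at 0, where `A`/`M` indicate amyloid positivity / MCI, `scale`
#' is the subject's lognormal global factor and noise is iid Gaussian.
#' Background voxels are exactly 0.
#'
#' @param record One-row data frame or list with `id, age, group,
#'   amyloid_positive`.
#' @param atlas An `roi_atlas` from [generate_atlas()].
#' @param spec A `cohort_spec`.
#' @param seed Integer seed for this subject's RNG stream; defaults to a
#'   hash of `(spec$seed, record$id)`.
#' @return A `gm_volume`.
#' @export
generate_subject_volume <- function(record, atlas, spec,
                                    seed = subject_seed(spec$seed, record$id)) {
  if (record$age < spec$age_range[1] || record$age > spec$age_range[2]) {
    stop_parameter("subject age outside the spec age range")
  }
  set.seed(seed)
  scale <- exp(rnorm(1, 0, spec$subject_sd))
  vol <- array(0, dim(atlas$labels))
  idx <- atlas_roi_indices(atlas)
  for (i in seq_len(nrow(spec$trajectory))) {
    pr <- spec$trajectory[i, ]
    roi <- pr$roi
    level <- aging_trajectory(record$age, pr)
    if (isTRUE(record$amyloid_positive)) level <- level * (1 - spec$amyloid_effect[[roi]])
    if (record$group == "MCI") level <- level * (1 - spec$mci_effect[[roi]])
    vol[idx[[roi]]] <- level * scale
  }
  labeled <- idx$total
  if (spec$voxel_sd > 0) {
    vol[labeled] <- vol[labeled] + rnorm(length(labeled), 0, spec$voxel_sd)
  }
  vol[vol < 0] <- 0
  gm_volume(vol, spec$voxel_size)
}

#' Generate a full synthetic cohort
#'
#' Draws the subject table (ages from a truncated normal rounded to 0.1 y,
#' balanced sex, amyloid status Bernoulli with SUVR drawn consistently
#' around the 1.11 positivity cut-off) and, optionally, one GM volume per
#' subject. Exactly reproducible per seed; CN/MCI counts are exactly as
#' requested.
#'
#' @param spec A `cohort_spec`.
#' @param volumes If `FALSE`, generate the subject table only (fast path for
#'   large-n sampling checks).
#' @return A `zmatch_cohort`: list with `records` (tibble), `volumes`
#'   (named list of `gm_volume`), `atlas`, `spec`.
#' @export
generate_cohort <- function(spec, volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  draw_group <- function(n, prefix, age_par, p_pos) {
    age <- round(rtrunc_norm(n, age_par[1], age_par[2],
                             spec$age_range[1], spec$age_range[2]), 1)
    sex <- ifelse(runif(n) < 0.5, "M", "F")
    pos <- runif(n) < p_pos
    suvr <- ifelse(pos, runif(n, 1.12, 1.60), runif(n, 0.85, 1.10))
    tibble(id = sprintf("%s%04d", prefix, seq_len(n)), age = age, sex = sex,
           group = ifelse(prefix == "CN", "CN", "MCI"),
           amyloid_suvr = round(suvr, 3), amyloid_positive = pos)
  }
  records <- dplyr::bind_rows(
    draw_group(spec$n_cn, "CN", spec$age_cn, spec$p_amyloid_pos_cn),
    draw_group(spec$n_mci, "MCI", spec$age_mci, spec$p_amyloid_pos_mci)
  )
  atlas <- generate_atlas(spec$grid_shape, spec$voxel_size)
  vols <- NULL
  if (volumes) {
    vols <- lapply(seq_len(nrow(records)), function(i) {
      generate_subject_volume(records[i, ], atlas, spec)
    })
    names(vols) <- records$id
  }
  structure(list(records = records, volumes = vols, atlas = atlas, spec = spec),
            class = "zmatch_cohort")
}

#' @export
print.zmatch_cohort <- function(x, ...) {
  cat(sprintf("<zmatch_cohort: %d CN, %d MCI, grid %s%s>\n",
              sum(x$records$group == "CN"), sum(x$records$group == "MCI"),
              x$atlas$grid_id,
              if (is.null(x$volumes)) ", records only" else ""))
  invisible(x)
}

# Stack cohort volumes into a voxels x subjects matrix (column names = ids).
cohort_matrix <- function(cohort) {
  stopifnot(!is.null(cohort$volumes))
  vapply(cohort$volumes, function(v) as.numeric(v$data),
         numeric(prod(dim(cohort$atlas$labels))))
}

#' Write a cohort to disk (CSV table + NIfTI volumes + atlas TSV)
#'
#' @param cohort A `zmatch_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  utils::write.table(cohort$atlas$label_table, file.path(dir, "atlas_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$volumes)) {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (id in names(cohort$volumes)) {
      write_volume(cohort$volumes[[id]], file.path(vdir, paste0(id, ".nii.gz")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv`, `atlas.nii.gz`,
#'   `atlas_labels.tsv`, and a `volumes/` directory of per-subject NIfTI.
#' @return A `zmatch_cohort` (with `spec = NULL`).
#' @export
read_cohort <- function(dir) {
  records <- as_tibble(utils::read.csv(file.path(dir, "cohort.csv")))
  records$amyloid_positive <- as.logical(records$amyloid_positive)
  atlas <- read_volume(file.path(dir, "atlas.nii.gz"), type = "atlas",
                       label_table_path = file.path(dir, "atlas_labels.tsv"))
  vols <- lapply(records$id, function(id) {
    read_volume(file.path(dir, "volumes", paste0(id, ".nii.gz")))
  })
  names(vols) <- records$id
  spec <- cohort_spec(grid_shape = dim(atlas$labels), voxel_size = atlas$voxel_size)
  structure(list(records = records, volumes = vols, atlas = atlas, spec = spec),
            class = "zmatch_cohort")
}
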