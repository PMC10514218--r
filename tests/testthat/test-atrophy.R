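# Builds references directly from hand-made volumes so the Z arithmetic can
# be checked against closed forms.

ref_const <- function(mean_val, sd_val, d = c(8, 8, 8)) {
  # two volumes mean_val +/- sd_val/sqrt(2) give exactly (mean_val, sd_val)
  h <- sd_val / sqrt(2)
  build_reference(list(const_vol(mean_val - h, d = d),
                       const_vol(mean_val + h, d = d)))
}

test_that("Z-map arithmetic and masking follow the definition", {
  ref <- ref_const(0.6, 0.05)
  z <- compute_zmap(const_vol(0.5), ref)
  expect_equal(unique(z$data[!is.na(z$data)]), -2)
  expect_equal(z$flagged_voxels, 0)

  z0 <- compute_zmap(ref$mean_map, ref)
  expect_true(all(z0$data[!is.na(z0$data)] == 0))

  # sub-epsilon reference mean voxels are outside the mask
  expect_true(all(is.na(compute_zmap(const_vol(0.5), ref_const(0.01, 0.05))$data)))

  # SD below the floor: flagged, excluded via NA sentinel
  zf <- compute_zmap(const_vol(0.5), ref_const(0.6, 0))
  expect_true(all(is.na(zf$data)))
  expect_equal(zf$flagged_voxels, 8^3)
})

test_that("reference members standardize to mean 0 and SD 1", {
  vols <- lapply(1:12, rand_vol)
  names(vols) <- sprintf("CN%04d", 1:12)
  ref <- build_reference(vols)
  zs <- sapply(vols, function(v) as.numeric(compute_zmap(v, ref)$data))
  keep <- stats::complete.cases(zs)
  expect_gt(sum(keep), 0)
  expect_lt(max(abs(rowMeans(zs[keep, ]))), 1e-10)
  expect_lt(max(abs(apply(zs[keep, ], 1, sd) - 1)), 1e-10)
})

test_that("W-maps reduce to Z-maps and follow the regression arithmetic", {
  d <- c(8, 8, 8)
  ages <- c(62, 68, 71, 75, 81, 86)
  set.seed(71)
  vols <- lapply(ages, function(a) {
    gm_volume(array(0.9 - 0.004 * a + rnorm(prod(d), 0, 0.02), d), c(2, 2, 2))
  })
  wm <- fit_wscore_model(vols, ages)

  # subject exactly on the fitted plane: W = 0
  on_plane <- gm_volume(array(wm$intercept_map$data + wm$slope_map$data * 74, d),
                        c(2, 2, 2))
  w0 <- compute_wmap(on_plane, 74, wm)
  expect_lt(max(abs(w0$data[!is.na(w0$data)])), 1e-10)

  # slope frozen to zero: W equals Z against (intercept, resid_sd)
  wm_flat <- wm
  wm_flat$slope_map$data[] <- 0
  subj <- rand_vol(72, lo = 0.5, hi = 0.9)
  w <- compute_wmap(subj, 80, wm_flat)
  ref <- zmatch:::new_reference_model(wm$intercept_map, wm$resid_sd_map,
                                      sprintf("CN%04d", seq_along(ages)),
                                      "standard")
  z <- compute_zmap(subj, ref, epsilon = wm$epsilon)
  same <- !is.na(w$data) & !is.na(z$data)
  expect_identical(is.na(w$data), is.na(z$data))
  expect_lt(max(abs(w$data[same] - z$data[same])), 1e-12)

  # 0.1 below prediction with residual SD 0.05 gives W = -2
  wm2 <- wm
  wm2$resid_sd_map$data[] <- 0.05
  below <- gm_volume(array(wm2$intercept_map$data + wm2$slope_map$data * 70 - 0.1, d),
                     c(2, 2, 2))
  w2 <- compute_wmap(below, 70, wm2)
  expect_equal(unique(round(w2$data[!is.na(w2$data)], 9)), -2)
})

test_that("subthreshold counting is exact, masked, and monotone", {
  atlas <- generate_atlas(c(16, 16, 16))
  idx <- atlas_roi_indices(atlas)
  ref <- ref_const(0.6, 0.05, d = c(16, 16, 16))

  z0 <- compute_zmap(ref$mean_map, ref)
  for (roi in names(idx)) {
    expect_equal(count_subthreshold(z0, atlas, roi, -2.5), 0)
  }

  # constructed map: exactly 7 MTL voxels at Z = -4
  vol <- ref$mean_map
  vol$data[idx$MTL[1:7]] <- 0.6 - 4 * 0.05
  z <- compute_zmap(vol, ref)
  expect_equal(count_subthreshold(z, atlas, "MTL", -3.5), 7)
  expect_equal(count_subthreshold(z, atlas, "MTL", -4.5), 0)
  expect_equal(count_subthreshold(z, atlas, "total", -3.5), 7)
  expect_error(count_subthreshold(z, atlas, "cerebellum", -3.5),
               class = "zmatch_error_parameter")
  expect_error(count_subthreshold(z, atlas, "MTL", 2.5),
               class = "zmatch_error_parameter")

  # monotonicity across thresholds on random Z-like inputs
  for (s in 1:5) {
    noisy <- ref$mean_map
    set.seed(80 + s)
    noisy$data <- noisy$data + array(rnorm(16^3, 0, 0.15), dim(noisy$data))
    zn <- compute_zmap(noisy, ref)
    for (roi in c("MTL", "total")) {
      cnts <- vapply(c(-2.5, -3.5, -4.5), function(th)
        count_subthreshold(zn, atlas, roi, th), numeric(1))
      expect_true(all(diff(cnts) <= 0))
    }
  }
})

test_that("extent tables have factorial cardinality and are deterministic", {
  spec <- cohort_spec(n_cn = 2, n_mci = 1, grid_shape = c(16, 16, 16), seed = 17)
  co <- generate_cohort(spec)
  co$records <- co$records[1:2, ]
  co$volumes <- co$volumes[1:2]
  ext <- build_extent_table(co, strategies = list(reference_strategy("standard")))
  # 2 subjects x (6 ROIs + total) x 3 thresholds x 4 kernels x 1 reference
  expect_equal(nrow(ext), 168)
  expect_true(all(ext$n_subthreshold >= 0))
  expect_true(all(ext$n_subthreshold == round(ext$n_subthreshold)))
  expect_equal(ext$volume_mm3, ext$n_subthreshold * prod(spec$voxel_size))

  ext2 <- build_extent_table(co, strategies = list(reference_strategy("standard")))
  expect_identical(as.data.frame(ext), as.data.frame(ext2))
})

test_that("noise-free all-CN cohort scores zero everywhere against itself", {
  spec <- cohort_spec(n_cn = 8, n_mci = 1, subject_sd = 0, voxel_sd = 0,
                      grid_shape = c(16, 16, 16), seed = 19)
  co <- generate_cohort(spec)
  keep <- co$records$group == "CN" & !co$records$amyloid_positive &
    abs(co$records$age - 72) < 6
  # at least two identical-model CN are needed; ages differ, so restrict to
  # a tight bracket where trajectories are close but not identical
  co$records <- co$records[co$records$group == "CN", ]
  co$volumes <- co$volumes[co$records$id]
  ext <- build_extent_table(co, strategies = list(reference_strategy("standard")),
                            kernels = 0, rois = "total")
  # every subject is a reference member: with zero noise the only spread is
  # age/amyloid structure, so Z stays far above -2.5
  expect_true(all(ext$n_subthreshold == 0))
})

test_that("leave-one-out standard scoring matches direct recomputation", {
  spec <- cohort_spec(n_cn = 10, n_mci = 3, grid_shape = c(16, 16, 16), seed = 37)
  co <- generate_cohort(spec)
  ext <- build_extent_table(co, strategies = default_strategies()["standard"],
                            kernels = 0, rois = "total", exclude_self = TRUE)
  cn <- co$records$id[co$records$group == "CN"]
  for (id in cn[c(1, 5, 10)]) {
    ref <- build_reference(co$volumes[setdiff(cn, id)])
    z <- compute_zmap(co$volumes[[id]], ref)
    for (th in c(-2.5, -3.5)) {
      expect_equal(
        ext$n_subthreshold[ext$subject_id == id & ext$z_threshold == th],
        count_subthreshold(z, co$atlas, "total", th))
    }
  }
  # MCI subjects are not members; their scores match the full reference
  full <- build_standard_reference(co)
  zm <- compute_zmap(co$volumes[["MCI0001"]], full)
  expect_equal(
    ext$n_subthreshold[ext$subject_id == "MCI0001" & ext$z_threshold == -2.5],
    count_subthreshold(zm, co$atlas, "total", -2.5))
})

test_that("skipped subjects are recorded with their target age", {
  spec <- cohort_spec(n_cn = 25, n_mci = 10, grid_shape = c(16, 16, 16), seed = 23)
  co <- generate_cohort(spec)
  ext <- build_extent_table(co, strategies = default_strategies()["bracket_5y"],
                            kernels = 0, rois = "total")
  sk <- skipped_subjects(ext)
  scored <- unique(ext$subject_id)
  expect_setequal(c(scored, unique(sk$subject_id)), co$records$id)
  if (nrow(sk) > 0) {
    expect_true(all(sk$reference_type == "bracket_5y"))
    expect_true(all(is.finite(sk$target_age)))
  }
})
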