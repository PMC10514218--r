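# Volume containers, NIfTI I/O, Gaussian smoothing, brain masks.
#
# All volumes live on a fixed voxel grid identified by a grid token
# (shape + voxel size); operations across objects require identical grids.
# Smoothing uses zero padding outside the grid, the standard VBM choice:
# edge voxels are attenuated because part of the kernel mass falls outside.

#' Construct a gray-matter volume
#'
#' A `gm_volume` holds one subject's 3-D modulated gray-matter concentration
#' map (dimensionless, typically in \[0, ~1.5\]) together with the physical
#' voxel size in mm.
#'
#' @param data 3-D numeric array, all values finite.
#' @param voxel_size Numeric length-3 (or scalar, recycled), mm per axis,
#'   strictly positive.
#' @return An object of class `gm_volume` with fields `data`, `voxel_size`,
#'   `grid_id`.
#' @export
gm_volume <- function(data, voxel_size = c(2, 2, 2)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_format("gm_volume data must be a 3-D array")
  }
  if (!all(is.finite(data))) {
    stop_format("gm_volume data must be finite everywhere")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) {
    stop_parameter("voxel_size must be strictly positive")
  }
  structure(
    list(data = data, voxel_size = voxel_size,
         grid_id = grid_token(dim(data), voxel_size)),
    class = "gm_volume"
  )
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume %s, range [%.3g, %.3g]>\n",
              x$grid_id, min(x$data), max(x$data)))
  invisible(x)
}

#' Construct an ROI atlas
#'
#' Integer label field on the volume grid; 0 marks background. Every nonzero
#' label must appear in `label_table`. "Total gray matter" is defined
#' throughout the package as the union of all nonzero labels.
#'
#' @param labels 3-D integer-valued array, 0 = background.
#' @param label_table Data frame with columns `label` (integer) and `name`.
#' @param voxel_size Numeric length-3, mm.
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, label_table, voxel_size = c(2, 2, 2)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop_format("atlas labels must be a 3-D array")
  }
  if (any(labels != round(labels))) {
    stop_format("atlas labels must be integer-valued")
  }
  label_table <- as_tibble(label_table)
  if (!all(c("label", "name") %in% names(label_table))) {
    stop_format("label_table needs columns 'label' and 'name'")
  }
  present <- sort(unique(as.integer(labels[labels != 0])))
  missing <- setdiff(present, label_table$label)
  if (length(missing) > 0) {
    stop_format(sprintf("atlas labels without a label_table entry: %s",
                        paste(missing, collapse = ", ")))
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  structure(
    list(labels = array(as.integer(round(labels)), dim(labels)),
         label_table = label_table, voxel_size = voxel_size,
         grid_id = grid_token(dim(labels), voxel_size)),
    class = "roi_atlas"
  )
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas %s, %d ROIs, %d labeled voxels>\n", x$grid_id,
              nrow(x$label_table), sum(x$labels != 0)))
  invisible(x)
}

#' Voxel index sets for each ROI, plus the total-GM union
#'
#' @param atlas An `roi_atlas`.
#' @return Named list of integer voxel indices, one per ROI name plus
#'   `"total"` (union of all nonzero labels).
#' @export
atlas_roi_indices <- function(atlas) {
  lab <- as.integer(atlas$labels)
  out <- lapply(seq_len(nrow(atlas$label_table)), function(i) {
    which(lab == atlas$label_table$label[i])
  })
  names(out) <- atlas$label_table$name
  out$total <- which(lab != 0L)
  out
}

#' Convert a Gaussian kernel FWHM to its standard deviation
#'
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, the usual neuroimaging convention.
#'
#' @param fwhm_mm Full width at half maximum, mm; must be >= 0.
#' @return Sigma in mm.
#' @examples
#' fwhm_to_sigma(8) # 3.397287
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0)) {
    stop_parameter("fwhm_mm must be finite and >= 0")
  }
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# 1-D sampled Gaussian kernel, normalized to unit mass. Radius 6 sigma keeps
# the truncated tail mass ~1e-9 so the semigroup property holds numerically.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- ceiling(6 * sigma_vox)
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# n x n convolution operator with zero padding: (K v)[i] = sum_j k[i-j] v[j]
conv_operator <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1L & idx <= n
    K[idx[ok], j] <- k[ok]
  }
  K
}

# Separable convolution of a 3-D array with per-axis 1-D kernels.
smooth_array <- function(arr, voxel_size, sigma_mm) {
  d <- dim(arr)
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / voxel_size[ax]
    if (sigma_vox <= 0) next
    K <- conv_operator(d[ax], gauss_kernel_1d(sigma_vox))
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- if (ax == 1) arr else aperm(arr, perm)
    dd <- dim(a)
    a <- array(K %*% matrix(a, dd[1], dd[2] * dd[3]), dd)
    arr <- switch(ax, `1` = a, `2` = aperm(a, c(2, 1, 3)), `3` = aperm(a, c(2, 3, 1)))
  }
  arr
}

#' Gaussian smoothing of a gray-matter volume
#'
#' Separable convolution with a sampled Gaussian kernel; the FWHM is given in
#' mm and converted per axis to voxel units, so anisotropic voxels are
#' handled correctly. Zero padding is used outside the grid, so edge voxels
#' are attenuated. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param vol A `gm_volume`.
#' @param fwhm_mm Kernel FWHM in mm, >= 0.
#' @return A smoothed `gm_volume` on the same grid.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "gm_volume"))
  sigma <- fwhm_to_sigma(fwhm_mm)
  if (sigma == 0) return(vol)
  gm_volume(smooth_array(vol$data, vol$voxel_size, sigma), vol$voxel_size)
}

#' Read a volume or atlas from a NIfTI-1 file
#'
#' @param path Path to a `.nii`/`.nii.gz` file holding a 3-D scalar image.
#' @param type `"gm"` for a gray-matter volume, `"atlas"` for an
#'   integer-labeled atlas (requires `label_table` or a TSV sidecar via
#'   `label_table_path` with columns `label<TAB>name`).
#' @param label_table,label_table_path Label table for atlas reads.
#' @return A `gm_volume` or `roi_atlas`.
#' @export
read_volume <- function(path, type = c("gm", "atlas"),
                        label_table = NULL, label_table_path = NULL) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop_format(sprintf("expected a 3-D NIfTI image, got %d dimensions in '%s'",
                        length(d), path))
  }
  vox <- RNifti::pixdim(img)[1:3]
  dat <- array(as.numeric(img), d)
  if (type == "gm") {
    return(gm_volume(dat, vox))
  }
  if (any(dat != round(dat))) {
    stop_format(sprintf("atlas file '%s' contains non-integer values", path))
  }
  if (is.null(label_table)) {
    if (is.null(label_table_path)) {
      stop_parameter("atlas reads need label_table or label_table_path")
    }
    label_table <- utils::read.delim(label_table_path, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
  }
  roi_atlas(dat, label_table, vox)
}

#' Write a volume, atlas, or mask as NIfTI-1
#'
#' Data are written as doubles so a write-then-read round-trip is bit exact.
#'
#' @param obj A `gm_volume`, `roi_atlas`, or `brain_mask`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(obj, path) {
  dat <- if (inherits(obj, "gm_volume")) obj$data
         else if (inherits(obj, "roi_atlas")) obj$labels + 0
         else if (inherits(obj, "brain_mask")) obj$mask + 0
         else stop_parameter("write_volume needs a gm_volume, roi_atlas, or brain_mask")
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- obj$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Build a brain mask from a reference mean map
#'
#' The mask keeps voxels whose mean GM concentration exceeds `epsilon`,
#' restricting Z computation to voxels with reference support and keeping
#' near-zero-SD background out of the statistics.
#'
#' @param mean_vol A `gm_volume` (typically a reference mean map).
#' @param epsilon Concentration threshold, >= 0. Default 0.05 excludes
#'   background while keeping the simulated cortical ribbon.
#' @return A `brain_mask` with logical field `mask`.
#' @export
make_brain_mask <- function(mean_vol, epsilon = 0.05) {
  stopifnot(inherits(mean_vol, "gm_volume"))
  if (!is.finite(epsilon) || epsilon < 0) {
    stop_parameter("epsilon must be >= 0")
  }
  structure(
    list(mask = mean_vol$data > epsilon, voxel_size = mean_vol$voxel_size,
         grid_id = mean_vol$grid_id),
    class = "brain_mask"
  )
}
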