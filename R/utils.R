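# Internal helpers shared across modules: grid identity, error constructors.

grid_token <- function(dim, voxel_size) {
  paste0(paste(dim, collapse = "x"), "@",
         paste(format(voxel_size, trim = TRUE), collapse = "x"), "mm")
}

stop_parameter <- function(msg) {
  abort(msg, class = "zmatch_error_parameter")
}

stop_format <- function(msg) {
  abort(msg, class = "zmatch_error_format")
}

stop_grid <- function(msg) {
  abort(msg, class = "zmatch_error_grid")
}

stop_coverage <- function(msg, target_age) {
  abort(msg, class = "zmatch_error_coverage", target_age = target_age)
}

#' Check that two volume-like objects share a grid
#'
#' Grid compatibility means identical array dimensions and voxel sizes; no
#' resampling is performed anywhere in the package, so every pairwise
#' operation requires it.
#'
#' @param a,b Objects with `grid_id` fields (`gm_volume`, `roi_atlas`,
#'   `brain_mask`, `reference_model`).
#' @return Invisibly `TRUE`; signals a grid error otherwise.
#' @export
check_same_grid <- function(a, b) {
  if (!identical(a$grid_id, b$grid_id)) {
    stop_grid(sprintf("grid mismatch: '%s' vs '%s' (shape and voxel size must be identical)",
                      a$grid_id, b$grid_id))
  }
  invisible(TRUE)
}
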