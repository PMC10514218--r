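# Shared fixtures: small cohort specs and cached replicate simulations.
# All fixtures are generated in code under fixed seeds.

const_vol <- function(value, d = c(8, 8, 8), vox = c(2, 2, 2)) {
  gm_volume(array(value, d), vox)
}

rand_vol <- function(seed, d = c(8, 8, 8), vox = c(2, 2, 2),
                     lo = 0.3, hi = 1.0) {
  set.seed(seed)
  gm_volume(array(runif(prod(d), lo, hi), d), vox)
}

# small, fast cohort for module tests
small_spec <- function(...) {
  cohort_spec(n_cn = 30, n_mci = 15, grid_shape = c(16, 16, 16), seed = 7, ...)
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(small_spec())
    cache
  }
})

# Replicate simulations shared between property and acceptance tests;
# computed once per session.
.zm_sims <- new.env(parent = emptyenv())

ordering_sim <- function() {
  if (is.null(.zm_sims$ordering)) {
    .zm_sims$ordering <- simulate_reference_comparison(
      spec = cohort_spec(), n_reps = 20, seed = 101,
      strategies = default_strategies(),
      roi = "total", threshold = -3.5, fwhm = 0)
  }
  .zm_sims$ordering
}

null_sim <- function() {
  if (is.null(.zm_sims$null)) {
    # leave-one-out scoring: with self-inclusion a CN shrinks its own
    # reference Z, so the label would not be exchangeable even at zero effect
    .zm_sims$null <- simulate_reference_comparison(
      spec = null_cohort_spec(), n_reps = 50, seed = 202,
      strategies = default_strategies()[c("standard", "bracket_10y")],
      roi = "total", threshold = -2.5, fwhm = 0, exclude_self = TRUE)
  }
  .zm_sims$null
}
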