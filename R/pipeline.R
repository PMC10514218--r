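# End-to-end orchestration: factorial runs over reference strategies x
# ROIs x Z-thresholds x smoothing kernels, producing extent tables, AUC
# grids with paired DeLong comparisons against the standard reference, and
# per-cell Wilcoxon group tests. Paired comparisons always use the
# intersection of subjects scored under both strategies (bracket coverage
# shrinks samples at the age extremes); the per-strategy AUCs in the grid
# are computed on each strategy's full scored sample.

#' Run configuration
#'
#' @param spec A `cohort_spec` for synthetic input (ignored when `cohort`
#'   or `input_dir` is given).
#' @param cohort An existing `zmatch_cohort`.
#' @param input_dir Directory in [write_cohort()] layout (file mode).
#' @param strategies List of [reference_strategy()] descriptors.
#' @param k Bracket member count, default 20.
#' @param thresholds Negative Z thresholds, default -2.5, -3.5, -4.5.
#' @param kernels Smoothing FWHM in mm, default 0, 2, 4, 8.
#' @param rois ROI names (`NULL` = all atlas ROIs + total).
#' @param exclude_self Leave each subject out of its own reference.
#' @param sd_floor,epsilon Masking policy.
#' @param raw_alpha Per-cell significance level for group tests (the
#'   Bonferroni-interpreted alpha is reported alongside).
#' @param seed Integer seed (used when generating synthetic input).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = cohort_spec(), cohort = NULL, input_dir = NULL,
                       strategies = default_strategies(), k = 20,
                       thresholds = c(-2.5, -3.5, -4.5),
                       kernels = c(0, 2, 4, 8), rois = NULL,
                       exclude_self = FALSE, sd_floor = 1e-4, epsilon = 0.05,
                       raw_alpha = 1e-4, seed = 1L, out_dir = NULL) {
  if (length(strategies) < 1) stop_parameter("need at least one reference strategy")
  if (length(thresholds) < 1 || any(thresholds >= 0)) {
    stop_parameter("need at least one negative Z threshold")
  }
  if (length(kernels) < 1 || any(kernels < 0)) {
    stop_parameter("need at least one nonnegative smoothing kernel")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_parameter(sprintf("input_dir '%s' does not exist", input_dir))
  }
  structure(
    list(spec = spec, cohort = cohort, input_dir = input_dir,
         strategies = strategies, k = k, thresholds = thresholds,
         kernels = kernels, rois = rois, exclude_self = exclude_self,
         sd_floor = sd_floor, epsilon = epsilon, raw_alpha = raw_alpha,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort)) return(config$cohort)
  if (!is.null(config$input_dir)) return(read_cohort(config$input_dir))
  spec <- config$spec
  spec$seed <- config$seed
  generate_cohort(spec)
}

# Per-cell score table: subject_id, group, score; one cell = one
# (reference_type, roi, z_threshold, fwhm_mm) combination.
cell_scores <- function(extents) {
  dplyr::group_by(extents, .data$reference_type, .data$roi,
                  .data$z_threshold, .data$fwhm_mm)
}

auc_grid_from_extents <- function(extents, baseline = "standard") {
  nested <- tidyr::nest(cell_scores(extents))
  has_baseline <- baseline %in% nested$reference_type
  base_tbl <- if (has_baseline) {
    dplyr::filter(nested, .data$reference_type == baseline)
  } else NULL
  rows <- purrr::pmap(nested, function(reference_type, roi, z_threshold,
                                       fwhm_mm, data) {
    rr <- roc_auc(data, .data$n_subthreshold, .data$group)
    out <- tibble(
      reference_type = reference_type, roi = roi, z_threshold = z_threshold,
      fwhm_mm = fwhm_mm, auc = rr$auc, ci_lower = rr$ci_lower,
      ci_upper = rr$ci_upper, optimal_cutoff = rr$optimal_cutoff,
      sensitivity = rr$sensitivity, specificity = rr$specificity,
      n_used = nrow(data), delong_p_vs_baseline = NA_real_,
      delong_degenerate = NA)
    if (has_baseline && reference_type != baseline) {
      bd <- base_tbl$data[[which(base_tbl$roi == roi &
                                 base_tbl$z_threshold == z_threshold &
                                 base_tbl$fwhm_mm == fwhm_mm)]]
      paired <- dplyr::inner_join(
        dplyr::select(data, "subject_id", "group", score_a = "n_subthreshold"),
        dplyr::select(bd, "subject_id", score_b = "n_subthreshold"),
        by = "subject_id")
      if (nrow(paired) > 0 && length(unique(paired$group)) == 2) {
        dl <- delong_test(paired, .data$score_a, .data$score_b, .data$group)
        out$delong_p_vs_baseline <- dl$p_value
        out$delong_degenerate <- dl$degenerate
      }
    }
    out
  })
  dplyr::bind_rows(rows)
}

group_tests_from_extents <- function(extents, raw_alpha = 1e-4) {
  nested <- tidyr::nest(cell_scores(extents))
  m <- nrow(nested)
  rows <- purrr::pmap(nested, function(reference_type, roi, z_threshold,
                                       fwhm_mm, data) {
    wt <- wilcoxon_rank_sum(data$n_subthreshold[data$group == "CN"],
                            data$n_subthreshold[data$group == "MCI"])
    tibble(reference_type = reference_type, roi = roi,
           z_threshold = z_threshold, fwhm_mm = fwhm_mm,
           U = wt$U, p_value = wt$p_value,
           significant = wt$p_value < raw_alpha)
  })
  out <- dplyr::bind_rows(rows)
  out$raw_alpha <- raw_alpha
  out$bonferroni_alpha <- bonferroni_alpha(raw_alpha, m)
  out
}

#' Run the full atrophy-quantification pipeline
#'
#' Generates or loads the cohort, builds per-kernel references under each
#' strategy, computes Z-maps and subthreshold extents, and evaluates every
#' (strategy, ROI, threshold, kernel) cell with ROC/AUC, Youden cut-offs,
#' Wilcoxon group tests, and paired DeLong comparisons against the standard
#' reference. Reruns with an identical configuration are reproducible.
#'
#' @param config A [run_config()].
#' @return A `zmatch_run`: list with `extents`, `auc_grid`, `group_tests`,
#'   `skips`, `coverage`, `records`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- resolve_cohort(config)
  extents <- build_extent_table(
    cohort, strategies = config$strategies, thresholds = config$thresholds,
    kernels = config$kernels, rois = config$rois, k = config$k,
    exclude_self = config$exclude_self, sd_floor = config$sd_floor,
    epsilon = config$epsilon)
  auc_grid <- auc_grid_from_extents(extents)
  group_tests <- group_tests_from_extents(extents, config$raw_alpha)
  cn <- cohort$records[cohort$records$group == "CN", ]
  coverage <- dplyr::bind_rows(lapply(config$strategies, function(s) {
    if (s$type != "bracket") return(NULL)
    rng <- coverage_ages(eligible_cn(cohort$records, s$amyloid_filter),
                         s$half_width, config$k)
    tibble(reference_type = s$name,
           min_age = if (is.null(rng)) NA_real_ else rng[1],
           max_age = if (is.null(rng)) NA_real_ else rng[2])
  }))
  run <- structure(
    list(extents = extents, auc_grid = auc_grid, group_tests = group_tests,
         skips = skipped_subjects(extents), coverage = coverage,
         records = cohort$records, config = config,
         version = as.character(utils::packageVersion("zmatch"))),
    class = "zmatch_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.zmatch_run <- function(x, ...) {
  cat(sprintf("<zmatch_run: %d subjects, %d extent rows, %d AUC cells, %d skips>\n",
              nrow(x$records), nrow(x$extents), nrow(x$auc_grid), nrow(x$skips)))
  best <- x$auc_grid[which.max(x$auc_grid$auc), ]
  cat(sprintf("  best AUC %.3f (%s, %s, Z %g, %g mm)\n", best$auc,
              best$reference_type, best$roi, best$z_threshold, best$fwhm_mm))
  invisible(x)
}

#' Write run artifacts (CSV tables + JSON config snapshot)
#'
#' @param run A `zmatch_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$extents, file.path(dir, "extents.csv"), row.names = FALSE)
  utils::write.csv(run$auc_grid, file.path(dir, "auc_grid.csv"), row.names = FALSE)
  utils::write.csv(run$group_tests, file.path(dir, "group_tests.csv"), row.names = FALSE)
  utils::write.csv(run$skips, file.path(dir, "skips.csv"), row.names = FALSE)
  cfg <- run$config
  snapshot <- list(
    version = run$version, seed = cfg$seed, k = cfg$k,
    thresholds = cfg$thresholds, kernels = cfg$kernels,
    strategies = lapply(cfg$strategies, unclass),
    exclude_self = cfg$exclude_self, sd_floor = cfg$sd_floor,
    epsilon = cfg$epsilon, raw_alpha = cfg$raw_alpha)
  jsonlite::write_json(snapshot, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Paired comparison of two reference strategies
#'
#' For every (ROI, threshold, kernel) cell, a paired DeLong test between the
#' two strategies restricted to the subjects scored under both (bracket
#' coverage shrinks samples; the intersection is mandatory for a valid
#' paired test). Cells with an empty intersection or a single class are
#' marked non-comparable.
#'
#' @param run A `zmatch_run` containing both strategies.
#' @param strategy_a,strategy_b Strategy names as they appear in
#'   `run$extents$reference_type`.
#' @return Tibble with per-cell paired AUCs, DeLong statistic and p-value,
#'   and a `comparable` flag.
#' @export
compare_reference_strategies <- function(run, strategy_a, strategy_b) {
  ext <- run$extents
  for (s in c(strategy_a, strategy_b)) {
    if (!s %in% ext$reference_type) {
      stop_parameter(sprintf("strategy '%s' not present in the run", s))
    }
  }
  a <- dplyr::filter(ext, .data$reference_type == strategy_a)
  b <- dplyr::filter(ext, .data$reference_type == strategy_b)
  paired <- dplyr::inner_join(
    dplyr::select(a, "subject_id", "group", "roi", "z_threshold", "fwhm_mm",
                  score_a = "n_subthreshold"),
    dplyr::select(b, "subject_id", "roi", "z_threshold", "fwhm_mm",
                  score_b = "n_subthreshold"),
    by = c("subject_id", "roi", "z_threshold", "fwhm_mm"))
  nested <- tidyr::nest(dplyr::group_by(paired, .data$roi, .data$z_threshold,
                                        .data$fwhm_mm))
  rows <- purrr::pmap(nested, function(roi, z_threshold, fwhm_mm, data) {
    base <- tibble(strategy_a = strategy_a, strategy_b = strategy_b,
                   roi = roi, z_threshold = z_threshold, fwhm_mm = fwhm_mm,
                   n_paired = nrow(data))
    if (nrow(data) == 0 || length(unique(data$group)) < 2) {
      return(dplyr::mutate(base, auc_a = NA_real_, auc_b = NA_real_,
                           auc_diff = NA_real_, statistic = NA_real_,
                           p_value = NA_real_, degenerate = NA,
                           comparable = FALSE))
    }
    dl <- delong_test(data, .data$score_a, .data$score_b, .data$group)
    dplyr::bind_cols(base, dplyr::select(dl, -"n_pos", -"n_neg"),
                     tibble(comparable = TRUE))
  })
  dplyr::bind_rows(rows)
}

#' The package's null simulation condition
#'
#' A cohort spec with zero MCI and amyloid effects and the MCI age
#' distribution set equal to the CN one. Under this condition the diagnosis
#' label carries no information at all, so AUC = 0.5 and uniform
#' strategy-comparison p-values are the correct expectations. (With the
#' default unequal age distributions, age itself separates the groups under
#' a broad-age reference, which is the effect under study, not a null.)
#'
#' @param ... Passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(...) {
  cohort_spec(age_mci = c(73.45, 5.75),
              p_amyloid_pos_mci = 0.24,
              amyloid_effect = c(MTL = 0, frontal = 0, temporal = 0,
                                 parietal = 0, occipital = 0, other_gm = 0),
              mci_effect = c(MTL = 0, frontal = 0, temporal = 0,
                             parietal = 0, occipital = 0, other_gm = 0),
              ...)
}

#' Replicate-cohort comparison of reference strategies
#'
#' Generates `n_reps` independent synthetic cohorts and, for one evaluation
#' cell (ROI, threshold, kernel), computes each strategy's AUC with DeLong
#' CI, all pairwise paired DeLong tests on the subject intersection, and
#' the mean extent of the oldest-decile CN under each strategy (the
#' age-bias diagnostic). This is the simulation engine behind the
#' reference-strategy ordering and null-calibration analyses.
#'
#' @param spec A `cohort_spec` (the per-replicate seed is `seed + rep`).
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed.
#' @param strategies Strategies to score.
#' @param roi,threshold,fwhm The evaluation cell.
#' @param decile_threshold Threshold used for the oldest-decile CN extent
#'   diagnostic; defaults to -2.5, the mildest threshold, where normal-range
#'   subjects still produce nonzero counts and the age bias of a broad-age
#'   reference is visible.
#' @param k Bracket member count.
#' @param exclude_self Leave each subject out of its own reference. The
#'   default `FALSE` mirrors routine practice (the index CN may be a
#'   reference member), which inflates CN-vs-MCI separation slightly; null
#'   calibration studies should set `TRUE` so the diagnosis label is truly
#'   exchangeable.
#' @return A `zmatch_sim`: list of tibbles `aucs`, `delong`, `decile`.
#' @export
simulate_reference_comparison <- function(spec = cohort_spec(), n_reps = 20,
                                          seed = 1L,
                                          strategies = default_strategies(),
                                          roi = "total", threshold = -3.5,
                                          fwhm = 0, decile_threshold = -2.5,
                                          k = 20, exclude_self = FALSE) {
  aucs <- list()
  dls <- list()
  dec <- list()
  strat_names <- vapply(strategies, `[[`, character(1), "name")
  for (rep_i in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- as.integer((seed + rep_i) %% 2147483647)
    cohort <- generate_cohort(sp)
    ext_all <- build_extent_table(
      cohort, strategies = strategies,
      thresholds = sort(unique(c(threshold, decile_threshold))),
      kernels = fwhm, rois = roi, k = k, exclude_self = exclude_self)
    ext <- dplyr::filter(ext_all, .data$z_threshold == threshold)
    # per-strategy AUC on each strategy's full scored sample
    for (s in strat_names) {
      cell <- dplyr::filter(ext, .data$reference_type == s)
      if (nrow(cell) == 0 || length(unique(cell$group)) < 2) next
      rr <- roc_auc(cell, .data$n_subthreshold, .data$group)
      aucs[[length(aucs) + 1]] <- tibble(
        rep = rep_i, strategy = s, auc = rr$auc, var_auc = rr$var_auc,
        ci_lower = rr$ci_lower, ci_upper = rr$ci_upper,
        n_used = rr$n_pos + rr$n_neg)
      cn_cell <- dplyr::filter(ext_all, .data$reference_type == s,
                               .data$group == "CN",
                               .data$z_threshold == decile_threshold)
      oldest <- cn_cell[cn_cell$age >= stats::quantile(cn_cell$age, 0.9), ]
      dec[[length(dec) + 1]] <- tibble(
        rep = rep_i, strategy = s,
        mean_extent_oldest_cn = mean(oldest$n_subthreshold),
        mean_extent_all_cn = mean(cn_cell$n_subthreshold))
    }
    # pairwise paired DeLong on intersections
    if (length(strat_names) >= 2) {
      pairs <- utils::combn(strat_names, 2, simplify = FALSE)
      for (pr in pairs) {
        a <- dplyr::filter(ext, .data$reference_type == pr[1])
        b <- dplyr::filter(ext, .data$reference_type == pr[2])
        paired <- dplyr::inner_join(
          dplyr::select(a, "subject_id", "group", score_a = "n_subthreshold"),
          dplyr::select(b, "subject_id", score_b = "n_subthreshold"),
          by = "subject_id")
        if (nrow(paired) == 0 || length(unique(paired$group)) < 2) next
        dl <- delong_test(paired, .data$score_a, .data$score_b, .data$group)
        dls[[length(dls) + 1]] <- dplyr::bind_cols(
          tibble(rep = rep_i, strategy_a = pr[1], strategy_b = pr[2]), dl)
      }
    }
  }
  structure(list(aucs = dplyr::bind_rows(aucs), delong = dplyr::bind_rows(dls),
                 decile = dplyr::bind_rows(dec),
                 cell = list(roi = roi, threshold = threshold, fwhm = fwhm)),
            class = "zmatch_sim")
}

#' @export
print.zmatch_sim <- function(x, ...) {
  cat(sprintf("<zmatch_sim: %d replicates, cell (%s, Z %g, %g mm)>\n",
              max(x$aucs$rep), x$cell$roi, x$cell$threshold, x$cell$fwhm))
  print(dplyr::summarise(dplyr::group_by(x$aucs, .data$strategy),
                         mean_auc = mean(.data$auc), .groups = "drop"))
  invisible(x)
}

#' Paired sign test between two strategies' replicate AUCs
#'
#' Counts replicates where `strategy_a`'s AUC exceeds `strategy_b`'s (ties
#' dropped) and returns the binomial sign-test p-value.
#'
#' @param sim A `zmatch_sim`.
#' @param strategy_a,strategy_b Strategy names.
#' @param alternative `"greater"` (a > b) or `"two.sided"`.
#' @return One-row tibble: `n_wins, n_losses, n_ties, p_value`.
#' @export
sign_test_aucs <- function(sim, strategy_a, strategy_b,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  wide <- tidyr::pivot_wider(
    dplyr::select(sim$aucs, "rep", "strategy", "auc"),
    names_from = "strategy", values_from = "auc")
  d <- wide[[strategy_a]] - wide[[strategy_b]]
  d <- d[!is.na(d)]
  wins <- sum(d > 0)
  losses <- sum(d < 0)
  p <- if (wins + losses == 0) 1 else
    binom.test(wins, wins + losses, 0.5, alternative = alternative)$p.value
  tibble(n_wins = wins, n_losses = losses, n_ties = sum(d == 0), p_value = p)
}
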