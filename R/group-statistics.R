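# Evaluation layer: ROC/AUC from the Mann-Whitney definition, Youden
# optimal cut-offs with midpoint reporting, paired DeLong AUC comparison
# from placement values, and the group-difference tests (t, Wilcoxon
# rank-sum, chi-square) with Bonferroni alpha arithmetic.
#
# AUC and the DeLong test are authored here from their definitions; the
# pROC package is used only as an independent cross-check in the test
# suite, never as the implementation.

# Mann-Whitney AUC with ties counted 1/2, via midranks. Exactly equals the
# exhaustive pairwise mean of [s_pos > s_neg] + 0.5 [s_pos == s_neg].
auc_mw <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop_parameter("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values for one score vector.
delong_placements <- function(scores, positive) {
  X <- scores[positive]
  Y <- scores[!positive]
  P <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(P), v01 = colMeans(P), auc = mean(P))
}

# DeLong variance of a single AUC.
delong_var <- function(pl) {
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

# Youden-optimal cut-off over all midpoint candidates; classification rule
# is score > cutoff -> positive. Ties in J break toward higher specificity,
# then toward the lower cutoff. Candidates are midpoints between adjacent
# distinct scores plus half-step points beyond the extremes, so reported
# cut-offs on integer voxel counts are half-integers.
cutoff_core <- function(scores, positive) {
  s <- sort(unique(scores))
  if (length(s) == 1) {
    gaps <- 1
    cand <- c(s - 0.5, s + 0.5)
  } else {
    gaps <- diff(s)
    cand <- c(s[1] - gaps[1] / 2, (s[-1] + s[-length(s)]) / 2,
              s[length(s)] + gaps[length(gaps)] / 2)
  }
  n1 <- sum(positive)
  n0 <- sum(!positive)
  best <- NULL
  for (cc in cand) {
    sens <- sum(scores[positive] > cc) / n1
    spec <- sum(scores[!positive] <= cc) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && cc < best$cutoff)))) {
      best <- list(cutoff = cc, sens = sens, spec = spec, j = j)
    }
  }
  best
}

tidy_pull <- function(data, col) {
  out <- rlang::eval_tidy(rlang::enquo(col), data)
  if (is.null(out)) stop_parameter("column not found in data")
  out
}

as_positive <- function(truth, positive) {
  if (is.logical(truth)) return(truth)
  truth == positive
}

#' ROC analysis of an atrophy score
#'
#' AUC is the Mann-Whitney probability that a positive (MCI) subject's score
#' exceeds a negative (CN) subject's, ties counted 1/2; higher extent means
#' more atrophy. The optimal cut-off maximizes Youden's J and is reported as
#' the midpoint between adjacent distinct scores. The AUC variance and 95%
#' CI come from the DeLong placement-value estimator.
#'
#' @param data Data frame with one row per subject.
#' @param score Column of per-subject scores (e.g. `n_subthreshold`).
#' @param truth Column of class labels (logical, or compared to `positive`).
#' @param positive Label of the positive class; default `"MCI"`.
#' @return A `roc_result` object; see [tidy.roc_result()] and
#'   [glance.roc_result()].
#' @export
roc_auc <- function(data, score, truth, positive = "MCI") {
  scores <- tidy_pull(data, {{ score }})
  pos <- as_positive(tidy_pull(data, {{ truth }}), positive)
  if (anyNA(scores) || anyNA(pos)) stop_parameter("scores/labels must not contain NA")
  if (all(pos) || !any(pos)) stop_parameter("both classes must be present")
  pl <- delong_placements(scores, pos)
  v <- delong_var(pl)
  co <- cutoff_core(scores, pos)
  structure(
    list(auc = pl$auc, n_pos = sum(pos), n_neg = sum(!pos),
         direction = "higher_score_positive",
         var_auc = v,
         ci_lower = max(0, pl$auc - qnorm(0.975) * sqrt(v)),
         ci_upper = min(1, pl$auc + qnorm(0.975) * sqrt(v)),
         optimal_cutoff = co$cutoff, sensitivity = co$sens,
         specificity = co$spec, youden_j = co$j,
         scores = scores, positive = pos),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.3f [%.3f, %.3f], cutoff %g (sens %.2f, spec %.2f), %d pos / %d neg>\n",
              x$auc, x$ci_lower, x$ci_upper, x$optimal_cutoff,
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cut-off of a score
#'
#' @inheritParams roc_auc
#' @return One-row tibble with `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
optimal_cutoff <- function(data, score, truth, positive = "MCI") {
  scores <- tidy_pull(data, {{ score }})
  pos <- as_positive(tidy_pull(data, {{ truth }}), positive)
  if (all(pos) || !any(pos)) stop_parameter("both classes must be present")
  co <- cutoff_core(scores, pos)
  tibble(cutoff = co$cutoff, sensitivity = co$sens, specificity = co$spec,
         youden_j = co$j)
}

# Paired DeLong test on two score vectors over the same subjects.
delong_core <- function(scores_a, scores_b, pos) {
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  degenerate <- !is.finite(var_diff) || var_diff < 1e-15
  z <- if (degenerate) 0 else (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = if (degenerate) 1 else 2 * pnorm(-abs(z)),
       degenerate = degenerate,
       var_a = delong_var(pa), var_b = delong_var(pb))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' DeLong placement-value covariance and a two-sided normal reference.
#' When the placement difference has (numerically) zero variance — e.g.
#' identical score vectors — the comparison is flagged `degenerate` and
#' `p_value = 1` is returned (the zero-difference limit) rather than a
#' silent division by zero.
#'
#' @param data Data frame with one row per subject.
#' @param score_a,score_b Columns of the two paired scores.
#' @param truth Column of class labels.
#' @param positive Positive-class label, default `"MCI"`.
#' @return One-row tibble: `auc_a, auc_b, auc_diff, statistic, p_value,
#'   degenerate, n_pos, n_neg`.
#' @export
delong_test <- function(data, score_a, score_b, truth, positive = "MCI") {
  sa <- tidy_pull(data, {{ score_a }})
  sb <- tidy_pull(data, {{ score_b }})
  pos <- as_positive(tidy_pull(data, {{ truth }}), positive)
  if (length(sa) != length(sb)) stop_parameter("paired scores must have equal length")
  if (all(pos) || !any(pos)) stop_parameter("both classes must be present")
  dl <- delong_core(sa, sb, pos)
  tibble(auc_a = dl$auc_a, auc_b = dl$auc_b, auc_diff = dl$auc_a - dl$auc_b,
         statistic = dl$z, p_value = dl$p_value, degenerate = dl$degenerate,
         n_pos = sum(pos), n_neg = sum(!pos))
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form independent-samples t-test from group means, SDs and sizes,
#' so statistics printed in demographic tables can be recomputed directly.
#' Two-sided throughout.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (`n >= 2`, `sd >= 0`).
#' @param variant `"pooled"` (equal variances) or `"welch"`.
#' @return One-row tibble: `statistic, df, p_value, variant`.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop_parameter("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop_parameter("sd must be >= 0")
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    stop_parameter("zero variance in both groups with equal means: t undefined")
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
         variant = variant)
}

#' @rdname two_sample_t
#' @param x,y Raw samples; summaries are computed first.
#' @export
two_sample_t_samples <- function(x, y, variant = c("pooled", "welch")) {
  two_sample_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y), variant)
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when `n1 + n2 <= 12` and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#' Two-sided.
#'
#' @param x,y Samples (each `n >= 1`).
#' @return One-row tibble: `U` (Mann-Whitney statistic for `x`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble(U = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact) "exact" else "normal_approx")
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, df = 1.
#'
#' @param table 2x2 matrix of nonnegative counts with all margins > 0.
#' @return One-row tibble: `statistic, df, p_value`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    stop_parameter("need a 2x2 table of nonnegative counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_parameter("all margins of the 2x2 table must be > 0")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Bonferroni-corrected alpha
#'
#' `corrected = raw_alpha * m`, capped at 1: the family-wise alpha implied
#' by judging each of `m` comparisons at `raw_alpha`.
#'
#' @param raw_alpha Per-comparison alpha in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return Corrected alpha.
#' @export
bonferroni_alpha <- function(raw_alpha, m) {
  if (raw_alpha <= 0 || raw_alpha >= 1) stop_parameter("raw_alpha must be in (0, 1)")
  if (m < 1) stop_parameter("m must be >= 1")
  min(1, raw_alpha * m)
}
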