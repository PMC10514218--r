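# Independent oracles: exhaustive pairwise AUC, brute-force cutoff scans,
# permutation/bootstrap references, and pROC as an external cross-check.

auc_pairwise_oracle <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

score_df <- function(scores, pos) {
  tibble::tibble(score = scores, group = ifelse(pos, "MCI", "CN"))
}

test_that("AUC equals the exhaustive pairwise Mann-Whitney probability", {
  d <- score_df(c(0, 1, 2, 5, 6, 7), c(F, F, F, T, T, T))
  expect_equal(roc_auc(d, score, group)$auc, 1.0)

  tied <- score_df(rep(3, 10), rep(c(F, T), 5))
  expect_equal(roc_auc(tied, score, group)$auc, 0.5)

  set.seed(91)
  for (i in 1:100) {
    n1 <- sample(2:20, 1)
    n0 <- sample(2:20, 1)
    # mix of continuous and heavily tied integer scores
    scores <- if (i %% 2) round(rnorm(n1 + n0) * 3) else rnorm(n1 + n0)
    pos <- c(rep(TRUE, n1), rep(FALSE, n0))
    got <- roc_auc(score_df(scores, pos), score, group)$auc
    expect_equal(got, auc_pairwise_oracle(scores, pos), tolerance = 0)
  }

  expect_error(roc_auc(score_df(1:3, c(T, T, T)), score, group),
               class = "zmatch_error_parameter")
})

test_that("AUC complement and pROC agreement hold on random scores", {
  set.seed(92)
  for (i in 1:10) {
    scores <- rnorm(30)
    pos <- rep(c(TRUE, FALSE), 15)
    a1 <- roc_auc(score_df(scores, pos), score, group)$auc
    a2 <- roc_auc(score_df(-scores, pos), score, group)$auc
    expect_equal(a1 + a2, 1)
    pr <- pROC::roc(response = pos, predictor = scores, quiet = TRUE,
                    direction = "<")
    expect_equal(a1, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("Youden cutoffs use midpoints and an exhaustive scan maximum", {
  d <- score_df(c(0, 1, 2, 5, 6), c(F, F, F, T, T))
  co <- optimal_cutoff(d, score, group)
  expect_equal(co$cutoff, 3.5)
  expect_equal(co$sensitivity, 1)
  expect_equal(co$specificity, 1)

  # degenerate: identical scores, J = 0 at any cutoff
  dd <- score_df(rep(2, 8), rep(c(T, F), 4))
  expect_equal(optimal_cutoff(dd, score, group)$youden_j, 0)

  set.seed(93)
  for (i in 1:10) {
    scores <- sample(0:30, 50, replace = TRUE)
    pos <- runif(50) < 0.4
    if (all(pos) || !any(pos)) next
    co <- optimal_cutoff(score_df(scores, pos), score, group)
    # brute force over a fine grid of candidate cutoffs
    grid <- seq(min(scores) - 1, max(scores) + 1, by = 0.25)
    j_grid <- vapply(grid, function(cc) {
      mean(scores[pos] > cc) + mean(scores[!pos] <= cc) - 1
    }, numeric(1))
    expect_equal(co$youden_j, max(j_grid), tolerance = 1e-12)
  }

  # invariance of the operating point under strictly monotone transforms
  scores <- c(0, 2, 3, 7, 9, 12, 15, 20)
  pos <- c(F, F, F, F, T, T, T, T)
  a <- optimal_cutoff(score_df(scores, pos), score, group)
  b <- optimal_cutoff(score_df(scores^3, pos), score, group)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
  expect_equal(a$youden_j, b$youden_j)
})

test_that("DeLong test matches pROC and flags degenerate comparisons", {
  set.seed(94)
  n <- 40
  pos <- rep(c(TRUE, FALSE), n / 2)
  base <- rnorm(n) + pos * 1.2
  d <- tibble::tibble(a = base + rnorm(n, 0, 0.4), b = base + rnorm(n, 0, 0.8),
                      group = ifelse(pos, "MCI", "CN"))
  got <- delong_test(d, a, b, group)
  pr <- pROC::roc.test(pROC::roc(pos, d$a, quiet = TRUE, direction = "<"),
                       pROC::roc(pos, d$b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(got$p_value, pr$p.value, tolerance = 1e-9)
  expect_equal(got$statistic, unname(pr$statistic), tolerance = 1e-9)
  expect_false(got$degenerate)

  same <- delong_test(tibble::tibble(a = d$a, b = d$a, group = d$group),
                      a, b, group)
  expect_equal(same$auc_diff, 0)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
})

test_that("DeLong variance approximates Hanley-McNeil on exponential scores", {
  set.seed(95)
  m <- 50
  n <- 50
  x <- rexp(m, 0.5)   # positives, larger scale
  y <- rexp(n, 1.5)
  pos <- c(rep(TRUE, m), rep(FALSE, n))
  rr <- roc_auc(score_df(c(x, y), pos), score, group)
  A <- rr$auc
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  hm <- (A * (1 - A) + (m - 1) * (q1 - A^2) + (n - 1) * (q2 - A^2)) / (m * n)
  expect_lt(abs(rr$var_auc - hm) / hm, 0.15)
})

test_that("DeLong p-values are uniform under the null", {
  set.seed(96)
  pvals <- replicate(500, {
    pos <- rep(c(TRUE, FALSE), 15)
    signal <- as.numeric(pos)
    d <- tibble::tibble(a = signal + rnorm(30), b = signal + rnorm(30),
                        group = ifelse(pos, "MCI", "CN"))
    delong_test(d, a, b, group)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("DeLong power agrees with a subject-resampling bootstrap oracle", {
  # paired scores with true AUCs ~0.9 vs ~0.7; compare rejection rates
  gen <- function() {
    pos <- rep(c(TRUE, FALSE), 15)
    lat <- rnorm(30)
    a <- lat + pos * 2.55 + rnorm(30)  # AUC ~ 0.9 at total SD sqrt(2)
    b <- lat + pos * 1.05 + rnorm(30)  # AUC ~ 0.7
    tibble::tibble(a = a, b = b, group = ifelse(pos, "MCI", "CN"), pos = pos)
  }
  set.seed(97)
  p_delong <- mean(replicate(400, delong_test(gen(), a, b, group)$p_value < 0.05))

  boot_p <- function(d, B = 199) {
    auc_diff <- function(dd) {
      zmatch:::auc_mw(dd$a, dd$pos) - zmatch:::auc_mw(dd$b, dd$pos)
    }
    obs <- auc_diff(d)
    diffs <- replicate(B, {
      idx <- c(sample(which(d$pos), replace = TRUE),
               sample(which(!d$pos), replace = TRUE))
      auc_diff(d[idx, ])
    })
    se <- sd(diffs)
    2 * pnorm(-abs(obs / se))
  }
  set.seed(98)
  p_boot <- mean(replicate(150, boot_p(gen())) < 0.05)
  # binomial Monte-Carlo error on the two power estimates
  mc_err <- 3 * sqrt(p_delong * (1 - p_delong) / 400 +
                       p_boot * (1 - p_boot) / 150)
  expect_lt(abs(p_delong - p_boot), mc_err + 0.05)
})

test_that("summary t-tests reproduce the printed demographic comparisons", {
  eq <- two_sample_t(5, 1, 10, 5, 1, 12)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  adni <- two_sample_t(73.45, 5.75, 131, 70.84, 7.50, 91, variant = "pooled")
  expect_equal(round(adni$p_value, 3), 0.004)

  valid <- two_sample_t(68.53, 3.04, 19, 72.78, 3.91, 19, variant = "pooled")
  expect_equal(round(valid$p_value, 3), 0.001)

  # raw-sample entry point agrees with stats::t.test
  set.seed(99)
  x <- rnorm(20, 1)
  y <- rnorm(25)
  ours <- two_sample_t_samples(x, y, variant = "welch")
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  ours_p <- two_sample_t_samples(x, y, variant = "pooled")
  ref_p <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours_p$p_value, ref_p$p.value, tolerance = 1e-12)

  expect_error(two_sample_t(1, 0, 5, 1, 0, 5), class = "zmatch_error_parameter")
})

test_that("Wilcoxon rank-sum uses exact enumeration and tie-corrected normal", {
  # identical multisets with ties: approximation path, p = 1
  x <- rep(1:5, 3)
  w <- wilcoxon_rank_sum(x, x)
  expect_equal(w$p_value, 1)
  expect_identical(w$method, "normal_approx")

  ex <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_identical(ex$method, "exact")
  expect_equal(ex$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$U, 0)

  # permutation oracle at n = 50 + 50
  set.seed(100)
  x <- rnorm(50, 0.3)
  y <- rnorm(50)
  got <- wilcoxon_rank_sum(x, y)
  r <- rank(c(x, y))
  u_obs <- sum(r[1:50]) - 50 * 51 / 2
  mu <- 50 * 50 / 2
  perm <- replicate(1e5, {
    sum(r[sample.int(100, 50)]) - 50 * 51 / 2
  })
  p_perm <- mean(abs(perm - mu) >= abs(u_obs - mu))
  expect_lt(abs(got$p_value - p_perm), 0.01)
})

test_that("chi-square on 2x2 tables matches the closed form", {
  gender <- chi_square_2x2(matrix(c(14, 5, 11, 8), 2, byrow = TRUE))
  expect_equal(round(gender$p_value, 3), 0.305)
  expect_equal(gender$df, 1)

  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(101)
  for (i in 1:20) {
    tab <- matrix(sample(1:40, 4, replace = TRUE), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; dd <- tab[2, 2]
    N <- sum(tab)
    closed <- N * (a * dd - b * c)^2 /
      (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
    expect_equal(chi_square_2x2(tab)$statistic, closed, tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "zmatch_error_parameter")
})

test_that("Bonferroni alpha arithmetic", {
  expect_equal(bonferroni_alpha(0.0001, 216), 0.0216)
  expect_equal(bonferroni_alpha(0.03, 1), 0.03)
  ms <- 1:50
  vals <- vapply(ms, function(m) bonferroni_alpha(0.01, m), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(bonferroni_alpha(0.5, 10), 1)
})
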