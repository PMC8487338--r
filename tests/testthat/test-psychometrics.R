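test_that("correlation dispatches on screening and applies Bonferroni", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(correlate(x, x, "parametric")$estimate, 1)
  y <- 1:8
  expect_equal(correlate(y, -y, "nonparametric")$estimate, -1)

  # hand-computed Spearman on ranks 1..6 vs (1,2,3,4,6,5):
  # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 1 - 12/210 = 33/35
  res <- correlate(1:6, c(1, 2, 3, 4, 6, 5), "nonparametric")
  expect_equal(res$estimate, 33 / 35, tolerance = 1e-12)

  res2 <- correlate(rnorm(50), rnorm(50), "parametric", n_tests = 12)
  expect_equal(res2$adjusted_alpha, 0.05 / 12)
  expect_error(correlate(rep(1, 10), 1:10), "constant")
})

test_that("Cronbach's alpha matches the variance formula", {
  # 4 x 6 toy matrix; alpha computed from the variance decomposition with
  # independent spreadsheet arithmetic beforehand: 0.9753846154
  m <- rbind(c(3, 4, 3, 5, 4, 4),
             c(2, 2, 3, 3, 2, 3),
             c(4, 5, 4, 4, 5, 5),
             c(1, 2, 1, 2, 1, 2))
  expect_equal(cronbach_alpha(m)$value, 0.9753846154, tolerance = 1e-9)

  identical_items <- matrix(rep(c(1, 3, 5, 2), 4), ncol = 4)
  expect_equal(cronbach_alpha(identical_items)$value, 1)

  set.seed(2)
  uncorrelated <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(cronbach_alpha(uncorrelated)$value), 0.05)

  bad <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(cronbach_alpha(bad), "zero-variance item\\(s\\): b")

  # alpha is invariant under adding a constant to all entries
  expect_equal(cronbach_alpha(m)$value, cronbach_alpha(m + 7)$value)
})

test_that("ICC matches the ANOVA mean-squares oracle", {
  # 6 subjects x 2 raters; variance-components oracle computed by hand:
  # MSR = 12.35, MSC = 0.0833..., MSE = 0.4833..., ICC(A,1) = 0.9343832021
  m <- rbind(c(9, 10), c(8, 7), c(6, 6), c(4, 5), c(7, 8), c(3, 2))
  expect_equal(icc(m)$value, 0.9343832021, tolerance = 1e-9)
  expect_equal(icc(m, "ICC(C,1)")$value, 0.9246753247, tolerance = 1e-9)

  expect_equal(icc(cbind(1:8, 1:8))$value, 1)

  # absolute agreement is hurt by a rater shift; consistency is not
  shifted <- cbind(1:10, 1:10 + 5)
  expect_lt(icc(shifted)$value, icc(shifted, "ICC(C,1)")$value)
  expect_equal(icc(shifted, "ICC(C,1)")$value, 1)

  # consistency ICC is invariant under adding a constant everywhere
  expect_equal(icc(m, "ICC(C,1)")$value, icc(m + 3, "ICC(C,1)")$value)

  expect_error(icc(rbind(c(1, NA), c(2, 3))), "incomplete")
})

test_that("PCA structure identifies mono-component data", {
  set.seed(3)
  g <- rnorm(500)
  rank1 <- sapply(1:4, function(i) g + rnorm(500, 0, 0.01))
  p <- pca_structure(rank1)
  expect_gt(p$percent_variance_first, 99)
  expect_equal(p$n_retained, 1)
  expect_true(all(p$loadings > 0.99))

  indep <- matrix(rnorm(4e4), ncol = 4)
  expect_true(all(abs(pca_structure(indep)$eigenvalues - 1) < 0.1))

  # exact sample correlation 0.5 built from orthogonal contrasts:
  # eigenvalues of a 2x2 correlation matrix are 1 +/- r
  x <- c(1, 1, -1, -1)
  z <- c(1, -1, 1, -1)
  y <- 0.5 * x + sqrt(0.75) * z
  p2 <- pca_structure(cbind(x, y))
  expect_equal(p2$eigenvalues, c(1.5, 0.5), tolerance = 1e-12)
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  # 5 positives / 5 negatives (lower predictor = positive); exhaustive
  # concordant-pair count over 25 pairs gives 21.5/25 = 0.86
  pred <- c(12, 14, 9, 10, 11, 15, 16, 13, 17, 11)
  crit <- c(rep(0, 5), rep(10, 5))
  res <- roc_vs_criterion(pred, crit, centile_cut = 60)
  expect_equal(res$auc, 0.86, tolerance = 1e-12)
  expect_equal(res$n_pos, 5)
  expect_gt(res$se, 0)
  expect_true(res$ci_lower <= res$auc && res$auc <= res$ci_upper)

  # perfect separation
  res2 <- roc_vs_criterion(c(1, 2, 3, 20, 21, 22), c(0, 0, 0, 9, 9, 9),
                           centile_cut = 60)
  expect_equal(res2$auc, 1)

  # independence gives chance-level ranking
  set.seed(4)
  res3 <- roc_vs_criterion(rnorm(10000), rnorm(10000))
  expect_lt(abs(res3$auc - 0.5), 0.03)

  expect_error(roc_vs_criterion(rnorm(20), rep(5, 20)), "empty class")
})

test_that("Mann-Whitney AUC equals the trapezoidal ROC area", {
  set.seed(5)
  pred <- rnorm(300)
  crit <- pred + rnorm(300, 0, 2)  # tie-free
  res <- roc_vs_criterion(pred, crit)
  # independent route: trapezoid over all thresholds, computed here from raw
  # data without the package's curve
  n <- length(pred)
  cutv <- sort(crit)[ceiling(0.05 * n)]
  pos <- crit < cutv
  marker <- -pred
  cuts <- c(-Inf, sort(unique(marker)), Inf)
  fpr <- sapply(cuts, function(cc) mean(marker[!pos] >= cc))
  tpr <- sapply(cuts, function(cc) mean(marker[pos] >= cc))
  o <- order(fpr, tpr)
  trap <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
  expect_equal(res$auc, trap, tolerance = 1e-10)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  pred <- rnorm(200)
  crit <- pred + rnorm(200)
  res <- roc_vs_criterion(pred, crit)
  n <- length(pred)
  pos <- crit < sort(crit)[ceiling(0.05 * n)]
  ref <- pROC::auc(pROC::roc(response = pos, predictor = pred,
                             direction = ">", quiet = TRUE))
  expect_equal(res$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("paired TOST matches the textbook one-sided t statistics", {
  # 10 fixed differences, bounds +/- 0.5 SD; t statistics computed by hand:
  # t_lower = 2.9628373895, t_upper = -0.1994402707, p_tost = 0.4231757645
  d <- c(0.3, -0.2, 0.5, 0.1, -0.4, 0.2, 0.6, -0.1, 0.0, 0.4)
  res <- tost_paired(d, rep(0, 10), bounds = 0.5)
  expect_equal(res$t_lower, 2.9628373895, tolerance = 1e-9)
  expect_equal(res$t_upper, -0.1994402707, tolerance = 1e-9)
  expect_equal(res$p_tost, 0.4231757645, tolerance = 1e-9)
  expect_equal(res$t_conventional, 1.3816985594, tolerance = 1e-9)
  expect_false(res$equivalent)

  set.seed(7)
  x <- rnorm(100)
  near <- tost_paired(x, x + rnorm(100, 0, 0.01), bounds = 0.5)
  expect_true(near$equivalent)

  far <- tost_paired(x, x + 2 * sd(x), bounds = 0.5)
  expect_false(far$equivalent)

  expect_error(tost_paired(1:5, 1:5 + 2), "zero-variance")
})

test_that("regression power analysis inverts the noncentral-F correctly", {
  res <- power_regression_n(u = 3, f2 = 0.05, alpha = 0.05, power = 0.95)
  expect_equal(res$n_required, 347L)

  # the integer rule never under-powers: N meets the target, N - 1 does not
  int_res <- power_regression_n(u = 3, f2 = 0.05, rule = "integer")
  pow_at <- function(N) {
    v <- N - 3 - 1
    lam <- 0.05 * N
    1 - pf(qf(0.95, 3, v), 3, v, ncp = lam)
  }
  expect_gte(int_res$achieved_power, 0.95)
  expect_lt(pow_at(int_res$n_required - 1), 0.95)

  # larger effects need fewer participants; grid-search oracle gave 176
  res10 <- power_regression_n(u = 3, f2 = 0.10)
  expect_equal(res10$n_required, 176L)
  expect_lt(res10$n_required, res$n_required)

  # monotone in target power
  expect_lt(power_regression_n(3, 0.05, power = 0.5)$n_required,
            res$n_required)

  expect_error(power_regression_n(3, 0.05, alpha = 0.5, power = 0.3),
               "alpha < power")
})

test_that("floor and ceiling proportions use the exact endpoints", {
  all_max <- floor_ceiling(rep(20, 30), c(0, 20))
  expect_equal(all_max$fraction_at_max, 1)
  expect_true(all_max$flag)

  interior <- floor_ceiling(seq(2, 18, length.out = 50), c(0, 20))
  expect_equal(interior$fraction_at_min, 0)
  expect_equal(interior$fraction_at_max, 0)
  expect_false(interior$flag)

  # 3 of 20 at the maximum is exactly 15%: the flag is strict
  x <- c(rep(20, 3), seq_len(17))
  res <- floor_ceiling(x, c(0, 20))
  expect_equal(res$fraction_at_max, 0.15)
  expect_false(res$flag)
})
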