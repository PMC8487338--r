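#' Correlate two measures with distribution-aware method choice
#'
#' Pearson when the screening verdict is parametric, Spearman otherwise.
#' The Bonferroni family size is always caller-supplied and echoed, so the
#' adjusted alpha is auditable.
#'
#' @param x,y Paired numeric vectors (n >= 5 complete pairs).
#' @param screening `"auto"` (screen both variables with
#'   [screen_distribution()]; non-parametric if either trips the rule),
#'   `"parametric"`, `"nonparametric"`, or the output of
#'   [screen_distribution()].
#' @param n_tests Bonferroni family size (default 1).
#' @param alpha Nominal level before correction.
#' @return One-row tibble: `estimate`, `p_value`, `method`, `n`, `n_tests`,
#'   `adjusted_alpha`, `significant`.
#' @export
correlate <- function(x, y, screening = "auto", n_tests = 1, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) abort("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("degenerate input: constant vector")
  if (is.data.frame(screening)) screening <- screening$method
  method <- switch(screening,
    auto = {
      v <- c(screen_distribution(x)$method, screen_distribution(y)$method)
      if (any(v == "nonparametric")) "spearman" else "pearson"
    },
    parametric = "pearson",
    nonparametric = "spearman",
    abort("screening must be auto, parametric, nonparametric, or a screen result")
  )
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    method = method,
    n = length(x),
    n_tests = n_tests,
    adjusted_alpha = alpha / n_tests,
    significant = ct$p.value < alpha / n_tests
  )
}

#' Cronbach's alpha
#'
#' Internal consistency of a subjects-by-items score matrix:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`, with sample
#' (n-1) variances.
#'
#' @param score_matrix Numeric matrix or data frame, subjects in rows,
#'   items in columns (>= 2 of each).
#' @return One-row tibble: `statistic`, `value`, `n_subjects`, `n_items`.
#' @export
cronbach_alpha <- function(score_matrix) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need >= 2 subjects and >= 2 items")
  if (anyNA(m)) abort("missing entries are not supported (no imputation)")
  v <- apply(m, 2, var)
  zero <- which(v == 0)
  if (length(zero) > 0L) {
    abort(paste0("degenerate input: zero-variance item(s): ",
                 paste(colnames(m)[zero] %||% zero, collapse = ", ")))
  }
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(v) / var(rowSums(m)))
  tibble::tibble(statistic = "cronbach_alpha", value = alpha,
                 n_subjects = nrow(m), n_items = k)
}

#' Intraclass correlation from a two-way design
#'
#' Single-measure ICC from the mean squares of the two-way ANOVA
#' decomposition of a complete subjects-by-(raters or occasions) table.
#' The default is the two-way random-effects, absolute-agreement form
#' ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE)) — the
#' conservative choice for both test-retest and inter-rater designs; the
#' consistency form ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE) is available
#' for comparison.
#'
#' @param score_matrix Complete numeric matrix/data frame: subjects in rows,
#'   occasions or raters in columns.
#' @param model `"ICC(A,1)"` (absolute agreement, default) or `"ICC(C,1)"`
#'   (consistency).
#' @return One-row tibble: `statistic`, `value`, `icc_model`, `n_subjects`,
#'   `n_raters_or_occasions`.
#' @export
icc <- function(score_matrix, model = c("ICC(A,1)", "ICC(C,1)")) {
  model <- match.arg(model)
  m <- as.matrix(score_matrix)
  if (anyNA(m)) abort("incomplete table: every subject needs every column")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need >= 2 subjects and >= 2 columns")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_err <- sum((m - gm)^2) - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  value <- switch(model,
    "ICC(A,1)" = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
    "ICC(C,1)" = (msr - mse) / (msr + (k - 1) * mse)
  )
  tibble::tibble(statistic = "icc", value = value, icc_model = model,
                 n_subjects = n, n_raters_or_occasions = k)
}

#' Principal-component structure of the subtests
#'
#' PCA on the correlation matrix; the first component's share of variance is
#' the mono-component check, loadings are the correlations of each variable
#' with the component, and components with eigenvalue > 1 are retained
#' (Kaiser rule).
#'
#' @param subtest_matrix Numeric matrix/data frame, >= 2 non-constant
#'   columns.
#' @return Object of class `pca_structure`: `eigenvalues`,
#'   `percent_variance_first`, `loadings` (first component), `n_retained`.
#' @export
pca_structure <- function(subtest_matrix) {
  m <- as.matrix(subtest_matrix)
  if (ncol(m) < 2) abort("need >= 2 columns")
  if (anyNA(m)) abort("missing entries are not supported")
  if (any(apply(m, 2, sd) == 0)) abort("degenerate input: constant column")
  R <- cor(m)
  eig <- eigen(R, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1  # orient the component positively
  loadings <- v1 * sqrt(eig$values[1])
  names(loadings) <- colnames(m)
  structure(
    list(
      eigenvalues = eig$values,
      percent_variance_first = 100 * eig$values[1] / ncol(m),
      loadings = loadings,
      n_retained = sum(eig$values > 1),
      n = nrow(m)
    ),
    class = "pca_structure"
  )
}

#' @export
print.pca_structure <- function(x, ...) {
  cat("<pca_structure>\n")
  cat(sprintf("  first component: %.2f%% of variance; %d component(s) with eigenvalue > 1\n",
              x$percent_variance_first, x$n_retained))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.pca_structure <- function(x, ...) {
  tibble::tibble(variable = names(x$loadings), loading = unname(x$loadings))
}

#' @export
glance.pca_structure <- function(x, ...) {
  tibble::tibble(percent_variance_first = x$percent_variance_first,
                 n_retained = x$n_retained, n = x$n,
                 n_variables = length(x$eigenvalues))
}

#' @export
autoplot.pca_structure <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$eigenvalue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Component", y = "Eigenvalue", title = "Scree plot") +
    ggplot2::theme_minimal()
}

#' ROC accuracy against a criterion centile split
#'
#' The positive ("impaired") class contains participants whose criterion
#' score lies strictly below the sample `centile_cut` centile (order
#' statistic at rank `ceiling(centile_cut/100 * n)`). The AUC is computed by
#' the Mann-Whitney rank formulation with midrank tie correction; its
#' standard error follows Hanley and McNeil, and the 95% CI is the normal
#' approximation truncated to \[0, 1\]. With `direction = "lower"` (default)
#' lower predictor scores indicate the positive class, as for a cognitive
#' screen predicting impairment.
#'
#' @param predictor Numeric vector (the screen score).
#' @param criterion_scores Numeric vector, paired with `predictor`.
#' @param centile_cut Criterion centile (percent) splitting the classes.
#' @param direction `"lower"` or `"higher"`: which predictor tail indicates
#'   the positive class.
#' @return Object of class `roc_result` (one-row tibble plus the empirical
#'   curve in attribute `"curve"`): `auc`, `se`, `ci_lower`, `ci_upper`,
#'   `n_pos`, `n_neg`, `centile_cut`, `direction`.
#' @export
roc_vs_criterion <- function(predictor, criterion_scores, centile_cut = 5,
                             direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  ok <- is.finite(predictor) & is.finite(criterion_scores)
  predictor <- predictor[ok]; criterion_scores <- criterion_scores[ok]
  n <- length(predictor)
  cut_value <- sort(criterion_scores)[ceiling(centile_cut / 100 * n)]
  positive <- criterion_scores < cut_value
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    abort(paste0("empty class after the centile split: ", n_pos,
                 " positive / ", n_neg, " negative (cut value ", cut_value,
                 ")"))
  }
  marker <- if (direction == "lower") -predictor else predictor
  r <- rank(marker)  # midranks handle ties
  auc <- (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  ci <- clip_range(auc + c(-1, 1) * stats::qnorm(0.975) * se, c(0, 1))
  res <- tibble::tibble(
    auc = auc, se = se, ci_lower = ci[1], ci_upper = ci[2],
    n_pos = n_pos, n_neg = n_neg, centile_cut = centile_cut,
    direction = direction
  )
  cuts <- c(-Inf, sort(unique(marker)), Inf)
  curve <- purrr::map_dfr(cuts, function(cc) {
    tibble::tibble(fpr = mean(marker[!positive] >= cc),
                   tpr = mean(marker[positive] >= cc))
  })
  attr(res, "curve") <- curve
  class(res) <- c("roc_result", class(res))
  res
}

#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- attr(object, "curve")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.2f, 95%% CI [%.2f, %.2f])",
                                  object$auc, object$ci_lower,
                                  object$ci_upper)) +
    ggplot2::theme_minimal()
}

#' Paired equivalence testing (TOST)
#'
#' Two one-sided paired t tests against a symmetric equivalence interval.
#' Bounds are stated in standardized-difference units and mapped to the raw
#' difference scale through the sample SD of the paired differences
#' (`bounds_scale = "sd"`, the default), or supplied directly on the raw
#' scale (`bounds_scale = "raw"`). Equivalence is declared when the larger of
#' the two one-sided p values is below `alpha`. The conventional paired t
#' statistic and two-sided p are reported alongside, since both are part of
#' the standard reporting shape.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param bounds Half-width of the symmetric equivalence interval.
#' @param bounds_scale `"sd"` (standardized-difference units) or `"raw"`.
#' @param alpha Level of each one-sided test.
#' @return One-row tibble of class `tost_result`: `t_conventional`, `df`,
#'   `p_nhst`, `t_lower`, `t_upper`, `p_tost`, `bound_lower`, `bound_upper`,
#'   `bounds_scale`, `equivalent`, `mean_diff`, `sd_diff`, `n`.
#' @export
tost_paired <- function(x, y, bounds = 0.5,
                        bounds_scale = c("sd", "raw"), alpha = 0.05) {
  bounds_scale <- match.arg(bounds_scale)
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 3) abort("need at least 3 complete pairs")
  s <- sd(d)
  if (s == 0) abort("degenerate input: zero-variance differences")
  if (length(bounds) != 1L || bounds <= 0) {
    abort("`bounds` is the positive half-width of a symmetric interval")
  }
  half <- if (bounds_scale == "sd") bounds * s else bounds
  m <- mean(d); se <- s / sqrt(n); df <- n - 1
  t_lower <- (m + half) / se   # H0: diff <= -half
  t_upper <- (m - half) / se   # H0: diff >= +half
  p_lower <- pt(t_lower, df, lower.tail = FALSE)
  p_upper <- pt(t_upper, df)
  t_conv <- m / se
  res <- tibble::tibble(
    t_conventional = t_conv, df = df,
    p_nhst = 2 * pt(abs(t_conv), df, lower.tail = FALSE),
    t_lower = t_lower, t_upper = t_upper,
    p_tost = max(p_lower, p_upper),
    bound_lower = -half, bound_upper = half, bounds_scale = bounds_scale,
    equivalent = max(p_lower, p_upper) < alpha,
    mean_diff = m, sd_diff = s, n = n
  )
  class(res) <- c("tost_result", class(res))
  res
}

#' A-priori sample size for multiple regression
#'
#' Inverts the noncentral-F power function of the overall regression test
#' with numerator df `u`, denominator df `v`, noncentrality
#' `lambda = f2 * (u + v + 1)`, and total N = u + v + 1. The default
#' `"continuous"` rule solves the power equation in continuous `v` and
#' reports the rounded N — the convention of standard a-priori power tools
#' for regression. `rule = "integer"` instead returns the smallest integer N
#' whose achieved power is at or above the target (never below it).
#'
#' @param u Numerator degrees of freedom (number of tested predictors).
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param alpha Test level.
#' @param power Target power (alpha < power < 1).
#' @param rule `"continuous"` (default) or `"integer"`.
#' @return One-row tibble: `n_required`, `v`, `achieved_power`, `u`, `f2`,
#'   `alpha`, `power_target`, `rule`.
#' @export
#' @examples
#' power_regression_n(u = 3, f2 = 0.05, alpha = 0.05, power = 0.95)
power_regression_n <- function(u, f2, alpha = 0.05, power = 0.95,
                               rule = c("continuous", "integer")) {
  rule <- match.arg(rule)
  if (u < 1) abort("`u` must be >= 1")
  if (f2 <= 0) abort("`f2` must be > 0")
  if (!(alpha > 0 && alpha < power && power < 1)) {
    abort("need 0 < alpha < power < 1")
  }
  pow_at <- function(v) {
    lambda <- f2 * (u + v + 1)
    1 - pf(qf(1 - alpha, u, v), u, v, ncp = lambda)
  }
  if (rule == "continuous") {
    v_star <- uniroot(function(v) pow_at(v) - power,
                      lower = 1 + 1e-9, upper = 1e7, tol = 1e-9)$root
    n_req <- round(u + v_star + 1)
    v_out <- v_star
  } else {
    v <- 1
    while (pow_at(v) < power) {
      v <- v + 1
      if (v > 1e7) abort("no attainable N below the search cap")
    }
    n_req <- u + v + 1
    v_out <- v
  }
  tibble::tibble(
    n_required = as.integer(n_req), v = v_out,
    achieved_power = pow_at(n_req - u - 1),
    u = u, f2 = f2, alpha = alpha, power_target = power, rule = rule
  )
}

#' Floor and ceiling effects
#'
#' Proportions of scores at the exact endpoints of the declared range; the
#' flag trips when either proportion strictly exceeds 15% (a common
#' acceptability convention).
#'
#' @param scores Numeric vector within `score_range`.
#' @param score_range Closed interval `c(min, max)`.
#' @param threshold Flagging threshold (default 0.15, strict `>`).
#' @return One-row tibble: `fraction_at_min`, `fraction_at_max`, `flag`, `n`.
#' @export
floor_ceiling <- function(scores, score_range, threshold = 0.15) {
  scores <- scores[is.finite(scores)]
  if (any(scores < score_range[1] | scores > score_range[2])) {
    abort("scores outside the declared range")
  }
  fmin <- mean(scores == score_range[1])
  fmax <- mean(scores == score_range[2])
  tibble::tibble(fraction_at_min = fmin, fraction_at_max = fmax,
                 flag = fmin > threshold || fmax > threshold,
                 n = length(scores))
}
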