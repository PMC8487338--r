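#' Screen a score distribution for normality
#'
#' The screening rule used throughout the pipeline: a distribution is treated
#' as non-parametric when |skewness| >= 1 or |excess kurtosis| >= 3
#' (population-moment estimators; excess kurtosis so a normal scores 0).
#' Both thresholds are strict `>=`.
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @return One-row tibble with `method` ("parametric" or "nonparametric"),
#'   `skewness`, `excess_kurtosis`, `n`.
#' @export
#' @examples
#' screen_distribution(rnorm(500))
screen_distribution <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) abort("need at least 8 finite observations to screen")
  m2 <- mean((values - mean(values))^2)
  if (m2 == 0) abort("degenerate input: zero variance")
  m3 <- mean((values - mean(values))^3)
  m4 <- mean((values - mean(values))^4)
  skew <- m3 / m2^1.5
  exkurt <- m4 / m2^2 - 3
  tibble::tibble(
    method = if (abs(skew) >= 1 || abs(exkurt) >= 3) "nonparametric"
             else "parametric",
    skewness = skew, excess_kurtosis = exkurt, n = n
  )
}

new_norm_equation <- function(measure, terms, source = "fitted",
                              fit = NULL, no_predictors = FALSE,
                              guard = FALSE) {
  stopifnot(all(c("covariate", "transform", "coefficient", "center")
                %in% names(terms)))
  structure(
    list(measure = measure, terms = terms, source = source, fit = fit,
         no_predictors = no_predictors, guard = guard),
    class = "norm_equation"
  )
}

#' @export
print.norm_equation <- function(x, ...) {
  cat("<norm_equation> ", x$measure, " (", x$source, ")\n", sep = "")
  if (nrow(x$terms) == 0L) {
    cat("  AS = RS (no significant demographic predictors)\n")
  } else {
    rhs <- paste(
      sprintf("%+.6f*[%s - %.6f]", x$terms$coefficient,
              vapply(seq_len(nrow(x$terms)), function(i) {
                gsub("x", x$terms$covariate[i],
                     transform_label(x$terms$transform[i]), fixed = TRUE)
              }, character(1)),
              x$terms$center),
      collapse = " "
    )
    cat("  AS = RS ", rhs, "\n", sep = "")
  }
  invisible(x)
}

#' Fit a demographic adjustment equation
#'
#' Implements the regression stage of the Equivalent Score method. For each
#' covariate (age, education) the candidate transform minimizing the residual
#' sum of squares in a single-covariate regression is selected; the selected
#' transforms plus a male/female indicator then enter a joint multiple linear
#' regression of the raw score. A covariate is retained when its joint-model
#' p-value is below `alpha` divided by the number of candidate transforms
#' screened for it (a selection-aware Bonferroni guard; sex, which is not
#' selected over candidates, is tested at `alpha`). Retained coefficients are
#' negated into the adjustment direction, so that
#' `AS = RS + sum(coefficient * (T(x) - center))` with `center` the sample
#' mean of the transformed covariate.
#'
#' `ln(x)` / `sqrt(x)` candidates are evaluated with the guards
#' `ln(max(x, 1))` / `sqrt(max(x, 0))` so cohorts containing education = 0
#' remain fittable; rows with education = 0 are counted in the fit report.
#'
#' @param cohort Cohort tibble with `age`, `education_years`, `sex`, and the
#'   raw measure column.
#' @param measure Measure column to norm.
#' @param candidate_transforms Named list of candidate transform ids per
#'   covariate; see [phv_candidate_transforms()].
#' @param alpha Significance level before the selection correction.
#' @return A `norm_equation`; its `fit` element carries the transform screen,
#'   dropped predictors, R^2, residual sigma, and the condition number of the
#'   candidate design.
#' @export
fit_norm_equation <- function(cohort, measure,
                              candidate_transforms = phv_candidate_transforms(),
                              alpha = 0.05) {
  need <- c("age", "education_years", "sex", measure)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L) {
    abort(paste0("cohort lacks columns: ", paste(miss, collapse = ", ")))
  }
  y <- cohort[[measure]]
  n <- length(y)
  n_cand <- sum(lengths(candidate_transforms))
  if (n <= n_cand + 10) abort("too few observations to fit candidates")

  cov_values <- list(age = cohort$age, education = cohort$education_years)

  # single-covariate screen: min RSS per covariate
  screen <- purrr::map_dfr(names(candidate_transforms), function(cv) {
    purrr::map_dfr(candidate_transforms[[cv]], function(tid) {
      tx <- transform_fn(tid, guard = TRUE)(cov_values[[cv]])
      rss <- sum(stats::resid(lm(y ~ tx))^2)
      tibble::tibble(covariate = cv, transform = tid, rss = rss)
    })
  })
  selected <- screen |>
    dplyr::group_by(.data$covariate) |>
    dplyr::slice_min(.data$rss, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  X <- purrr::map(seq_len(nrow(selected)), function(i) {
    transform_fn(selected$transform[i], guard = TRUE)(
      cov_values[[selected$covariate[i]]]
    )
  })
  names(X) <- selected$covariate
  df <- tibble::as_tibble(X)
  df$sex_male <- as.numeric(cohort$sex == "M")
  df$.y <- y

  fit <- lm(.y ~ ., data = df)
  smry <- summary(fit)
  pvals <- smry$coefficients[-1, "Pr(>|t|)"]
  thresholds <- c(
    setNames(alpha / lengths(candidate_transforms)[selected$covariate],
             selected$covariate),
    sex_male = alpha
  )
  keep <- names(pvals)[pvals < thresholds[names(pvals)]]
  dropped <- tibble::tibble(
    predictor = names(pvals), p_value = unname(pvals),
    threshold = unname(thresholds[names(pvals)]),
    retained = names(pvals) %in% keep
  )
  cond_number <- kappa(scale(as.matrix(df[setdiff(names(df), ".y")])),
                       exact = TRUE)

  keep_cov <- intersect(keep, selected$covariate)
  if (length(keep) == 0L || (length(keep_cov) == 0L && !"sex_male" %in% keep)) {
    warn(paste0("no significant demographic predictors for '", measure,
                "'; equation reduces to AS = RS"))
    eq_terms <- tibble::tibble(covariate = character(),
                               transform = character(),
                               coefficient = numeric(), center = numeric())
    refit <- NULL
  } else {
    retained <- keep
    refit <- lm(.y ~ ., data = df[c(retained, ".y")])
    b <- coef(refit)[-1]
    eq_terms <- purrr::map_dfr(retained, function(pr) {
      if (pr == "sex_male") {
        tibble::tibble(covariate = "sex_male", transform = "identity",
                       coefficient = round(-unname(b[pr]), 6),
                       center = round(mean(df$sex_male), 6))
      } else {
        tid <- selected$transform[selected$covariate == pr]
        tibble::tibble(covariate = pr, transform = tid,
                       coefficient = round(-unname(b[pr]), 6),
                       center = round(mean(df[[pr]]), 6))
      }
    })
  }

  report <- list(
    n = n, alpha = alpha,
    screen = screen, selected = selected, predictors = dropped,
    r_squared = smry$r.squared, sigma = smry$sigma,
    condition_number = cond_number,
    n_education_zero = sum(cohort$education_years == 0),
    kurtosis_convention = "excess (normal = 0)"
  )
  new_norm_equation(measure, eq_terms, source = "fitted", fit = report,
                    no_predictors = nrow(eq_terms) == 0L, guard = TRUE)
}

#' Apply an adjustment equation
#'
#' Computes `AS = RS + sum(coefficient * (T(x) - center))` exactly as the
#' equation prescribes. Adjusted scores are real-valued and not clipped to the
#' raw-score range (the ES bands operate on the unbounded adjusted scale).
#' Covariates must lie in the validity domain: 18 <= age <= 99, and
#' education >= 1 when the equation carries a `ln(education)` term
#' (education = 0 raises an explicit domain error, as does age >= 100 with a
#' `ln(100 - age)` term). Fitted equations, which were estimated with the
#' `ln(max(x, 1))` / `sqrt(max(x, 0))` guards, apply with the same guards
#' instead of erroring; published equations are applied exactly as printed.
#'
#' @param equation A `norm_equation` (fitted or from [published_norms()]).
#' @param raw_score,age,education Vectors of equal length (or length 1,
#'   recycled).
#' @param sex Optional "M"/"F" vector; only used when a fitted equation
#'   retained a sex term.
#' @return Numeric vector of adjusted scores.
#' @export
#' @examples
#' eq <- published_norms()[["total"]]
#' apply_norm_equation(eq, raw_score = 17, age = 60, education = 8)
apply_norm_equation <- function(equation, raw_score, age, education,
                                sex = NULL) {
  stopifnot(inherits(equation, "norm_equation"))
  k <- max(length(raw_score), length(age), length(education))
  raw_score <- rep_len(raw_score, k)
  age <- rep_len(age, k)
  education <- rep_len(education, k)
  if (any(age < 18 | age > 99)) {
    abort("age outside the validity domain [18, 99]")
  }
  as_ <- as.numeric(raw_score)
  for (i in seq_len(nrow(equation$terms))) {
    trm <- equation$terms[i, ]
    x <- switch(trm$covariate,
                age = age,
                education = education,
                sex_male = {
                  if (is.null(sex)) abort("equation has a sex term; supply `sex`")
                  as.numeric(sex == "M")
                },
                abort(paste0("unknown covariate '", trm$covariate, "'")))
    if (!isTRUE(equation$guard)) {
      bad <- transform_domain_violations(trm$transform, x)
      if (length(bad) > 0L) {
        abort(paste0(
          "covariate '", trm$covariate, "' outside the domain of ",
          transform_label(trm$transform), " (e.g. education = 0 with a ",
          "ln(education) term) at position(s): ",
          paste(head(bad, 5), collapse = ", ")
        ))
      }
    }
    as_ <- as_ + trm$coefficient *
      (transform_fn(trm$transform, guard = isTRUE(equation$guard))(x) -
         trm$center)
  }
  as_
}

#' Adjust all screen measures of a cohort
#'
#' Data-frame-first wrapper: applies one equation per measure and appends
#' `<measure>_as` columns.
#'
#' @param data Tibble with `age`, `education_years`, and raw measure columns.
#' @param norms Named list of `norm_equation`s (default the published ones).
#' @return `data` with adjusted-score columns appended.
#' @export
adjust_scores <- function(data, norms = published_norms()) {
  for (m in names(norms)) {
    if (!m %in% names(data)) next
    data[[paste0(m, "_as")]] <- apply_norm_equation(
      norms[[m]], data[[m]], data$age, data$education_years,
      sex = data$sex
    )
  }
  data
}

#' Published adjustment equations
#'
#' The six demographic adjustment equations from the published Italian
#' normative study of the ALS-CBS phone version, transcribed at full printed
#' precision. Coefficients follow the adjustment sign convention
#' `AS = RS + coefficient * (T(x) - center)`; the centering constants are the
#' standardization sample's mean transformed covariates, so an examinee at
#' the sample-mean demographics has `AS = RS` exactly.
#'
#' @return Named list of six `norm_equation` objects (total, attention,
#'   concentration_wm, concentration_total, tracking_monitoring,
#'   initiation_retrieval).
#' @export
#' @examples
#' published_norms()[["total"]]
published_norms <- function() {
  fx <- read_norms_fixture()
  purrr::map(fx$equations, function(eq) {
    new_norm_equation(
      measure = eq$measure,
      terms = tibble::as_tibble(eq$terms),
      source = paste0("published (", fx$version, ")")
    )
  }) |> setNames(purrr::map_chr(fx$equations, "measure"))
}

read_norms_fixture <- function() {
  path <- system.file("extdata", "alscbs_phv_norms.json",
                      package = "phonenorms")
  if (path == "") abort("published norms fixture not found")
  jsonlite::fromJSON(path, simplifyVector = FALSE) |>
    normalize_norms_list()
}

normalize_norms_list <- function(fx) {
  fx$equations <- purrr::map(fx$equations, function(eq) {
    eq$terms <- purrr::map_dfr(eq$terms, tibble::as_tibble)
    eq
  })
  fx$bands <- purrr::map(fx$bands, function(bd) {
    bd$es_upper <- as.numeric(unlist(bd$es_upper))
    bd
  })
  fx
}

#' @export
tidy.norm_equation <- function(x, ...) {
  dplyr::mutate(x$terms, measure = x$measure, source = x$source,
                .before = 1)
}

#' @export
glance.norm_equation <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    n_terms = nrow(x$terms),
    source = x$source,
    r_squared = x$fit$r_squared %||% NA_real_,
    sigma = x$fit$sigma %||% NA_real_,
    n = x$fit$n %||% NA_integer_,
    condition_number = x$fit$condition_number %||% NA_real_,
    no_predictors = x$no_predictors
  )
}

#' Plot the demographic adjustment surface of an equation
#'
#' Shows the adjustment added to the raw score (`AS - RS`) across age, one
#' line per education level.
#'
#' @param object A `norm_equation`.
#' @param ages,educations Grids to evaluate.
#' @param ... Unused.
#' @export
autoplot.norm_equation <- function(object, ages = 18:90,
                                   educations = c(5, 8, 13, 17, 21), ...) {
  grid <- tidyr::expand_grid(age = ages, education = educations)
  grid$adjustment <- apply_norm_equation(object, 0, grid$age, grid$education)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$age, y = .data$adjustment,
                                     colour = factor(.data$education))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Adjustment (AS - RS)",
                  colour = "Education (years)",
                  title = paste("Adjustment surface:", object$measure)) +
    ggplot2::theme_minimal()
}
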