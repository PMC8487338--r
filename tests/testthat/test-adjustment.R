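test_that("distribution screening applies the strict moment thresholds", {
  set.seed(1)
  norm_sample <- rnorm(10000)
  expect_equal(screen_distribution(norm_sample)$method, "parametric")

  # exponential(1): population skewness 2, excess kurtosis 6
  expo <- rexp(10000)
  scr <- screen_distribution(expo)
  expect_equal(scr$method, "nonparametric")
  expect_gt(scr$skewness, 1.5)

  # classification must match the rule applied to independently computed
  # moments, with strict >= at both thresholds
  for (seed in 1:8) {
    set.seed(seed)
    x <- rnorm(400)^sample(1:3, 1)
    m <- mean(x)
    sk <- mean((x - m)^3) / mean((x - m)^2)^1.5
    ku <- mean((x - m)^4) / mean((x - m)^2)^2 - 3
    want <- if (abs(sk) >= 1 || abs(ku) >= 3) "nonparametric" else "parametric"
    expect_equal(screen_distribution(x)$method, want)
  }

  expect_error(screen_distribution(rep(1, 20)), "zero variance")
  expect_error(screen_distribution(rnorm(5)), "at least 8")
})

test_that("published equations are transcribed and centered exactly", {
  norms <- published_norms()
  expect_length(norms, 6)
  expect_setequal(names(norms), phv_measures()$measure)

  tot <- norms[["total"]]
  expect_equal(tot$terms$coefficient[tot$terms$covariate == "age"],
               -2.036709)
  expect_equal(tot$terms$coefficient[tot$terms$covariate == "education"],
               -2.700291)

  # centering identity: evaluating each equation at the covariate values
  # whose transforms equal the printed centers returns AS = RS exactly
  for (eq in norms) {
    age_term <- eq$terms[eq$terms$covariate == "age", ]
    edu_term <- eq$terms[eq$terms$covariate == "education", ]
    age0 <- phonenorms:::transform_inverse(age_term$transform,
                                           age_term$center)
    edu0 <- phonenorms:::transform_inverse(edu_term$transform,
                                           edu_term$center)
    for (rs in c(0, 7, 17)) {
      expect_equal(apply_norm_equation(eq, rs, age0, edu0), rs,
                   tolerance = 1e-12)
    }
  }
})

test_that("the published total equation matches independent arithmetic", {
  # AS = 10 - 2.036709 (ln 20 - 3.791907) - 2.700291 (ln 5 - 2.497723),
  # evaluated with high-precision arithmetic beforehand
  eq <- published_norms()[["total"]]
  expect_equal(apply_norm_equation(eq, 10, 80, 5), 14.0202044583,
               tolerance = 1e-9)
  # purity: repeated application is identical
  expect_identical(apply_norm_equation(eq, 3, 55, 13),
                   apply_norm_equation(eq, 3, 55, 13))
})

test_that("adjustment respects covariate validity domains", {
  eq <- published_norms()[["total"]]
  expect_error(apply_norm_equation(eq, 10, 55, 0), "education = 0")
  expect_error(apply_norm_equation(eq, 10, 100, 10), "validity domain")
  expect_error(apply_norm_equation(eq, 10, 17, 10), "validity domain")
})

test_that("the published total adjustment compensates expected decline", {
  # the correction added to the raw score grows with age and shrinks with
  # education, per the printed coefficient signs
  eq <- published_norms()[["total"]]
  by_age <- apply_norm_equation(eq, 10, seq(20, 95, by = 5), 13)
  expect_true(all(diff(by_age) > 0))
  by_edu <- apply_norm_equation(eq, 10, 55, 1:26)
  expect_true(all(diff(by_edu) < 0))
})

test_that("fitting recovers the generating transforms and coefficients", {
  spec <- mid_spec(n = 2000, seed = 42)
  co <- simulate_cohort(spec)
  eq <- fit_norm_equation(co, "total")

  expect_setequal(eq$terms$covariate, c("age", "education"))
  expect_equal(eq$terms$transform[eq$terms$covariate == "age"],
               "ln_100_minus_x")
  expect_equal(eq$terms$transform[eq$terms$covariate == "education"],
               "ln_x")

  truth <- true_total_coefficients(spec)
  got <- setNames(eq$terms$coefficient, eq$terms$covariate)
  expect_lt(abs(got[["age"]] - truth[["age"]]) / abs(truth[["age"]]), 0.15)
  expect_lt(abs(got[["education"]] - truth[["education"]]) /
              abs(truth[["education"]]), 0.15)

  # centering identity for the fitted equation
  age0 <- phonenorms:::transform_inverse("ln_100_minus_x",
                                         eq$terms$center[eq$terms$covariate == "age"])
  edu0 <- phonenorms:::transform_inverse("ln_x",
                                         eq$terms$center[eq$terms$covariate == "education"])
  expect_equal(apply_norm_equation(eq, 12, age0, edu0), 12,
               tolerance = 1e-5)
})

test_that("a null generative model yields the identity equation", {
  mm <- phv_measure_model()
  mm$noise_sd <- mm$noise_sd * 3
  spec <- cohort_spec(n = 400, beta_age = 0, beta_edu = 0, beta0 = 0,
                      latent_sd = 1, measure_model = mm, seed = 77)
  co <- simulate_cohort(spec)
  expect_warning(eq <- fit_norm_equation(co, "total"), "no significant")
  expect_equal(nrow(eq$terms), 0)
  expect_true(eq$no_predictors)
  # AS = RS when there is nothing to adjust
  expect_equal(apply_norm_equation(eq, c(5, 12), c(30, 70), c(8, 18)),
               c(5, 12))
})

test_that("adjustment removes the modelled demographic effects", {
  spec <- mid_spec(n = 2000, seed = 42)
  co <- simulate_cohort(spec)
  eq <- fit_norm_equation(co, "total")
  co$total_as <- apply_norm_equation(eq, co$total, co$age,
                                     co$education_years)
  co2 <- co
  co2$total <- co2$total_as
  refit <- suppressWarnings(fit_norm_equation(co2, "total"))
  expect_equal(nrow(refit$terms), 0)
})
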