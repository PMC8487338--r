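test_that("degenerate distributions and seeding behave deterministically", {
  spec <- cohort_spec(n = 40, age_mean = 50, age_sd = 0, seed = 3)
  demo <- sample_demographics(spec)
  expect_true(all(demo$age == 50))

  spec2 <- cohort_spec(n = 120, seed = 99)
  a <- simulate_cohort(spec2, repeats = TRUE)
  b <- simulate_cohort(spec2, repeats = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))

  expect_error(cohort_spec(n = 0, seed = 1), "positive integer")
  expect_error(cohort_spec(age_range = c(60, 40), seed = 1), "interval")
  expect_error(cohort_spec(retest_reliability = 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("replicate cohorts reproduce the target age structure", {
  # the generator samples a truncated normal; its analytic mean is the
  # oracle, and it must sit close to the nominal mean of 52.7
  mu <- 52.7; sigma <- 15.75; lo <- 18; hi <- 89
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  trunc_mean <- mu + sigma * (dnorm(a) - dnorm(b)) / z
  expect_lt(abs(trunc_mean - 52.7), 0.2)

  ages <- unlist(lapply(1:200, function(i) {
    sample_demographics(cohort_spec(n = 359, seed = 1000 + i))$age
  }))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - trunc_mean), 3 * se)
  expect_true(all(ages >= 18 & ages <= 89))
})

test_that("zero noise and zero effects collapse scores to a constant map", {
  mm <- phv_measure_model()
  mm$noise_sd <- 0
  spec <- cohort_spec(n = 30, beta_age = 0, beta_edu = 0, beta0 = -6,
                      latent_sd = 0, measure_model = mm, seed = 5)
  co <- generate_scores(sample_demographics(spec), spec)
  for (m in c("attention", "concentration_total", "total")) {
    expect_length(unique(co[[m]]), 1)
  }
  row <- mm[mm$measure == "attention", ]
  expect_equal(unique(co$attention),
               as.integer(round(row$intercept + row$slope * -6)))

  # identical demographics -> identical scores under zero noise
  spec2 <- cohort_spec(n = 10, age_sd = 0, edu_sd = 0, latent_sd = 0,
                       measure_model = mm, seed = 6)
  co2 <- generate_scores(sample_demographics(spec2), spec2)
  expect_length(unique(co2$total), 1)
})

test_that("the built-in age effect orders age strata", {
  spec <- cohort_spec(n = 5000, seed = 21)
  co <- simulate_cohort(spec)
  young <- co$total[co$age <= 45]
  old <- co$total[co$age >= 66]
  expect_gt(mean(young), mean(old))
})

test_that("generated scores respect declared ranges", {
  for (seed in c(2, 17)) {
    co <- simulate_cohort(cohort_spec(n = 300, seed = seed), repeats = TRUE)
    reg <- phv_measures()
    for (i in seq_len(nrow(reg))) {
      m <- reg$measure[i]
      for (col in paste0(m, c("", "_retest", "_rater2", "_inperson"))) {
        expect_true(all(co[[col]] >= reg$min[i] & co[[col]] <= reg$max[i]),
                    label = paste(col, "within range"))
      }
    }
  }
})

test_that("retest construction hits the target latent correlation", {
  spec <- cohort_spec(n = 2000, retest_reliability = 0.7, seed = 8)
  co <- generate_repeats(simulate_cohort(spec), spec)
  lat <- attr(co, "latent")
  lat_re <- attr(co, "latent_retest")
  r <- cor(lat$total, lat_re$total)
  expect_lt(abs(r - 0.7), 0.05)
})

test_that("perfect reliability and null shifts reproduce the originals", {
  mm <- phv_measure_model()
  mm$noise_sd <- 0
  spec <- cohort_spec(n = 100, retest_reliability = 1, rater_sd = 0,
                      format_shift = 0, inperson_sd = 0,
                      measure_model = mm, seed = 12)
  co <- generate_repeats(generate_scores(sample_demographics(spec), spec),
                         spec)
  for (m in phv_measures()$measure) {
    expect_equal(co[[paste0(m, "_retest")]], co[[m]])
    expect_equal(co[[paste0(m, "_rater2")]], co[[m]])
    expect_equal(co[[paste0(m, "_inperson")]], co[[m]])
  }
})

test_that("a null format shift leaves paired phone/in-person means equal", {
  # mid-range intercepts keep scores off the bounds, so clipping cannot
  # bias the comparison of the two formats
  spec <- mid_spec(n = 2000, format_shift = 0, seed = 13)
  co <- generate_repeats(simulate_cohort(spec), spec)
  d <- co$total - co$total_inperson
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("item responses follow the 2PL generative model", {
  spec <- cohort_spec(n = 5000, seed = 31)
  co <- simulate_cohort(spec)

  flat <- tibble::tibble(item = "flat", a = 0, b = 0)
  rf <- generate_item_responses(co, flat, seed = 1)
  p <- mean(rf$item_flat)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(co)))

  # marginal pass rate of a = 2, b = 1 over theta ~ N(0,1): the analytic
  # integral (computed by numerical quadrature beforehand) is 0.2247998
  bank <- tibble::tibble(item = "hard", a = 2, b = 1)
  rh <- generate_item_responses(co, bank, seed = 2)
  expected <- 0.2247998
  se <- sqrt(expected * (1 - expected) / nrow(co))
  expect_lt(abs(mean(rh$item_hard) - expected), 3 * se)

  expect_error(
    generate_item_responses(co, tibble::tibble(item = "x", a = -1, b = 0)),
    ">= 0"
  )
})

test_that("degenerate cohorts make variance-based statistics error out", {
  mm <- phv_measure_model()
  mm$noise_sd <- 0
  spec <- cohort_spec(n = 50, age_sd = 0, edu_sd = 0, beta_age = 0,
                      beta_edu = 0, latent_sd = 0,
                      measure_model = mm, seed = 4)
  co <- generate_scores(sample_demographics(spec), spec)
  expect_error(screen_distribution(co$total), "zero variance")
  expect_error(correlate(co$total, co$age), "constant")
  expect_error(cronbach_alpha(co[c("attention", "concentration_wm")]),
               "zero-variance")
  expect_error(pca_structure(co[c("attention", "tracking_monitoring")]),
               "constant")
})
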