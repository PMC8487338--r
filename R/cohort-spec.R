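#' Specification of a synthetic normative cohort
#'
#' Defines the generative model for a synthetic standardization sample:
#' truncated-normal demographics, a latent cognitive-efficiency factor driven
#' by `ln(100 - age)` and `ln(education)` (the functional forms typical of
#' adjustment equations for this screen family), bounded integer measure
#' scores loading on that factor, and optional repeats (30-day retest, second
#' rater, in-person format) and binary item responses.
#'
#' The defaults emulate the published Italian standardization sample of the
#' ALS-CBS phone version: n = 359, age 52.7 +/- 15.75 on [18, 89], education
#' 13.06 +/- 4.44 on [0, 26], 143/359 male, subtest means near the ceiling and
#' a total score of roughly 16.9 +/- 2.7. Residual noise and effect sizes are
#' not published; the defaults are chosen so the generated score spread and
#' age/education correlations match the reported marginals (see the methods
#' vignette). Sex has no effect on scores, matching the reported absence of
#' sex differences.
#'
#' @param n Number of participants (>= 1).
#' @param age_mean,age_sd Age distribution in years before truncation.
#' @param age_range Closed interval for age, within \[18, 100\].
#' @param edu_mean,edu_sd Education distribution in years before truncation.
#' @param edu_range Closed interval for education, within \[0, 30\].
#' @param male_fraction Proportion of males in \[0, 1\].
#' @param beta0,beta_age,beta_edu Latent-ability regression coefficients on
#'   the intercept, `ln(100 - age)`, and `ln(max(education, 1))`.
#' @param latent_sd Residual SD of the latent factor.
#' @param measure_model Tibble mapping each measure (except the total, which
#'   is the sum of the four subtests) to `intercept`, `slope` (score units per
#'   latent unit), and `noise_sd`; see [phv_measure_model()].
#' @param retest_reliability Target test-retest correlation in \[0, 1\]
#'   (on the latent, pre-discretization scale).
#' @param rater_sd SD of second-rater scoring noise (score units).
#' @param format_shift Mean phone-minus-in-person difference (score units).
#' @param inperson_sd Residual SD of the in-person administration around the
#'   shifted latent score.
#' @param seed Integer seed; mandatory so every cohort is reproducible.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [sample_demographics()], [generate_scores()],
#'   [generate_repeats()], [generate_item_responses()], [simulate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec
cohort_spec <- function(n = 359,
                        age_mean = 52.7, age_sd = 15.75, age_range = c(18, 89),
                        edu_mean = 13.06, edu_sd = 4.44, edu_range = c(0, 26),
                        male_fraction = 143 / 359,
                        beta0 = -8.18, beta_age = 1.2, beta_edu = 1.4,
                        latent_sd = 0.8,
                        measure_model = phv_measure_model(),
                        retest_reliability = 0.7,
                        rater_sd = 0.3,
                        format_shift = 0.1,
                        inperson_sd = 1,
                        seed) {
  if (missing(seed)) abort("cohort_spec() requires an explicit integer `seed`")
  spec <- structure(
    list(
      n = n, age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      edu_mean = edu_mean, edu_sd = edu_sd, edu_range = edu_range,
      male_fraction = male_fraction,
      beta0 = beta0, beta_age = beta_age, beta_edu = beta_edu,
      latent_sd = latent_sd, measure_model = measure_model,
      retest_reliability = retest_reliability, rater_sd = rater_sd,
      format_shift = format_shift, inperson_sd = inperson_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with(spec, {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
      abort("`n` must be a positive integer")
    }
    if (length(age_range) != 2L || age_range[1] > age_range[2]) {
      abort("`age_range` must be a non-empty closed interval")
    }
    if (age_range[1] < 18 || age_range[2] > 100) {
      abort("`age_range` must lie within [18, 100]")
    }
    if (length(edu_range) != 2L || edu_range[1] > edu_range[2]) {
      abort("`edu_range` must be a non-empty closed interval")
    }
    if (edu_range[1] < 0 || edu_range[2] > 30) {
      abort("`edu_range` must lie within [0, 30]")
    }
    for (nm in c("age_sd", "edu_sd", "latent_sd", "rater_sd", "inperson_sd")) {
      if (spec[[nm]] < 0) abort(paste0("`", nm, "` must be >= 0"))
    }
    if (male_fraction < 0 || male_fraction > 1) {
      abort("`male_fraction` must be in [0, 1]")
    }
    if (retest_reliability < 0 || retest_reliability > 1) {
      abort("`retest_reliability` must be in [0, 1]")
    }
    if (is.na(seed)) abort("`seed` must be a finite integer")
  })
  mm <- spec$measure_model
  if (!all(c("measure", "intercept", "slope", "noise_sd") %in% names(mm))) {
    abort("`measure_model` needs columns measure, intercept, slope, noise_sd")
  }
  if (any(mm$noise_sd < 0)) abort("measure `noise_sd` must be >= 0")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  age ~ N(%.2f, %.2f) on [%g, %g]; education ~ N(%.2f, %.2f) on [%g, %g]\n",
              x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
              x$edu_mean, x$edu_sd, x$edu_range[1], x$edu_range[2]))
  cat(sprintf("  male fraction = %.3f\n", x$male_fraction))
  cat(sprintf("  latent: %.2f + %.2f ln(100 - age) + %.2f ln(education) + N(0, %.2f)\n",
              x$beta0, x$beta_age, x$beta_edu, x$latent_sd))
  cat(sprintf("  retest r = %.2f, rater sd = %.2f, format shift = %.2f\n",
              x$retest_reliability, x$rater_sd, x$format_shift))
  invisible(x)
}

#' Default measure-level generative model
#'
#' Every measure — the total included — is its own linear rescaling of the
#' latent factor plus measure noise, rounded and clipped to its range.
#' Intercepts are anchored at the published sample means; slopes and noise
#' SDs are chosen so that, with a unit-variance latent factor, the generated
#' SDs match the published marginals (total about 2.7, Itel-MMSE 0.96,
#' TICS 3). Because the total is generated directly, synthetic totals need
#' not equal the subtest sum exactly, mirroring the independent-rescaling
#' generative model rather than the scoring rule.
#'
#' Criterion screens (`itel_mmse`, `tics`) load on the same latent factor so
#' convergent-validity and ROC stages can run on synthetic cohorts.
#'
#' @return Tibble with columns `measure`, `intercept`, `slope`, `noise_sd`.
#' @export
phv_measure_model <- function() {
  tibble::tibble(
    measure = c("total", "attention", "concentration_wm",
                "concentration_total", "tracking_monitoring",
                "initiation_retrieval", "itel_mmse", "tics"),
    intercept = c(16.9, 4.3, 4.4, 6.2, 4.2, 4.0, 21.5, 34.9),
    slope = c(2.4, 0.55, 0.5, 1.1, 0.7, 0.65, 0.5, 1.6),
    noise_sd = c(1.24, 0.55, 0.5, 0.9, 0.7, 0.65, 0.82, 2.54)
  )
}
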