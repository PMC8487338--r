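# Synthetic-cohort generation. Each stage reseeds from spec$seed plus a fixed
# stage offset, so any stage is deterministic given the spec regardless of
# what was generated before it.

stage_seed <- function(spec, offset) {
  s <- (as.numeric(spec$seed) + offset) %% 2147483647
  as.integer(s)
}

# truncated-normal integers by rejection; exact and fast at cohort scale
r_trunc_norm_int <- function(n, mean, sd, range) {
  if (sd == 0) {
    x <- rep(round(mean), n)
    if (any(x < range[1] | x > range[2])) {
      abort("degenerate distribution (sd = 0) falls outside the declared range")
    }
    return(as.integer(x))
  }
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(rnorm(2L * (n - length(out)) + 10L, mean, sd))
    draw <- draw[draw >= range[1] & draw <= range[2]]
    out <- c(out, as.integer(draw))
  }
  out[seq_len(n)]
}

#' Draw cohort demographics
#'
#' Ages and educations are drawn from truncated normals (rejection sampling,
#' rounded to integer years, resampled if rounding leaves the range), sex from
#' a Bernoulli with the specified male fraction. Scores are left empty.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `id`, `age`, `education_years`, `sex`.
#' @export
#' @examples
#' sample_demographics(cohort_spec(n = 5, seed = 1))
sample_demographics <- function(spec) {
  spec <- validate_cohort_spec(spec)
  set.seed(stage_seed(spec, 0L))
  n <- spec$n
  tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    age = r_trunc_norm_int(n, spec$age_mean, spec$age_sd, spec$age_range),
    education_years = r_trunc_norm_int(n, spec$edu_mean, spec$edu_sd,
                                       spec$edu_range),
    sex = ifelse(runif(n) < spec$male_fraction, "M", "F")
  )
}

latent_ability <- function(cohort, spec, noise) {
  spec$beta0 + spec$beta_age * log(100 - cohort$age) +
    spec$beta_edu * log(pmax(cohort$education_years, 1)) + noise
}

#' Fill in measure scores from the latent generative model
#'
#' Each participant receives a latent ability
#' `g = beta0 + beta_age ln(100 - age) + beta_edu ln(max(education, 1)) + e`,
#' `e ~ N(0, latent_sd)`. Each measure's continuous latent score is
#' `intercept + slope * g` plus measure noise, then rounded and clipped to
#' the declared score range; the total score is generated the same way on
#' its 0--20 range. Criterion screens load on the same latent factor. Sex
#' never enters the model.
#'
#' The continuous pre-rounding scores are kept in the `"latent"` attribute of
#' the returned tibble; [generate_repeats()] uses them to build correlated
#' repeat administrations on the latent scale.
#'
#' @param records Tibble from [sample_demographics()].
#' @param spec The same [cohort_spec()].
#' @param criteria Also generate `itel_mmse` and `tics` columns
#'   (default `TRUE`).
#' @return `records` with score columns appended.
#' @export
generate_scores <- function(records, spec, criteria = TRUE) {
  spec <- validate_cohort_spec(spec)
  if (!all(c("age", "education_years") %in% names(records))) {
    abort("records lack demographics; run sample_demographics() first")
  }
  set.seed(stage_seed(spec, 1L))
  n <- nrow(records)
  g <- latent_ability(records, spec, rnorm(n, 0, spec$latent_sd))

  mm <- spec$measure_model
  if (!criteria) mm <- mm[!mm$measure %in% phv_criteria()$measure, ]
  latent <- tibble::tibble(id = records$id, g = g)
  out <- records
  for (i in seq_len(nrow(mm))) {
    m <- mm$measure[i]
    lat <- mm$intercept[i] + mm$slope[i] * g + rnorm(n, 0, mm$noise_sd[i])
    latent[[m]] <- lat
    out[[m]] <- as.integer(clip_range(round(lat), measure_range(m)))
  }
  out <- out[, c(names(records), mm$measure)]
  attr(out, "latent") <- latent
  attr(out, "cohort_spec") <- spec
  assert_scores_in_range(out)
  out
}

# correlated copy of a latent score vector with target correlation r
correlated_copy <- function(lat, r, z) {
  mu <- mean(lat)
  s <- stats::sd(lat)
  if (s == 0) return(lat)
  mu + r * (lat - mu) + sqrt(1 - r^2) * s * z
}

#' Generate repeat administrations
#'
#' Adds, for every screen measure, a 30-day retest column (`*_retest`,
#' a correlated copy on the latent scale achieving the target test-retest
#' correlation before discretization), a second-rater column (`*_rater2`,
#' observed score plus rounded rater noise), and an in-person column
#' (`*_inperson`, latent score minus the phone-minus-in-person shift plus
#' noise). All repeats are rounded and clipped to the measure range.
#'
#' @param records Output of [generate_scores()] (its `"latent"` attribute is
#'   required).
#' @param spec The same [cohort_spec()].
#' @return `records` with repeat columns appended; latent repeat scores are
#'   stored in the `"latent_retest"` attribute.
#' @export
generate_repeats <- function(records, spec) {
  spec <- validate_cohort_spec(spec)
  latent <- attr(records, "latent")
  if (is.null(latent)) {
    abort("records carry no latent scores; run generate_scores() first")
  }
  set.seed(stage_seed(spec, 2L))
  n <- nrow(records)
  r <- spec$retest_reliability
  out <- records
  latent_retest <- tibble::tibble(id = records$id)
  latent_inperson <- tibble::tibble(id = records$id)
  for (m in phv_measures()$measure) {
    rng <- measure_range(m)
    lat <- latent[[m]]
    ret <- correlated_copy(lat, r, rnorm(n))
    latent_retest[[m]] <- ret
    out[[paste0(m, "_retest")]] <-
      as.integer(clip_range(round(ret), rng))
    out[[paste0(m, "_rater2")]] <-
      as.integer(clip_range(records[[m]] + round(rnorm(n, 0, spec$rater_sd)),
                            rng))
    inp <- lat - spec$format_shift + rnorm(n, 0, spec$inperson_sd)
    latent_inperson[[m]] <- inp
    out[[paste0(m, "_inperson")]] <-
      as.integer(clip_range(round(inp), rng))
  }
  attr(out, "latent") <- latent
  attr(out, "latent_retest") <- latent_retest
  attr(out, "latent_inperson") <- latent_inperson
  attr(out, "cohort_spec") <- spec
  out
}

#' Generate binary item responses under a 2PL model
#'
#' The latent trait is the standardized cohort ability: the rank-based
#' inverse-normal transform of `g`, so the trait is a monotone function of
#' ability with exactly the standard-normal distribution that marginal
#' maximum likelihood assumes (this op is the generative inverse of
#' [fit_2pl()]). Each item response is Bernoulli with
#' `P(correct) = 1 / (1 + exp(-a (theta - b)))`. The direction convention is
#' that higher trait means higher success probability, so negative
#' discriminations in the bank are rejected.
#'
#' @param records Output of [generate_scores()].
#' @param item_bank Tibble with columns `item`, `a` (discrimination >= 0),
#'   `b` (difficulty).
#' @param seed Integer seed; defaults to the cohort spec's seed plus a fixed
#'   stage offset when the records carry one.
#' @return `records` with `item_<name>` columns of 0/1 responses.
#' @export
generate_item_responses <- function(records, item_bank, seed = NULL) {
  if (!all(c("item", "a", "b") %in% names(item_bank))) {
    abort("item_bank needs columns item, a, b")
  }
  if (any(item_bank$a < 0)) {
    abort("item discriminations must be >= 0 (higher trait -> higher success)")
  }
  latent <- attr(records, "latent")
  spec <- attr(records, "cohort_spec")
  if (is.null(seed)) {
    if (is.null(spec)) abort("supply `seed` (records carry no cohort_spec)")
    seed <- stage_seed(spec, 3L)
  }
  set.seed(as.integer(seed))
  g <- if (!is.null(latent)) latent$g else records$total
  theta <- if (stats::sd(g) > 0) {
    stats::qnorm(rank(g, ties.method = "average") / (length(g) + 1))
  } else g * 0
  out <- records
  for (i in seq_len(nrow(item_bank))) {
    p <- plogis(item_bank$a[i] * (theta - item_bank$b[i]))
    out[[paste0("item_", item_bank$item[i])]] <- rbinom(nrow(records), 1L, p)
  }
  attr(out, "latent") <- latent
  attr(out, "cohort_spec") <- spec
  out
}

#' Simulate a full cohort in one call
#'
#' Chains [sample_demographics()], [generate_scores()], and optionally
#' [generate_repeats()] and [generate_item_responses()].
#'
#' @inheritParams generate_scores
#' @param repeats Add retest / second-rater / in-person columns.
#' @param item_bank Optional item bank for binary responses.
#' @return A cohort tibble.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 50, seed = 7))
#' dplyr::glimpse(cohort)
simulate_cohort <- function(spec, repeats = FALSE, item_bank = NULL,
                            criteria = TRUE) {
  cohort <- generate_scores(sample_demographics(spec), spec,
                            criteria = criteria)
  if (repeats) cohort <- generate_repeats(cohort, spec)
  if (!is.null(item_bank)) {
    cohort <- generate_item_responses(cohort, item_bank)
  }
  cohort
}
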