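# Shared fixtures, all generated in code.

# A measure model with mid-range intercepts: keeps generated scores away from
# the floor/ceiling so regression-recovery checks are not attenuated by
# clipping. Chosen for recovery tests only; the package default emulates the
# published near-ceiling marginals.
mid_measure_model <- function() {
  mm <- phv_measure_model()
  mm$intercept <- c(10, 2.5, 2.5, 4.0, 2.5, 2.5, 11, 20)
  mm
}

mid_spec <- function(n, seed, ...) {
  cohort_spec(n = n, seed = seed, measure_model = mid_measure_model(), ...)
}

# true adjustment-direction coefficients of the generated total score:
# total = intercept + slope * g, and g carries beta_age * ln(100 - age)
# and beta_edu * ln(education)
true_total_coefficients <- function(spec) {
  mm <- spec$measure_model
  s <- mm$slope[mm$measure == "total"]
  c(age = -spec$beta_age * s, education = -spec$beta_edu * s)
}

toy_item_bank <- function() {
  tibble::tibble(
    item = c("i1", "i2", "i3"),
    a = c(0.8, 1.5, 2.4),
    b = c(-1, 0, 1)
  )
}
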