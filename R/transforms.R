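#' Covariate transforms used in demographic adjustment equations
#'
#' Normative adjustment equations in the Equivalent Score tradition regress
#' raw scores on transformed demographic covariates. The registry covers the
#' transforms that occur in published equations for this family of screens:
#' identity, `ln(100 - x)` (age), `x^2`, `x^3`, `sqrt(x)`, and `ln(x)`.
#'
#' `ln(x)` and `sqrt(x)` require non-negative/positive covariates; during
#' *fitting* the guard `ln(max(x, 1))` / `sqrt(max(x, 0))` is used so cohorts
#' containing education = 0 can be modelled, while *applying* an equation with
#' a `ln_x` term to education 0 raises a domain error (the published equations
#' are applied exactly as printed).
#'
#' @return A tibble with columns `transform_id`, `label`, and the function
#'   itself in a list column `fn`.
#' @export
phv_transforms <- function() {
  tibble::tibble(
    transform_id = c("identity", "ln_100_minus_x", "x_squared", "x_cubed",
                     "sqrt_x", "ln_x"),
    label = c("x", "ln(100 - x)", "x^2", "x^3", "sqrt(x)", "ln(x)"),
    fn = list(
      function(x) x,
      function(x) log(100 - x),
      function(x) x^2,
      function(x) x^3,
      function(x) sqrt(x),
      function(x) log(x)
    )
  )
}

transform_fn <- function(transform_id, guard = FALSE) {
  reg <- phv_transforms()
  idx <- match(transform_id, reg$transform_id)
  if (is.na(idx)) abort(paste0("unknown transform '", transform_id, "'"))
  f <- reg$fn[[idx]]
  if (!guard) return(f)
  switch(transform_id,
    ln_x = function(x) log(pmax(x, 1)),
    sqrt_x = function(x) sqrt(pmax(x, 0)),
    f
  )
}

transform_label <- function(transform_id) {
  reg <- phv_transforms()
  reg$label[match(transform_id, reg$transform_id)]
}

# inverse transform: the covariate value at which T(x) equals `value`
transform_inverse <- function(transform_id, value) {
  switch(transform_id,
    identity = value,
    ln_100_minus_x = 100 - exp(value),
    x_squared = sqrt(value),
    x_cubed = value^(1 / 3),
    sqrt_x = value^2,
    ln_x = exp(value),
    abort(paste0("unknown transform '", transform_id, "'"))
  )
}

# domain check when applying an equation as printed; returns index of violations
transform_domain_violations <- function(transform_id, x) {
  switch(transform_id,
    ln_100_minus_x = which(x >= 100),
    ln_x = which(x <= 0),
    sqrt_x = which(x < 0),
    integer(0)
  )
}

#' Default candidate transforms for equation fitting
#'
#' Age candidates cover the decelerating decline (`ln(100 - age)`) and
#' accelerating polynomial (`age^2`, `age^3`) shapes seen in published
#' normative equations; education candidates cover the diminishing-returns
#' shapes `ln(education)` and `sqrt(education)`.
#'
#' @return Named list with character vectors `age` and `education`.
#' @export
phv_candidate_transforms <- function() {
  list(
    age = c("identity", "ln_100_minus_x", "x_squared", "x_cubed"),
    education = c("identity", "ln_x", "sqrt_x")
  )
}
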