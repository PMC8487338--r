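# CSV and norms-file I/O with an explicit header contract.

cohort_required_columns <- c("id", "age", "education_years")

#' Read a cohort CSV
#'
#' Header contract: `id, age, education_years` (plus `sex` for cohorts used
#' in equation fitting), the measure columns
#' named as in [phv_measures()], optional `itel_mmse`/`tics`, optional
#' `*_retest`, `*_rater2`, `*_inperson` repeats, and optional `item_*`
#' 0/1 responses. Scores are validated against the declared ranges; rows
#' that violate them are reported by id.
#'
#' @param path CSV path.
#' @param require_scores Also require the six measure columns.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, require_scores = FALSE) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  need <- cohort_required_columns
  if (require_scores) need <- c(need, phv_measures()$measure)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0L) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  assert_scores_in_range(cohort)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(cohort)
}

#' Write derived norms (equations + bands) to a JSON file
#'
#' User-derived norms are always written to their own file; the published
#' fixture shipped with the package is read-only.
#'
#' @param norms Named list of `norm_equation`s.
#' @param bands Named list of `es_band_table`s.
#' @param path Output path (`.json`).
#' @param version Version stamp embedded in the file.
#' @return `path`, invisibly.
#' @export
write_norms <- function(norms, bands, path, version = "derived") {
  payload <- list(
    version = version,
    note = paste("Derived norms; intermediate ES thresholds use the",
                 "20th/35th-centile partition rule."),
    equations = purrr::map(unname(norms), function(eq) {
      list(measure = eq$measure, guard = isTRUE(eq$guard),
           terms = purrr::transpose(as.list(eq$terms)) |>
             purrr::map(~purrr::map(.x, identity)))
    }),
    bands = purrr::map(unname(bands), function(bd) {
      list(measure = bd$measure, oTL = bd$oTL, iTL = bd$iTL,
           es_upper = bd$es_upper)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a norms JSON file
#'
#' @param path Path written by [write_norms()].
#' @return List with `equations` (named `norm_equation`s) and `bands`
#'   (named `es_band_table`s).
#' @export
read_norms <- function(path) {
  fx <- jsonlite::fromJSON(path, simplifyVector = FALSE) |>
    normalize_norms_list()
  eqs <- purrr::map(fx$equations, function(eq) {
    new_norm_equation(eq$measure, tibble::as_tibble(eq$terms),
                      source = paste0("file (", fx$version, ")"),
                      guard = isTRUE(eq$guard))
  }) |> setNames(purrr::map_chr(fx$equations, "measure"))
  bds <- purrr::map(fx$bands, function(bd) {
    new_es_band_table(bd$measure, n = NA_integer_, oTL = bd$oTL,
                      iTL = bd$iTL, es_upper = bd$es_upper,
                      source = paste0("file (", fx$version, ")"))
  }) |> setNames(purrr::map_chr(fx$bands, "measure"))
  list(equations = eqs, bands = bds, version = fx$version)
}
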