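#' Measure registry for the ALS-CBS phone version
#'
#' The cognitive section of the screen yields a total score (0--20, the sum of
#' the four subtests) and five reported measures: Attention (0--5),
#' Concentration working-memory span (0--5), Concentration total correct
#' sequences (0--8), Tracking/Monitoring (0--5), and Initiation and Retrieval
#' (0--5). The Concentration "total" outcome is an auxiliary sustained-attention
#' measure and does not enter the screen total.
#'
#' @return A tibble with one row per measure: `measure` (machine name),
#'   `label`, `min`, `max`, and `in_total` (whether the measure is one of the
#'   four subtests summed into the total score).
#' @export
#' @examples
#' phv_measures()
phv_measures <- function() {
  tibble::tibble(
    measure = c(
      "total", "attention", "concentration_wm", "concentration_total",
      "tracking_monitoring", "initiation_retrieval"
    ),
    label = c(
      "Total score", "Attention", "Concentration-WM", "Concentration-Total",
      "Tracking/Monitoring", "Initiation and Retrieval"
    ),
    min = 0L,
    max = c(20L, 5L, 5L, 8L, 5L, 5L),
    in_total = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
}

# criterion telephone screens used for convergent validity / ROC
phv_criteria <- function() {
  tibble::tibble(
    measure = c("itel_mmse", "tics"),
    label = c("Itel-MMSE", "TICS"),
    min = 0L,
    max = c(22L, 41L)
  )
}

measure_range <- function(measure) {
  reg <- dplyr::bind_rows(phv_measures()[c("measure", "min", "max")],
                          phv_criteria()[c("measure", "min", "max")])
  row <- reg[reg$measure == measure, ]
  if (nrow(row) == 0L) abort(paste0("unknown measure '", measure, "'"))
  c(row$min, row$max)
}

clip_range <- function(x, range) pmin(pmax(x, range[1]), range[2])

assert_scores_in_range <- function(cohort, measures = phv_measures()) {
  for (i in seq_len(nrow(measures))) {
    m <- measures$measure[i]
    if (!m %in% names(cohort)) next
    bad <- which(cohort[[m]] < measures$min[i] | cohort[[m]] > measures$max[i])
    if (length(bad) > 0L) {
      abort(paste0(
        "scores out of range for '", m, "' (", measures$min[i], "-",
        measures$max[i], ") in rows with id: ",
        paste(cohort$id[bad], collapse = ", ")
      ))
    }
  }
  invisible(cohort)
}
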