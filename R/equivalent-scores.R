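#' Non-parametric tolerance-limit ranks
#'
#' Order-statistic ranks bracketing the population `p`-th centile with the
#' stated confidence, computed by exact binomial enumeration. The outer rank
#' is the largest `r` such that `P[Binomial(n, p) >= r] >= confidence` (the
#' `r`-th order statistic is, with that confidence, at or below the
#' population centile); the inner rank is the smallest `s` such that
#' `P[Binomial(n, p) <= s - 1] >= confidence`.
#'
#' @param n Sample size.
#' @param p Target centile as a probability (default .05).
#' @param confidence Confidence level (default .95).
#' @return One-row tibble with `n`, `p`, `confidence`, `outer_rank`,
#'   `inner_rank`.
#' @export
#' @examples
#' tolerance_limit_ranks(359)
tolerance_limit_ranks <- function(n, p = 0.05, confidence = 0.95) {
  stopifnot(n >= 1, p > 0, p < 1, confidence > 0, confidence < 1)
  probs <- dbinom(0:n, n, p)
  upper_tail <- rev(cumsum(rev(probs)))  # upper_tail[r + 1] = P[X >= r]
  lower_tail <- cumsum(probs)            # lower_tail[s]     = P[X <= s - 1]
  outer_ok <- which(upper_tail[-1] >= confidence)  # candidate ranks r >= 1
  if (length(outer_ok) == 0L) {
    n_min <- ceiling(log(1 - confidence) / log(1 - p))
    abort(paste0(
      "no valid outer tolerance rank at n = ", n, ", p = ", p,
      ", confidence = ", confidence, "; minimum usable n is ", n_min
    ))
  }
  outer_rank <- max(outer_ok)
  inner_rank <- which(lower_tail >= confidence)[1]
  tibble::tibble(n = n, p = p, confidence = confidence,
                 outer_rank = as.integer(outer_rank),
                 inner_rank = as.integer(inner_rank))
}

new_es_band_table <- function(measure, n, oTL, iTL, es_upper,
                              ranks = NULL, source = "derived",
                              partition_rule =
                                "equal cumulative-probability thirds: 20th and 35th centiles between the 5th centile and the median") {
  stopifnot(length(es_upper) == 4L)
  structure(
    list(measure = measure, n = n, oTL = oTL, iTL = iTL,
         es_upper = as.numeric(es_upper), ranks = ranks, source = source,
         partition_rule = partition_rule),
    class = "es_band_table"
  )
}

#' Derive Equivalent Score bands from ranked adjusted scores
#'
#' The five-level ES scale anchored to non-parametric tolerance limits:
#' ES 0 ("defective") is everything at or below the outer tolerance limit
#' (oTL); ES 4 ("high-end normal") everything above the sample median; the
#' interval between is split into ES 1-3 ("borderline", "low-end normal",
#' "normal"). The oTL/iTL are the order statistics at the ranks from
#' [tolerance_limit_ranks()]; the ES1/ES2 upper boundaries sit at the sample
#' centiles dividing the cumulative-probability interval (p, .50] into three
#' equal parts — the 20th and 35th centiles for p = .05 — and the ES3 upper
#' boundary is the sample median. Centiles use the rank convention
#' `ceiling(q * n)`.
#'
#' @param adjusted_scores Numeric vector of adjusted scores.
#' @param measure Measure name carried into the table.
#' @param p,confidence Passed to [tolerance_limit_ranks()].
#' @return An `es_band_table`.
#' @export
derive_es_bands <- function(adjusted_scores, measure = "measure",
                            p = 0.05, confidence = 0.95) {
  x <- sort(adjusted_scores[is.finite(adjusted_scores)])
  n <- length(x)
  ranks <- tolerance_limit_ranks(n, p, confidence)
  q_ranks <- ceiling(c(es1 = (p + (0.5 - p) / 3),
                       es2 = (p + 2 * (0.5 - p) / 3),
                       es3 = 0.5) * n)
  oTL <- x[ranks$outer_rank]
  iTL <- x[ranks$inner_rank]
  uppers <- c(oTL, x[q_ranks])
  if (any(diff(uppers) <= 0)) {
    abort(paste0(
      "ES band bounds collapse for '", measure, "': ties leave bounds (",
      paste(signif(uppers, 6), collapse = ", "),
      ") non-increasing; more distinct adjusted scores are needed"
    ))
  }
  new_es_band_table(
    measure = measure, n = n, oTL = oTL, iTL = iTL, es_upper = uppers,
    ranks = c(outer = ranks$outer_rank, inner = ranks$inner_rank,
              setNames(as.integer(q_ranks), names(q_ranks)))
  )
}

#' @export
print.es_band_table <- function(x, ...) {
  cat("<es_band_table> ", x$measure, " (", x$source, ")\n", sep = "")
  cat(sprintf("  oTL = %g, iTL = %g\n", x$oTL, x$iTL))
  u <- x$es_upper
  cat(sprintf("  ES0: <= %g | ES1: (%g, %g] | ES2: (%g, %g] | ES3: (%g, %g] | ES4: > %g\n",
              u[1], u[1], u[2], u[2], u[3], u[3], u[4], u[4]))
  invisible(x)
}

es_labels <- c("defective", "borderline", "low-end normal", "normal",
               "high-end normal")

#' Classify adjusted scores into Equivalent Scores
#'
#' Total, monotone non-decreasing step classification: scores at or below the
#' ES0 bound (the oTL) get ES 0, then each successive band up to its
#' inclusive upper bound, with everything above the ES3 bound (the median)
#' getting ES 4. The borderline flag marks scores of uncertain normality,
#' `oTL < score <= iTL`.
#'
#' @param band_table An `es_band_table` (derived or from
#'   [published_bands()]).
#' @param adjusted_score Numeric vector.
#' @return Tibble with `adjusted_score`, `es` (0-4), `label`, `borderline`.
#' @export
#' @examples
#' classify_es(published_bands()[["total"]], c(12.42, 13.0, 17.14))
classify_es <- function(band_table, adjusted_score) {
  stopifnot(inherits(band_table, "es_band_table"))
  u <- band_table$es_upper
  es <- vapply(adjusted_score, function(z) sum(z > u), numeric(1))
  tibble::tibble(
    adjusted_score = adjusted_score,
    es = as.integer(es),
    label = es_labels[es + 1L],
    borderline = adjusted_score > band_table$oTL &
      adjusted_score <= band_table$iTL
  )
}

#' Published Equivalent Score band tables
#'
#' The six published band tables (tolerance limits and ES interval bounds on
#' the adjusted-score scale) for the ALS-CBS phone version total and subtest
#' scores, transcribed as printed. These are authoritative for scoring
#' patients; [derive_es_bands()] is for new cohorts and never overwrites
#' this fixture.
#'
#' @return Named list of six `es_band_table` objects.
#' @export
#' @examples
#' published_bands()[["total"]]
published_bands <- function() {
  fx <- read_norms_fixture()
  purrr::map(fx$bands, function(bd) {
    new_es_band_table(
      measure = bd$measure, n = 359L, oTL = bd$oTL, iTL = bd$iTL,
      es_upper = bd$es_upper, source = paste0("published (", fx$version, ")")
    )
  }) |> setNames(purrr::map_chr(fx$bands, "measure"))
}

#' Score patients against norms
#'
#' The applet-style patient scorer: adjusts each raw measure with its
#' equation and classifies the adjusted score into an ES band, appending
#' `<measure>_as`, `<measure>_es`, and `<measure>_borderline` columns.
#'
#' @param data Tibble with `age`, `education_years`, and raw measure columns
#'   (any subset of the six).
#' @param norms Named list of `norm_equation`s (default published).
#' @param bands Named list of `es_band_table`s (default published).
#' @return `data` with adjusted-score and ES columns appended.
#' @export
#' @examples
#' patients <- tibble::tibble(id = "P1", age = 70, education_years = 8,
#'                            sex = "F", total = 14)
#' score_patients(patients)
score_patients <- function(data, norms = published_norms(),
                           bands = published_bands()) {
  data <- adjust_scores(data, norms)
  for (m in names(bands)) {
    as_col <- paste0(m, "_as")
    if (!as_col %in% names(data)) next
    cls <- classify_es(bands[[m]], data[[as_col]])
    data[[paste0(m, "_es")]] <- cls$es
    data[[paste0(m, "_borderline")]] <- cls$borderline
  }
  data
}

#' @export
tidy.es_band_table <- function(x, ...) {
  u <- x$es_upper
  tibble::tibble(
    measure = x$measure,
    es = 0:4,
    label = es_labels,
    lower = c(-Inf, u),
    upper = c(u, Inf),
    source = x$source
  )
}

#' @export
glance.es_band_table <- function(x, ...) {
  tibble::tibble(measure = x$measure, n = x$n, oTL = x$oTL, iTL = x$iTL,
                 median_bound = x$es_upper[4], source = x$source,
                 partition_rule = x$partition_rule)
}

#' Plot an Equivalent Score band table
#'
#' Horizontal bands on the adjusted-score axis, one fill per ES level, with
#' the tolerance limits marked.
#'
#' @param object An `es_band_table`.
#' @param pad Padding beyond the outer bounds for the open-ended bands.
#' @param ... Unused.
#' @export
autoplot.es_band_table <- function(object, pad = 2, ...) {
  bands <- tidy(object)
  bands$lower[1] <- object$es_upper[1] - pad
  bands$upper[5] <- object$es_upper[4] + pad
  ggplot2::ggplot(bands) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                    ymin = 0, ymax = 1,
                                    fill = factor(.data$es))) +
    ggplot2::geom_vline(xintercept = c(object$oTL, object$iTL),
                        linetype = "dashed") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", name = "ES") +
    ggplot2::labs(x = "Adjusted score", y = NULL,
                  title = paste("Equivalent Score bands:", object$measure),
                  subtitle = "dashed lines: outer / inner tolerance limits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
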