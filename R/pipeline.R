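#' Run the full validation battery on a cohort
#'
#' Reproduces the standard analysis sequence of a normative/psychometric
#' study on one cohort tibble: distribution screening per measure,
#' demographic correlations (Bonferroni-corrected; the family size is
#' echoed), convergent validity against criterion screens, PCA of the four
#' subtests, Cronbach's alpha, test-retest and inter-rater ICCs, ROC
#' accuracy against each criterion's 5th-centile split, paired equivalence
#' (TOST) between phone and in-person formats, and floor/ceiling checks.
#' Stages whose columns are absent are skipped and listed.
#'
#' @param cohort Cohort tibble (see [read_cohort()] for the column
#'   contract).
#' @param tost_bounds,tost_bounds_scale Equivalence bounds forwarded to
#'   [tost_paired()].
#' @param icc_model ICC form forwarded to [icc()].
#' @return Object of class `validation_report`: a named list of result
#'   tibbles plus the conventions used.
#' @export
validate_cohort <- function(cohort, tost_bounds = 0.5,
                            tost_bounds_scale = "sd",
                            icc_model = "ICC(A,1)") {
  measures <- intersect(phv_measures()$measure, names(cohort))
  subtests <- intersect(phv_measures()$measure[phv_measures()$in_total],
                        names(cohort))
  criteria <- intersect(phv_criteria()$measure, names(cohort))
  skipped <- character()

  screening <- purrr::map_dfr(c(measures, criteria), function(m) {
    dplyr::mutate(screen_distribution(cohort[[m]]), measure = m, .before = 1)
  })
  screen_of <- setNames(screening$method, screening$measure)

  # demographic correlations: 6 measures x 2 covariates family
  demo_family <- length(measures) * 2L
  demographic <- purrr::map_dfr(measures, function(m) {
    purrr::map_dfr(c("age", "education_years"), function(cv) {
      dplyr::mutate(
        correlate(cohort[[m]], cohort[[cv]], screening = screen_of[[m]],
                  n_tests = demo_family),
        measure = m, covariate = cv, .before = 1
      )
    })
  })

  convergent <- NULL
  if (length(criteria) > 0L) {
    conv_family <- length(measures) * length(criteria)
    convergent <- purrr::map_dfr(measures, function(m) {
      purrr::map_dfr(criteria, function(cr) {
        dplyr::mutate(
          correlate(cohort[[m]], cohort[[cr]],
                    screening = if (screen_of[[m]] == "nonparametric" ||
                                    screen_of[[cr]] == "nonparametric")
                      "nonparametric" else "parametric",
                    n_tests = conv_family),
          measure = m, criterion = cr, .before = 1
        )
      })
    })
  } else skipped <- c(skipped, "convergent_validity", "roc")

  pca <- if (length(subtests) >= 2) pca_structure(cohort[subtests]) else {
    skipped <- c(skipped, "pca"); NULL
  }
  alpha_res <- if (length(subtests) >= 2) cronbach_alpha(cohort[subtests])
    else { skipped <- c(skipped, "cronbach_alpha"); NULL }

  icc_retest <- if ("total_retest" %in% names(cohort)) {
    dplyr::mutate(icc(cohort[c("total", "total_retest")], model = icc_model),
                  design = "test-retest", .before = 1)
  } else { skipped <- c(skipped, "icc_retest"); NULL }
  icc_rater <- if ("total_rater2" %in% names(cohort)) {
    dplyr::mutate(icc(cohort[c("total", "total_rater2")], model = icc_model),
                  design = "inter-rater", .before = 1)
  } else { skipped <- c(skipped, "icc_rater"); NULL }

  roc <- NULL
  if (length(criteria) > 0L) {
    roc <- purrr::map_dfr(criteria, function(cr) {
      res <- tryCatch(roc_vs_criterion(cohort$total, cohort[[cr]]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        # e.g. a ceilinged criterion with no one strictly below its 5th
        # centile in a small sample; report the stage as skipped
        skipped <<- c(skipped, paste0("roc_", cr, " (",
                                      conditionMessage(res), ")"))
        return(NULL)
      }
      dplyr::mutate(tibble::as_tibble(res), criterion = cr, .before = 1)
    })
    if (nrow(roc) == 0L) roc <- NULL
  }

  tost <- if ("total_inperson" %in% names(cohort)) {
    tost_paired(cohort$total, cohort$total_inperson, bounds = tost_bounds,
                bounds_scale = tost_bounds_scale)
  } else { skipped <- c(skipped, "tost"); NULL }

  fc <- purrr::map_dfr(measures, function(m) {
    dplyr::mutate(floor_ceiling(cohort[[m]], measure_range(m)),
                  measure = m, .before = 1)
  })

  structure(
    list(
      n = nrow(cohort),
      screening = screening,
      demographic_correlations = demographic,
      convergent_validity = convergent,
      pca = pca,
      cronbach_alpha = alpha_res,
      icc = dplyr::bind_rows(icc_retest, icc_rater),
      roc = roc,
      tost = tost,
      floor_ceiling = fc,
      skipped = skipped,
      conventions = list(
        kurtosis = "excess (normal = 0); nonparametric iff |skew| >= 1 or |ex.kurt| >= 3",
        icc_model = icc_model,
        tost_bounds = tost_bounds, tost_bounds_scale = tost_bounds_scale,
        roc = "positive class strictly below the criterion 5th centile; Hanley-McNeil SE",
        bonferroni = "family sizes echoed per table"
      )
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n =", x$n, "\n")
  if (!is.null(x$cronbach_alpha)) {
    cat(sprintf("  Cronbach's alpha = %.2f\n", x$cronbach_alpha$value))
  }
  if (!is.null(x$icc) && nrow(x$icc) > 0) {
    for (i in seq_len(nrow(x$icc))) {
      cat(sprintf("  ICC (%s, %s) = %.2f\n", x$icc$design[i],
                  x$icc$icc_model[i], x$icc$value[i]))
    }
  }
  if (!is.null(x$pca)) {
    cat(sprintf("  PCA: first component %.2f%% of variance (%d retained)\n",
                x$pca$percent_variance_first, x$pca$n_retained))
  }
  if (!is.null(x$roc)) {
    for (i in seq_len(nrow(x$roc))) {
      cat(sprintf("  AUC vs %s = %.2f, 95%% CI [%.2f, %.2f], SE = %.2f\n",
                  x$roc$criterion[i], x$roc$auc[i], x$roc$ci_lower[i],
                  x$roc$ci_upper[i], x$roc$se[i]))
    }
  }
  if (!is.null(x$tost)) {
    cat(sprintf("  TOST: t(%d) = %.2f, p(two-sided) = %.3f, p(TOST) = %.3f, equivalent = %s\n",
                x$tost$df, x$tost$t_conventional, x$tost$p_nhst,
                x$tost$p_tost, x$tost$equivalent))
  }
  if (length(x$skipped) > 0) {
    cat("  skipped (columns absent):", paste(x$skipped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    cronbach_alpha = x$cronbach_alpha$value %||% NA_real_,
    icc_retest = (x$icc$value[x$icc$design == "test-retest"])[1] %||% NA_real_,
    icc_rater = (x$icc$value[x$icc$design == "inter-rater"])[1] %||% NA_real_,
    pca_pct_first = if (!is.null(x$pca)) x$pca$percent_variance_first
      else NA_real_,
    tost_p = x$tost$p_tost %||% NA_real_
  )
}

#' Derive a complete set of norms from a cohort
#'
#' Fits one adjustment equation per measure, adjusts the cohort, and derives
#' ES band tables from the adjusted scores.
#'
#' @param cohort Cohort tibble with demographics and the six raw measures.
#' @param measures Which measures to norm.
#' @param alpha Significance level for predictor retention.
#' @return List with `equations`, `bands`, and the cohort with `_as`
#'   columns (`adjusted`).
#' @export
derive_norms <- function(cohort, measures = phv_measures()$measure,
                         alpha = 0.05) {
  measures <- intersect(measures, names(cohort))
  equations <- purrr::map(measures, function(m) {
    fit_norm_equation(cohort, m, alpha = alpha)
  }) |> setNames(measures)
  adjusted <- adjust_scores(cohort, equations)
  bands <- purrr::map(measures, function(m) {
    derive_es_bands(adjusted[[paste0(m, "_as")]], measure = m)
  }) |> setNames(measures)
  list(equations = equations, bands = bands, adjusted = adjusted)
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON path")
  config
}

#' Run a pipeline command from a configuration
#'
#' Orchestrates the analysis sequence with file inputs/outputs. Commands:
#' \describe{
#'   \item{simulate}{Generate a synthetic cohort (requires an explicit
#'     `seed` in `config$cohort`) and write it to `config$output`.}
#'   \item{derive-norms}{Read `config$input`, fit equations and ES bands,
#'     write a norms JSON to `config$output` (and a text report to
#'     `config$report` when given).}
#'   \item{score}{Read a patient CSV from `config$input`, score against the
#'     published norms (or `config$norms` file), write `config$output`.}
#'   \item{validate}{Run [validate_cohort()] on `config$input`, write a JSON
#'     report to `config$output`.}
#'   \item{irt}{Dichotomize `item_*` columns of `config$input`, fit the 2PL,
#'     write the classified item parameters to `config$output`.}
#' }
#' Outputs are deterministic given the configuration; every report embeds
#' the configuration used. Input files are never modified.
#'
#' @param config Named list or path to a YAML config with at least
#'   `command`.
#' @return The in-memory result of the command, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- resolve_config(config)
  command <- config$command %||% abort("config needs a `command`")
  result <- switch(command,
    "simulate" = pipeline_simulate(config),
    "derive-norms" = pipeline_derive_norms(config),
    "score" = pipeline_score(config),
    "validate" = pipeline_validate(config),
    "irt" = pipeline_irt(config),
    abort(paste0("unknown command '", command, "'"))
  )
  invisible(result)
}

pipeline_simulate <- function(config) {
  spec_args <- config$cohort %||% abort("simulate needs a `cohort` block")
  if (is.null(spec_args$seed)) {
    abort("stochastic command 'simulate' requires an explicit seed")
  }
  keep <- intersect(names(spec_args), names(formals(cohort_spec)))
  spec <- do.call(cohort_spec, spec_args[keep])
  cohort <- simulate_cohort(
    spec,
    repeats = isTRUE(config$repeats),
    item_bank = if (!is.null(config$item_bank))
      tibble::as_tibble(config$item_bank) else NULL
  )
  if (!is.null(config$output)) write_cohort(cohort, config$output)
  cohort
}

pipeline_derive_norms <- function(config) {
  cohort <- read_cohort(config$input, require_scores = TRUE)
  res <- derive_norms(cohort, alpha = config$alpha %||% 0.05)
  if (!is.null(config$output)) {
    write_norms(res$equations, res$bands, config$output,
                version = config$version %||% "derived")
  }
  if (!is.null(config$report)) {
    lines <- c(
      "Derived norms report",
      paste0("n = ", nrow(cohort)),
      "",
      purrr::map_chr(res$equations, function(eq) {
        paste0(eq$measure, ": ", nrow(eq$terms), " term(s), R^2 = ",
               signif(eq$fit$r_squared, 4))
      }),
      "",
      purrr::map_chr(res$bands, function(bd) {
        sprintf("%s: oTL %.2f, iTL %.2f, ES uppers %s [%s]",
                bd$measure, bd$oTL, bd$iTL,
                paste(signif(bd$es_upper, 6), collapse = ", "),
                bd$partition_rule)
      }),
      "",
      paste0("config: ", jsonlite::toJSON(config, auto_unbox = TRUE))
    )
    writeLines(lines, config$report)
  }
  res
}

pipeline_score <- function(config) {
  patients <- read_cohort(config$input)
  if (!is.null(config$norms)) {
    nf <- read_norms(config$norms)
    scored <- score_patients(patients, norms = nf$equations,
                             bands = nf$bands)
  } else {
    scored <- score_patients(patients)
  }
  if (!is.null(config$output)) write_cohort(scored, config$output)
  scored
}

pipeline_validate <- function(config) {
  cohort <- read_cohort(config$input, require_scores = TRUE)
  report <- validate_cohort(
    cohort,
    tost_bounds = config$tost_bounds %||% 0.5,
    tost_bounds_scale = config$tost_bounds_scale %||% "sd",
    icc_model = config$icc_model %||% "ICC(A,1)"
  )
  if (!is.null(config$output)) {
    payload <- list(
      config = config,
      n = report$n,
      conventions = report$conventions,
      cronbach_alpha = report$cronbach_alpha,
      icc = report$icc,
      pca = if (!is.null(report$pca)) glance(report$pca),
      roc = report$roc,
      tost = report$tost,
      demographic_correlations = report$demographic_correlations,
      convergent_validity = report$convergent_validity,
      floor_ceiling = report$floor_ceiling,
      skipped = report$skipped
    )
    jsonlite::write_json(payload, config$output, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

pipeline_irt <- function(config) {
  cohort <- read_cohort(config$input)
  item_cols <- grep("^item_", names(cohort), value = TRUE)
  if (length(item_cols) == 0L) abort("no item_* columns in input")
  items <- cohort[item_cols]
  names(items) <- sub("^item_", "", names(items))
  dirs <- unlist(config$item_directions %||% NULL)
  dich <- dichotomize_items(items, item_directions = dirs,
                            centile = config$centile %||% 5)
  fit <- fit_2pl(dich$binary,
                 max_iter = config$max_iter %||% 1000,
                 tol = config$tol %||% 1e-4)
  params <- classify_items(
    fit,
    discriminative_cut = config$discriminative_cut %||% 1.5,
    highly_discriminative_cut = config$highly_discriminative_cut %||% 1.7,
    difficulty_cut = config$difficulty_cut %||% 3
  )
  params$dropped_zero_variance <- FALSE
  if (length(dich$dropped) > 0L) {
    params <- dplyr::bind_rows(
      params,
      tibble::tibble(item = dich$dropped, a = NA_real_, b = NA_real_,
                     heywood = FALSE, discriminative = NA,
                     highly_discriminative = NA, difficult = NA,
                     dropped_zero_variance = TRUE)
    )
  }
  if (!is.null(config$output)) readr::write_csv(params, config$output)
  list(params = params, fit = fit, dichotomization = dich)
}
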