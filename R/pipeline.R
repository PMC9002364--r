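#' Study configuration
#'
#' Bundles the choices the stratified analysis depends on: the predictor
#' panel, the adjustment covariates, the MetS definitions to evaluate,
#' the predictor coding for the odds-ratio models, and numeric settings.
#' Adjustment covariates must be disjoint from predictors.
#'
#' @param predictors Index columns to evaluate as MetS predictors.
#' @param covariates Adjustment covariates for the odds-ratio models
#'   (default: age, systolic blood pressure, total cholesterol, LDL
#'   cholesterol and eGFR).
#' @param criteria MetS definitions to run; the first is used for the
#'   cut-off/odds-ratio table.
#' @param mode Predictor coding for the adjusted models: `"binary"`
#'   dichotomises at the Youden-optimal cut-off (score >= cut-off),
#'   `"continuous"` keeps the natural per-unit scale.
#' @param alpha Normality-gate significance level (Shapiro-Wilk).
#' @param conf_level Confidence level for intervals.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(predictors = c("bmi", "wc", "vfa", "sfa", "vai",
                                        "cvai", "lap"),
                         covariates = c("age", "sbp", "tc", "ldl", "egfr"),
                         criteria = c("china2020", "atpiii", "idf"),
                         mode = c("binary", "continuous"),
                         alpha = 0.05, conf_level = 0.95) {
  mode <- match.arg(mode)
  criteria <- match.arg(criteria, several.ok = TRUE)
  overlap <- intersect(predictors, covariates)
  if (length(overlap) > 0L) {
    abort(sprintf("adjustment covariates must be disjoint from predictors (%s).",
                  paste(overlap, collapse = ", ")),
          class = "metsindex_config_error")
  }
  structure(
    list(predictors = predictors, covariates = covariates,
         criteria = criteria, mode = mode, alpha = alpha,
         conf_level = conf_level),
    class = "study_config"
  )
}

# Shapiro-Wilk normality gate; constant or out-of-range samples count as
# non-normal rather than erroring
.is_normalish <- function(x, alpha) {
  if (length(x) < 3 || length(x) > 5000) return(FALSE)
  p <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  p > alpha
}

.fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
.fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
}

#' Descriptive comparison table
#'
#' Two-group summaries with normality-gated test selection, mirroring
#' conventional clinical baseline tables: when Shapiro-Wilk accepts
#' normality in both groups (at `alpha`) a variable is summarised as
#' mean +/- SD and compared by Student's t-test (pooled variance);
#' otherwise as median (IQR) with the Mann-Whitney U test. Logical
#' variables are compared by the chi-square test without continuity
#' correction (the corrected statistic is reported alongside), falling
#' back to Fisher's exact test when any expected cell is below 5. Groups
#' with fewer than 3 subjects are summarised without a test and flagged.
#'
#' @param data A data frame.
#' @param group Unquoted two-level grouping column (logical or factor).
#' @param vars Character vector of variable columns to summarise.
#' @param alpha Normality-gate level. Default 0.05.
#'
#' @return A tibble with one row per variable: `variable`, `type`,
#'   `summary_1`, `summary_2` (groups in sorted level order), `test`,
#'   `statistic`, `p_value`, `statistic_corrected`, `p_corrected`,
#'   `note`.
#' @export
descriptive_table <- function(data, group, vars, alpha = 0.05) {
  g <- pull(data, {{ group }})
  levels <- sort(unique(g))
  if (length(levels) != 2L) {
    abort("`group` must have exactly two observed levels.",
          class = "metsindex_domain_error")
  }
  check_required_columns(data, vars, "data")
  too_small <- any(table(g) < 3)
  map_dfr(vars, function(v) {
    x1 <- data[[v]][g == levels[1]]
    x2 <- data[[v]][g == levels[2]]
    x1 <- x1[!is.na(x1)]
    x2 <- x2[!is.na(x2)]
    if (is.logical(data[[v]])) {
      tab <- rbind(c(sum(x1), sum(!x1)), c(sum(x2), sum(!x2)))
      s1 <- sprintf("%d (%.1f%%)", sum(x1), 100 * mean(x1))
      s2 <- sprintf("%d (%.1f%%)", sum(x2), 100 * mean(x2))
      if (too_small) {
        return(tibble(variable = v, type = "categorical",
                      summary_1 = s1, summary_2 = s2, test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      statistic_corrected = NA_real_, p_corrected = NA_real_,
                      note = "group too small for a test"))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        tibble(variable = v, type = "categorical", summary_1 = s1,
               summary_2 = s2, test = "fisher", statistic = NA_real_,
               p_value = ft$p.value, statistic_corrected = NA_real_,
               p_corrected = NA_real_, note = "expected cell < 5")
      } else {
        ct <- chisq.test(tab, correct = FALSE)
        ctc <- chisq.test(tab, correct = TRUE)
        tibble(variable = v, type = "categorical", summary_1 = s1,
               summary_2 = s2, test = "chi-square",
               statistic = unname(ct$statistic), p_value = ct$p.value,
               statistic_corrected = unname(ctc$statistic),
               p_corrected = ctc$p.value, note = NA_character_)
      }
    } else {
      normal <- .is_normalish(x1, alpha) && .is_normalish(x2, alpha)
      if (too_small) {
        return(tibble(variable = v, type = "continuous",
                      summary_1 = .fmt_median_iqr(x1),
                      summary_2 = .fmt_median_iqr(x2), test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      statistic_corrected = NA_real_, p_corrected = NA_real_,
                      note = "group too small for a test"))
      }
      if (normal) {
        tt <- t.test(x1, x2, var.equal = TRUE)
        tibble(variable = v, type = "continuous",
               summary_1 = .fmt_mean_sd(x1), summary_2 = .fmt_mean_sd(x2),
               test = "t-test", statistic = unname(tt$statistic),
               p_value = tt$p.value, statistic_corrected = NA_real_,
               p_corrected = NA_real_, note = NA_character_)
      } else {
        wt <- suppressWarnings(wilcox.test(x1, x2))
        tibble(variable = v, type = "continuous",
               summary_1 = .fmt_median_iqr(x1),
               summary_2 = .fmt_median_iqr(x2),
               test = "mann-whitney", statistic = unname(wt$statistic),
               p_value = wt$p.value, statistic_corrected = NA_real_,
               p_corrected = NA_real_, note = NA_character_)
      }
    }
  })
}

#' Prevalence summary
#'
#' T2DM prevalence by sex, and MetS prevalence by sex within T2DM
#' status, with percentages rounded to one decimal for reporting and the
#' raw fractions retained. Empty strata yield an undefined percentage
#' and a flag instead of an error.
#'
#' @param data A data frame with columns `sex`, `t2dm` and `mets`.
#'
#' @return A tibble: `measure` ("t2dm" or "mets"), `sex`, `t2dm`
#'   (`NA` for the T2DM-prevalence rows), `n_events`, `n_total`,
#'   `fraction`, `pct`, `undefined`.
#' @export
prevalence_summary <- function(data) {
  check_required_columns(data, c("sex", "t2dm", "mets"), "data")
  sexes <- c("male", "female")
  t2dm_rows <- map_dfr(sexes, function(s) {
    den <- sum(data$sex == s)
    num <- sum(data$sex == s & data$t2dm)
    tibble(measure = "t2dm", sex = s, t2dm = NA, n_events = num,
           n_total = den, fraction = num / den,
           pct = round(100 * num / den, 1), undefined = den == 0)
  })
  mets_rows <- map_dfr(sexes, function(s) {
    map_dfr(c(TRUE, FALSE), function(dm) {
      den <- sum(data$sex == s & data$t2dm == dm)
      num <- sum(data$sex == s & data$t2dm == dm & data$mets)
      tibble(measure = "mets", sex = s, t2dm = dm, n_events = num,
             n_total = den, fraction = num / den,
             pct = round(100 * num / den, 1), undefined = den == 0)
    })
  })
  bind_rows(t2dm_rows, mets_rows)
}

# makes sure indices / t2dm / mets columns are present, deriving any
# that are missing from the raw measurements
.prepare_cohort <- function(data, criterion = "china2020") {
  if (!all(c("bmi", "vai", "cvai", "lap", "egfr") %in% names(data))) {
    data <- add_indices(data, check_ranges = FALSE)
  }
  if (!"t2dm" %in% names(data)) data <- classify_t2dm(data)
  if (!"mets" %in% names(data)) data <- classify_mets(data, criterion)
  data
}

#' Cut-off and adjusted odds-ratio table
#'
#' For every sex x T2DM stratum and predictor: the Youden-optimal
#' cut-off with sensitivity/specificity (percent), followed by the
#' Firth-adjusted odds ratio of the predictor (coded per
#' `config$mode`) with Wald 95% CI, adjusting for the configured
#' covariates. Strata with too few events (fewer than the number of
#' covariates plus 2), a single outcome class or a constant predictor
#' yield a diagnostics row instead of a fit.
#'
#' @param data A cohort; indices, `t2dm` and `mets` columns are derived
#'   if absent (MetS under `criterion`).
#' @param config A [study_config()].
#' @param criterion MetS definition for the outcome. Defaults to the
#'   first of `config$criteria`.
#'
#' @return A tibble: `sex`, `t2dm`, `predictor`, `n`, `n_events`,
#'   `cutoff`, `youden`, `sensitivity`, `specificity`, `or`, `or_low`,
#'   `or_high`, `p_value`, `mode`, `note`.
#' @export
cutoff_or_table <- function(data, config = study_config(),
                            criterion = config$criteria[1]) {
  data <- .prepare_cohort(data, criterion)
  check_required_columns(data, c(config$predictors, config$covariates,
                                 "sex", "t2dm", "mets"), "cohort")
  strata <- distinct(data, .data$sex, .data$t2dm) |>
    arrange(.data$sex, .data$t2dm)
  pmap(strata, function(sex, t2dm) {
    sub <- data[data$sex == sex & data$t2dm == t2dm, ]
    map_dfr(config$predictors, function(pred) {
      base <- tibble(
        sex = sex, t2dm = t2dm, predictor = pred, n = nrow(sub),
        n_events = sum(sub$mets), cutoff = NA_real_, youden = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_, or = NA_real_,
        or_low = NA_real_, or_high = NA_real_, p_value = NA_real_,
        mode = config$mode, note = NA_character_
      )
      scores <- sub[[pred]]
      if (length(unique(sub$mets)) < 2L) {
        base$note <- "single outcome class"
        return(base)
      }
      if (length(unique(scores)) < 2L) {
        base$note <- "constant predictor"
        return(base)
      }
      roc <- roc_curve(sub, !!rlang::sym(pred), "mets")
      cut <- optimal_cutoff(roc)
      base$cutoff <- cut$threshold
      base$youden <- cut$youden
      base$sensitivity <- cut$sensitivity
      base$specificity <- cut$specificity
      min_events <- min(sum(sub$mets), sum(!sub$mets))
      if (min_events < length(config$covariates) + 2L) {
        base$note <- "too few events for an adjusted model"
        return(base)
      }
      model_data <- sub[c("mets", config$covariates)]
      model_data$x <- if (config$mode == "binary") {
        as.numeric(scores >= cut$threshold)
      } else {
        scores
      }
      fml <- stats::as.formula(
        paste("mets ~ x +", paste(config$covariates, collapse = " + "))
      )
      fit <- tryCatch(
        fit_firth(model_data, fml, conf_level = config$conf_level),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        base$note <- "adjusted model did not converge"
        return(base)
      }
      td <- tidy(fit)
      xi <- which(td$term == "x")
      base$or <- exp(td$estimate[xi])
      base$or_low <- exp(td$conf.low[xi])
      base$or_high <- exp(td$conf.high[xi])
      base$p_value <- td$p.value[xi]
      if (fit$separation_suspected) base$note <- "separation suspected"
      base
    })
  }) |> list_rbind()
}

#' AUC table across criteria
#'
#' For every MetS definition in `config$criteria`, sex x T2DM stratum
#' and predictor: the AUC with DeLong 95% CI and the p-value against
#' AUC = 0.5. T2DM status is classified once; the MetS outcome is
#' re-derived per criterion. A `label_col` may be supplied to evaluate
#' against a precomputed outcome column instead (e.g. a planted truth),
#' in which case criteria classification is skipped.
#'
#' @inheritParams cutoff_or_table
#' @param label_col Optional name of an existing logical outcome column.
#'
#' @return A tibble: `criterion`, `sex`, `t2dm`, `predictor`, `n`,
#'   `auc`, `ci_low`, `ci_high`, `p_value`, `note`.
#' @export
auc_table <- function(data, config = study_config(), label_col = NULL) {
  if (!all(c("bmi", "vai", "cvai", "lap", "egfr") %in% names(data))) {
    data <- add_indices(data, check_ranges = FALSE)
  }
  if (!"t2dm" %in% names(data)) data <- classify_t2dm(data)
  criteria <- if (is.null(label_col)) config$criteria else "supplied"
  map_dfr(criteria, function(crit) {
    labelled <- if (is.null(label_col)) {
      d <- data
      d$mets <- diagnose_mets(mets_components(data, crit))$mets
      d
    } else {
      d <- data
      d$mets <- data[[label_col]]
      d
    }
    strata <- distinct(labelled, .data$sex, .data$t2dm) |>
      arrange(.data$sex, .data$t2dm)
    pmap(strata, function(sex, t2dm) {
      sub <- labelled[labelled$sex == sex & labelled$t2dm == t2dm, ]
      map_dfr(config$predictors, function(pred) {
        base <- tibble(criterion = crit, sex = sex, t2dm = t2dm,
                       predictor = pred, n = nrow(sub), auc = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       p_value = NA_real_, note = NA_character_)
        if (length(unique(sub$mets)) < 2L) {
          base$note <- "single outcome class"
          return(base)
        }
        a <- roc_auc(sub, !!rlang::sym(pred), "mets",
                     conf_level = config$conf_level)
        base$auc <- a$auc
        base$ci_low <- a$ci_low
        base$ci_high <- a$ci_high
        base$p_value <- a$p_value
        base
      })
    }) |> list_rbind()
  })
}

#' Run the full stratified study
#'
#' End-to-end orchestration: validates the cohort, derives the index
#' panel, classifies T2DM and MetS, and writes to `out_dir`:
#' `descriptive.csv` (MetS+/- comparisons within each sex x T2DM
#' stratum), `prevalence.csv`, `cutoff_or.csv` (cut-off/odds-ratio
#' analogue under the first configured criterion), `auc.csv` (all
#' criteria), per-stratum ROC plot PNGs (optional) and `manifest.json`
#' (configuration, seed, package and R versions). Output is
#' deterministic: identical cohort, config and seed give byte-identical
#' CSVs.
#'
#' @param cohort A subject-level cohort data frame (raw measurements).
#' @param config A [study_config()].
#' @param out_dir Output directory, created if needed.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents the provenance of the cohort).
#' @param write_plots Write ROC panels as PNGs. Default `TRUE`.
#'
#' @return Invisibly, a list with the result tibbles and file paths.
#' @export
run_study <- function(cohort, config = study_config(), out_dir,
                      seed = NULL, write_plots = TRUE) {
  check_required_columns(
    cohort,
    c("subject_id", "sex", "age", "weight", "height", "wc", "sbp", "dbp",
      "fbg", "tc", "tg", "hdl", "ldl", "creatinine"),
    "cohort"
  )
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  primary <- config$criteria[1]
  prepared <- .prepare_cohort(cohort, primary)

  desc_vars <- intersect(
    c("age", "bmi", "wc", "sbp", "dbp", "fbg", "tc", "tg", "hdl", "ldl",
      "egfr", "hemoglobin", "creatinine", "uric_acid", "vfa", "sfa",
      "vai", "cvai", "lap", "diagnosed_hypertension"),
    names(prepared)
  )
  strata <- distinct(prepared, .data$sex, .data$t2dm) |>
    arrange(.data$sex, .data$t2dm)
  descriptive <- pmap(strata, function(sex, t2dm) {
    sub <- prepared[prepared$sex == sex & prepared$t2dm == t2dm, ]
    if (length(unique(sub$mets)) < 2L) return(NULL)
    descriptive_table(sub, "mets", desc_vars, alpha = config$alpha) |>
      mutate(sex = sex, t2dm = t2dm, .before = 1)
  }) |> list_rbind()

  prevalence <- prevalence_summary(prepared)
  table3 <- cutoff_or_table(prepared, config, criterion = primary)
  table4 <- auc_table(prepared, config)

  paths <- list(
    descriptive = file.path(out_dir, "descriptive.csv"),
    prevalence = file.path(out_dir, "prevalence.csv"),
    cutoff_or = file.path(out_dir, "cutoff_or.csv"),
    auc = file.path(out_dir, "auc.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(descriptive, paths$descriptive)
  readr::write_csv(prevalence, paths$prevalence)
  readr::write_csv(table3, paths$cutoff_or)
  readr::write_csv(table4, paths$auc)

  if (write_plots) {
    pmap(strata, function(sex, t2dm) {
      sub <- prepared[prepared$sex == sex & prepared$t2dm == t2dm, ]
      if (length(unique(sub$mets)) < 2L) return(NULL)
      p <- plot_roc_panel(sub, config$predictors, "mets") +
        ggplot2::ggtitle(sprintf("%s, %s T2DM", sex,
                                 if (t2dm) "with" else "without"))
      ggplot2::ggsave(
        file.path(out_dir, sprintf("roc_%s_t2dm_%d.png", sex, as.integer(t2dm))),
        p, width = 5, height = 5, dpi = 150
      )
      NULL
    })
  }

  manifest <- list(
    package = "metsindex",
    package_version = as.character(packageVersion("metsindex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    n_subjects = nrow(prepared),
    config = list(
      predictors = config$predictors, covariates = config$covariates,
      criteria = config$criteria, mode = config$mode,
      alpha = config$alpha, conf_level = config$conf_level,
      normality_test = "shapiro-wilk"
    )
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(descriptive = descriptive, prevalence = prevalence,
                 cutoff_or = table3, auc = table4, paths = paths))
}

#' ROC panel for several predictors
#'
#' Overlays the ROC curves of several predictor columns against one
#' outcome column.
#'
#' @param data A data frame.
#' @param predictors Character vector of score columns.
#' @param label_col Name of the logical outcome column.
#'
#' @return A ggplot.
#' @export
plot_roc_panel <- function(data, predictors, label_col = "mets") {
  check_required_columns(data, c(predictors, label_col), "data")
  curves <- map_dfr(predictors, function(pred) {
    roc <- roc_curve(data, !!rlang::sym(pred), !!rlang::sym(label_col))
    tibble(predictor = pred, fpr = 1 - roc$specificity,
           tpr = roc$sensitivity)
  })
  curves <- arrange(curves, .data$predictor, .data$fpr, .data$tpr)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$predictor)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Index") +
    ggplot2::theme_minimal()
}
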