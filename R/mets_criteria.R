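#' Metabolic syndrome criterion definitions
#'
#' Declarative threshold sets for the three supported metabolic syndrome
#' definitions. Each definition lists, per component, the cut-point and
#' its direction, so alternate guideline revisions can be plugged in by
#' supplying a modified list to [mets_components()].
#'
#' * `china2020` — Chinese type 2 diabetes guideline (2020 edition):
#'   WC >= 90 (M) / >= 85 (F) cm; fasting glucose >= 6.1 mmol/L or
#'   treated diagnosed diabetes; BP >= 130/85 mmHg or treated
#'   hypertension; TG >= 1.70 mmol/L; HDL < 1.04 mmol/L (both sexes).
#'   MetS when >= 3 of 5 components are present.
#' * `atpiii` — revised NCEP-ATPIII: WC >= 90 (M) / >= 80 (F) cm;
#'   TG >= 1.7; HDL < 1.03 (M) / < 1.29 (F); BP >= 130/85 or
#'   antihypertensive use; fasting glucose >= 5.6 or diagnosed diabetes.
#'   MetS when >= 3 of 5.
#' * `idf` — International Diabetes Federation: central obesity is
#'   mandatory (ethnic-specific WC >= 90 (M) / >= 80 (F) cm for Chinese
#'   populations) plus >= 2 of the remaining four components, whose
#'   cut-points match the revised ATPIII set.
#'
#' @param criterion One of `"china2020"`, `"atpiii"`, `"idf"`.
#' @return A list with elements `criterion`, `wc_male`, `wc_female`,
#'   `fbg`, `tg`, `hdl_male`, `hdl_female`, `sbp`, `dbp`,
#'   `obesity_mandatory`.
#' @export
mets_criterion_defs <- function(criterion = c("china2020", "atpiii", "idf")) {
  criterion <- match.arg(criterion)
  switch(
    criterion,
    china2020 = list(
      criterion = "china2020",
      wc_male = 90, wc_female = 85,
      fbg = 6.1, tg = 1.70,
      hdl_male = 1.04, hdl_female = 1.04,
      sbp = 130, dbp = 85,
      obesity_mandatory = FALSE
    ),
    atpiii = list(
      criterion = "atpiii",
      wc_male = 90, wc_female = 80,
      fbg = 5.6, tg = 1.7,
      hdl_male = 1.03, hdl_female = 1.29,
      sbp = 130, dbp = 85,
      obesity_mandatory = FALSE
    ),
    idf = list(
      criterion = "idf",
      wc_male = 90, wc_female = 80,
      fbg = 5.6, tg = 1.7,
      hdl_male = 1.03, hdl_female = 1.29,
      sbp = 130, dbp = 85,
      obesity_mandatory = TRUE
    )
  )
}

# returns a logical column, defaulting to FALSE when absent
.flag_col <- function(data, col) {
  if (col %in% names(data)) {
    x <- data[[col]]
    if (!is.logical(x)) x <- as.logical(x)
    x
  } else {
    rep(NA, nrow(data))
  }
}

#' Classify type 2 diabetes
#'
#' A subject is classified T2DM when previously diagnosed, using insulin
#' or hypoglycemic drugs, or with fasting blood glucose >= 7.0 mmol/L
#' (inclusive).
#'
#' @param data A data frame with columns `fbg` (mmol/L) and/or the flags
#'   `diagnosed_t2dm`, `glucose_lowering_meds`.
#'
#' @return The input as a tibble with a logical `t2dm` column appended.
#' @export
classify_t2dm <- function(data) {
  diagnosed <- .flag_col(data, "diagnosed_t2dm")
  meds <- .flag_col(data, "glucose_lowering_meds")
  fbg <- if ("fbg" %in% names(data)) data[[ "fbg" ]] else rep(NA_real_, nrow(data))
  none <- is.na(diagnosed) & is.na(meds) & is.na(fbg)
  if (any(none)) {
    abort(
      sprintf(
        "T2DM status indeterminate (no diagnosis flag, medication flag or fasting glucose) for subject%s %s.",
        if (sum(none) > 1L) "s" else "",
        paste(utils::head(subject_labels(data, which(none)), 5L), collapse = ", ")
      ),
      class = "metsindex_indeterminate"
    )
  }
  out <- as_tibble(data)
  out$t2dm <- (!is.na(diagnosed) & diagnosed) |
    (!is.na(meds) & meds) |
    (!is.na(fbg) & fbg >= 7.0)
  out
}

#' Metabolic syndrome component flags
#'
#' Evaluates the five components of the chosen definition for each
#' subject. Blood pressure `>= 130/85` is read as SBP >= 130 **or**
#' DBP >= 85. Treated hypertension (`diagnosed_hypertension` together
#' with `antihypertensive_meds`) satisfies the blood-pressure component
#' under china2020; antihypertensive use alone satisfies it under
#' atpiii/idf. Diagnosed-and-treated diabetes satisfies the china2020
#' hyperglycemia component; a diabetes diagnosis alone satisfies it under
#' atpiii/idf. Lipid-lowering treatment is not used as a surrogate for
#' the TG or HDL components.
#'
#' @param data A data frame with columns `sex`, `wc`, `fbg`, `sbp`,
#'   `dbp`, `tg`, `hdl` and (optionally) the flags `diagnosed_t2dm`,
#'   `glucose_lowering_meds`, `diagnosed_hypertension`,
#'   `antihypertensive_meds`. Missing flags are treated as `FALSE`.
#' @param criterion Definition name, see [mets_criterion_defs()].
#' @param defs Optional full definition list overriding `criterion`.
#'
#' @return A tibble with logical columns `central_obesity`,
#'   `hyperglycemia`, `elevated_bp`, `elevated_tg`, `low_hdl` and a
#'   `criterion` column.
#' @export
mets_components <- function(data, criterion = c("china2020", "atpiii", "idf"),
                            defs = NULL) {
  defs <- defs %||% mets_criterion_defs(criterion)
  required <- c("sex", "wc", "fbg", "sbp", "dbp", "tg", "hdl")
  check_required_columns(data, required, "cohort")
  incomplete <- !complete.cases(data[required])
  if (any(incomplete)) {
    rows <- which(incomplete)
    fields <- required[vapply(data[required], anyNA, logical(1))]
    abort(
      sprintf(
        "MetS components indeterminate: missing %s for subject%s %s.",
        paste(fields, collapse = ", "),
        if (length(rows) > 1L) "s" else "",
        paste(utils::head(subject_labels(data, rows), 5L), collapse = ", ")
      ),
      class = "metsindex_indeterminate"
    )
  }
  sex <- check_sex(data$sex)
  male <- sex == "male"
  dm_diag <- .flag_col(data, "diagnosed_t2dm")
  dm_meds <- .flag_col(data, "glucose_lowering_meds")
  ht_diag <- .flag_col(data, "diagnosed_hypertension")
  ht_meds <- .flag_col(data, "antihypertensive_meds")
  dm_diag[is.na(dm_diag)] <- FALSE
  dm_meds[is.na(dm_meds)] <- FALSE
  ht_diag[is.na(ht_diag)] <- FALSE
  ht_meds[is.na(ht_meds)] <- FALSE

  hyperglycemia_flag <- if (defs$criterion == "china2020") {
    dm_diag & dm_meds
  } else {
    dm_diag
  }
  bp_flag <- if (defs$criterion == "china2020") {
    ht_diag & ht_meds
  } else {
    ht_meds
  }

  tibble(
    central_obesity = if_else(male, data$wc >= defs$wc_male,
                              data$wc >= defs$wc_female),
    hyperglycemia = data$fbg >= defs$fbg | hyperglycemia_flag,
    elevated_bp = data$sbp >= defs$sbp | data$dbp >= defs$dbp | bp_flag,
    elevated_tg = data$tg >= defs$tg,
    low_hdl = if_else(male, data$hdl < defs$hdl_male,
                      data$hdl < defs$hdl_female),
    criterion = defs$criterion
  )
}

#' Combine component flags into a metabolic syndrome diagnosis
#'
#' Applies the criterion-specific combination rule: at least 3 of the 5
#' components for china2020 and atpiii; central obesity plus at least 2
#' of the remaining four for idf. `n_positive` always counts all five
#' flags.
#'
#' @param components A tibble as returned by [mets_components()] (five
#'   component columns plus `criterion`).
#'
#' @return The input with integer `n_positive` and logical `mets`
#'   appended.
#' @export
diagnose_mets <- function(components) {
  flags <- c("central_obesity", "hyperglycemia", "elevated_bp",
             "elevated_tg", "low_hdl")
  check_required_columns(components, c(flags, "criterion"), "components")
  flag_mat <- as.matrix(as.data.frame(components[flags]))
  storage.mode(flag_mat) <- "logical"
  n_positive <- as.integer(rowSums(flag_mat))
  mandatory <- vapply(components$criterion,
                      function(cr) mets_criterion_defs(cr)$obesity_mandatory,
                      logical(1))
  mets <- if_else(
    mandatory,
    components$central_obesity & (n_positive - components$central_obesity) >= 2L,
    n_positive >= 3L
  )
  out <- as_tibble(components)
  out$n_positive <- n_positive
  out$mets <- mets
  out
}

#' Classify metabolic syndrome for a cohort
#'
#' Convenience wrapper: evaluates components with [mets_components()] and
#' the diagnosis with [diagnose_mets()], returning the cohort with the
#' audit-trail columns appended.
#'
#' @inheritParams mets_components
#'
#' @return The input as a tibble with columns `central_obesity`,
#'   `hyperglycemia`, `elevated_bp`, `elevated_tg`, `low_hdl`,
#'   `criterion`, `n_positive` and `mets` appended.
#' @export
classify_mets <- function(data, criterion = c("china2020", "atpiii", "idf"),
                          defs = NULL) {
  comp <- diagnose_mets(mets_components(data, criterion, defs))
  bind_cols(as_tibble(data), comp)
}
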