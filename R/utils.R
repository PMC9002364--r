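# internal validation helpers

check_numeric_positive <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", name), class = "metsindex_domain_error")
  }
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    abort(
      sprintf(
        "`%s` must be strictly positive (offending value%s: %s).",
        name, if (sum(bad) > 1L) "s" else "",
        paste(format(utils::head(x[bad], 5L)), collapse = ", ")
      ),
      class = "metsindex_domain_error"
    )
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` contains missing values.", name),
          class = "metsindex_domain_error")
  }
  invisible(x)
}

# normalizes sex coding to "male"/"female"; errors on anything else
check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  ok <- sex %in% c("male", "female")
  if (anyNA(sex) || !all(ok)) {
    bad <- unique(sex[!ok | is.na(sex)])
    abort(
      sprintf("`sex` must be \"male\" or \"female\" (got: %s).",
              paste(bad, collapse = ", ")),
      class = "metsindex_domain_error"
    )
  }
  sex
}

check_required_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(
      sprintf("%s is missing required column%s: %s.",
              what, if (length(missing) > 1L) "s" else "",
              paste(missing, collapse = ", ")),
      class = "metsindex_missing_column"
    )
  }
  invisible(data)
}

# subject ids for error context; falls back to row numbers
subject_labels <- function(data, idx) {
  if ("subject_id" %in% names(data)) {
    as.character(data$subject_id[idx])
  } else {
    paste0("row ", idx)
  }
}
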