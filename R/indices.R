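#' Body mass index
#'
#' @param weight Body weight in kilograms.
#' @param height Standing height in metres.
#'
#' @return BMI in kg/m^2, vectorised over the inputs.
#' @examples
#' compute_bmi(81, 1.80)
#' @export
compute_bmi <- function(weight, height) {
  check_numeric_positive(weight, "weight")
  check_numeric_positive(height, "height")
  weight / height^2
}

# sex-specific constants of the VAI formula
.vai_const <- list(
  male   = c(a = 39.68, b = 1.88, tg0 = 1.03, hdl0 = 1.31),
  female = c(a = 36.58, b = 1.89, tg0 = 0.81, hdl0 = 1.52)
)

#' Visceral adiposity index (VAI)
#'
#' Sex-specific composite of waist circumference, BMI, triglycerides and
#' HDL cholesterol estimating visceral adipose dysfunction:
#' `WC / (a + b * BMI) * (TG / tg0) * (hdl0 / HDL)` with constants
#' (39.68, 1.88, 1.03, 1.31) for men and (36.58, 1.89, 0.81, 1.52) for
#' women.
#'
#' @param sex "male" or "female" (recycled or per-subject vector).
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m^2.
#' @param tg Fasting triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#'
#' @return VAI, dimensionless and strictly positive for valid inputs.
#' @examples
#' compute_vai("male", wc = 90, bmi = 26.6, tg = 2.06, hdl = 0.88)
#' @export
compute_vai <- function(sex, wc, bmi, tg, hdl) {
  sex <- check_sex(sex)
  check_numeric_positive(wc, "wc")
  check_numeric_positive(bmi, "bmi")
  check_numeric_positive(tg, "tg")
  check_numeric_positive(hdl, "hdl")
  male <- sex == "male"
  a    <- if_else(male, .vai_const$male[["a"]],    .vai_const$female[["a"]])
  b    <- if_else(male, .vai_const$male[["b"]],    .vai_const$female[["b"]])
  tg0  <- if_else(male, .vai_const$male[["tg0"]],  .vai_const$female[["tg0"]])
  hdl0 <- if_else(male, .vai_const$male[["hdl0"]], .vai_const$female[["hdl0"]])
  wc / (a + b * bmi) * (tg / tg0) * (hdl0 / hdl)
}

#' Chinese visceral adiposity index (CVAI)
#'
#' Linear visceral-adiposity score calibrated in Chinese populations:
#' for men `-267.93 + age + 0.03*BMI + 4.00*WC + 22.00*log10(TG) -
#' 16.32*HDL`, for women `-187.32 + age + 4.32*BMI + 1.12*WC +
#' 39.76*log10(TG) - 11.66*HDL`. May be negative.
#'
#' @inheritParams compute_vai
#' @param age Age in years.
#'
#' @return CVAI, dimensionless.
#' @examples
#' compute_cvai("male", age = 50, bmi = 25, wc = 90, tg = 1.7, hdl = 1)
#' @export
compute_cvai <- function(sex, age, bmi, wc, tg, hdl) {
  sex <- check_sex(sex)
  check_numeric_positive(age, "age")
  check_numeric_positive(bmi, "bmi")
  check_numeric_positive(wc, "wc")
  check_numeric_positive(tg, "tg")
  check_numeric_positive(hdl, "hdl")
  male <- sex == "male"
  if_else(
    male,
    -267.93 + age + 0.03 * bmi + 4.00 * wc + 22.00 * log10(tg) - 16.32 * hdl,
    -187.32 + age + 4.32 * bmi + 1.12 * wc + 39.76 * log10(tg) - 11.66 * hdl
  )
}

#' Lipid accumulation product (LAP)
#'
#' `(WC - 65) * TG` for men and `(WC - 58) * TG` for women. Non-positive
#' values arise when WC does not exceed the sex offset; they are retained
#' (downstream ROC analysis accepts any real score) and flagged by
#' [add_indices()].
#'
#' @inheritParams compute_vai
#'
#' @return LAP, dimensionless; may be non-positive.
#' @examples
#' compute_lap("male", wc = 90, tg = 2.06)
#' @export
compute_lap <- function(sex, wc, tg) {
  sex <- check_sex(sex)
  check_numeric_positive(wc, "wc")
  check_numeric_positive(tg, "tg")
  offset <- if_else(sex == "male", 65, 58)
  (wc - offset) * tg
}

#' CKD-EPI estimated glomerular filtration rate (2009 creatinine equation)
#'
#' Serum creatinine supplied in umol/L is converted internally to mg/dL
#' (division by 88.4). The equation is
#' `141 * min(Scr/k, 1)^alpha * max(Scr/k, 1)^-1.209 * 0.993^age *
#' 1.018[female]` with `k = 0.7` and `alpha = -0.329` for women, `k = 0.9`
#' and `alpha = -0.411` for men. The race coefficient (1.159) is excluded
#' by default.
#'
#' @inheritParams compute_cvai
#' @param creatinine Serum creatinine, umol/L.
#' @param black Apply the 1.159 race coefficient of the original 2009
#'   equation. Default `FALSE`.
#'
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr_ckdepi("female", age = 50, creatinine = 61.88)
#' @export
compute_egfr_ckdepi <- function(sex, age, creatinine, black = FALSE) {
  sex <- check_sex(sex)
  check_numeric_positive(age, "age")
  check_numeric_positive(creatinine, "creatinine")
  scr <- creatinine / 88.4
  female <- sex == "female"
  kappa <- if_else(female, 0.7, 0.9)
  alpha <- if_else(female, -0.329, -0.411)
  egfr <- 141 *
    pmin(scr / kappa, 1)^alpha *
    pmax(scr / kappa, 1)^(-1.209) *
    0.993^age *
    if_else(female, 1.018, 1)
  if (isTRUE(black)) egfr <- egfr * 1.159
  egfr
}

# plausibility ranges used for soft guard rails (warnings, not errors)
.range_guards <- list(
  bmi        = c(10, 60),
  wc         = c(40, 200),
  height     = c(1.2, 2.2),
  creatinine = c(20, 3000)
)

#' Derive the index panel for a cohort
#'
#' Appends BMI, VAI, CVAI, LAP (with a non-positivity flag) and CKD-EPI
#' eGFR to a subject-level cohort. Waist circumference and fat areas are
#' carried through unchanged. Values outside broad physiologic ranges
#' (BMI 10-60 kg/m^2, WC 40-200 cm, height 1.2-2.2 m) trigger warnings
#' naming the subjects, never errors, so that synthetic extremes remain
#' testable; set `check_ranges = FALSE` to silence them.
#'
#' @param data A data frame with one row per subject and columns
#'   `sex`, `age`, `weight`, `height`, `wc`, `tg`, `hdl`, `creatinine`.
#' @param black Passed to [compute_egfr_ckdepi()].
#' @param check_ranges Emit range warnings. Default `TRUE`.
#'
#' @return The input as a tibble with columns `bmi`, `vai`, `cvai`,
#'   `lap`, `lap_nonpositive` and `egfr` appended.
#' @examples
#' cohort <- tibble::tibble(
#'   subject_id = "s1", sex = "male", age = 50, weight = 81, height = 1.8,
#'   wc = 90, tg = 2.06, hdl = 0.88, creatinine = 100
#' )
#' add_indices(cohort)
#' @export
add_indices <- function(data, black = FALSE, check_ranges = TRUE) {
  check_required_columns(
    data,
    c("sex", "age", "weight", "height", "wc", "tg", "hdl", "creatinine"),
    "cohort"
  )
  for (col in c("age", "weight", "height", "wc", "tg", "hdl", "creatinine")) {
    x <- data[[col]]
    bad <- is.na(x) | (is.numeric(x) & x <= 0)
    if (!is.numeric(x) || any(bad)) {
      abort(
        sprintf(
          "Column `%s` must be strictly positive and non-missing (subjects: %s).",
          col,
          paste(utils::head(subject_labels(data, which(bad)), 5L), collapse = ", ")
        ),
        class = "metsindex_domain_error"
      )
    }
  }
  out <- as_tibble(data)
  out$sex <- check_sex(out$sex)
  out$bmi <- compute_bmi(out$weight, out$height)
  if (check_ranges) {
    guard_cols <- c(bmi = "bmi", wc = "wc", height = "height",
                    creatinine = "creatinine")
    for (nm in names(guard_cols)) {
      rng <- .range_guards[[nm]]
      x <- out[[guard_cols[[nm]]]]
      off <- which(x < rng[1] | x > rng[2])
      if (length(off) > 0L) {
        warn(sprintf(
          "`%s` outside the plausible range [%g, %g] for subject%s %s.",
          nm, rng[1], rng[2], if (length(off) > 1L) "s" else "",
          paste(utils::head(subject_labels(out, off), 5L), collapse = ", ")
        ))
      }
    }
  }
  out$vai <- compute_vai(out$sex, out$wc, out$bmi, out$tg, out$hdl)
  out$cvai <- compute_cvai(out$sex, out$age, out$bmi, out$wc, out$tg, out$hdl)
  out$lap <- compute_lap(out$sex, out$wc, out$tg)
  out$lap_nonpositive <- out$lap <= 0
  out$egfr <- compute_egfr_ckdepi(out$sex, out$age, out$creatinine,
                                  black = black)
  out
}
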