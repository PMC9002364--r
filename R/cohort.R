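# marginal-distribution constructors used by the cohort spec
.n_ <- function(mean, sd) list(dist = "normal", mean = mean, sd = sd)
.ln_ <- function(median, q1, q3) list(dist = "lognormal", median = median,
                                      q1 = q1, q3 = q3)

#' Default synthetic cohort specification
#'
#' Encodes the eight sex x T2DM x MetS strata of the reference CKD
#' cohort (total n = 537: 372 men, 165 women) with the published
#' per-stratum marginal summaries: variables reported as mean +/- SD are
#' modelled as normal, variables reported as median (IQR) as lognormal
#' with parameters matched by quantile (log-median and log-IQR). Raw
#' measurements (WC, TG, HDL, ...) are sampled, never the derived
#' indices, so the index calculators are genuinely exercised downstream.
#' Adiposity-related variables (BMI, WC, VFA, SFA, TG) share an
#' exchangeable Spearman rank correlation (default 0.3) through a
#' Gaussian copula; this correlation is an assumption, not a published
#' quantity. Heights are drawn from sex-specific normals and weight is
#' back-computed from the sampled BMI.
#'
#' @param copula_rho Target exchangeable Spearman correlation among the
#'   adiposity variables. Default 0.3.
#'
#' @return An object of class `cohort_spec`: a list with `strata`
#'   (tibble of stratum sizes and flag prevalences), `params` (marginal
#'   parameters per stratum and variable), `copula_vars`, `copula_rho`,
#'   `glucose_meds_prev` and `height`.
#' @export
default_cohort_spec <- function(copula_rho = 0.3) {
  strata <- tibble(
    stratum_id = c("m_dm0_mets0", "m_dm0_mets1", "m_dm1_mets0", "m_dm1_mets1",
                   "f_dm0_mets0", "f_dm0_mets1", "f_dm1_mets0", "f_dm1_mets1"),
    sex = rep(c("male", "female"), each = 4),
    t2dm = rep(c(FALSE, FALSE, TRUE, TRUE), 2),
    mets = rep(c(FALSE, TRUE), 4),
    n = c(79L, 79L, 42L, 172L, 69L, 26L, 11L, 59L),
    hypertension = c(0.481, 0.810, 0.786, 0.942, 0.580, 0.885, 0.545, 0.898)
  )
  params <- list(
    m_dm0_mets0 = list(
      age = .n_(41.05, 14.86), bmi = .ln_(23.9, 21.6, 25.9),
      wc = .n_(81.33, 8.53), sbp = .n_(124.8, 13.29), dbp = .n_(74.82, 9.49),
      fbg = .ln_(4.48, 4.17, 4.74), tc = .ln_(4.21, 3.49, 4.83),
      tg = .ln_(1.37, 1.07, 1.75), hdl = .ln_(1.16, 0.93, 1.41),
      ldl = .ln_(2.75, 2.15, 3.14), creatinine = .ln_(107.6, 80.9, 159.3),
      uric_acid = .n_(404.28, 100.38), hemoglobin = .n_(127.15, 20.55),
      vfa = .n_(79.54, 30.23), sfa = .ln_(174, 130, 204)
    ),
    m_dm0_mets1 = list(
      age = .n_(45.58, 15.59), bmi = .ln_(27.3, 25.1, 29.8),
      wc = .n_(93.01, 9.33), sbp = .n_(133.54, 14.29), dbp = .n_(80.72, 11.09),
      fbg = .ln_(4.56, 4.3, 5.45), tc = .ln_(4.19, 3.65, 5.18),
      tg = .ln_(2.41, 1.91, 3.22), hdl = .ln_(0.86, 0.76, 0.98),
      ldl = .ln_(2.55, 1.98, 3.22), creatinine = .ln_(135.8, 107.1, 192),
      uric_acid = .n_(434.56, 113.14), hemoglobin = .n_(131.43, 22.45),
      vfa = .n_(134.58, 41.27), sfa = .ln_(235, 205, 276)
    ),
    m_dm1_mets0 = list(
      age = .n_(57.36, 8.36), bmi = .ln_(22.85, 21.45, 25.63),
      wc = .ln_(81, 75, 85.5), sbp = .n_(149.55, 24.67), dbp = .n_(84.74, 12.41),
      fbg = .ln_(5.32, 4.46, 6.71), tc = .ln_(3.94, 3.31, 4.99),
      tg = .ln_(1.17, 0.95, 1.32), hdl = .ln_(1.24, 1.12, 1.39),
      ldl = .ln_(2.53, 1.91, 3.53), creatinine = .ln_(147.15, 81.83, 275.2),
      uric_acid = .n_(381.28, 99.64), hemoglobin = .n_(115.36, 22.35),
      vfa = .ln_(64, 43, 99), sfa = .ln_(141, 115, 184)
    ),
    m_dm1_mets1 = list(
      age = .n_(53.56, 10.57), bmi = .ln_(26.6, 24.46, 28.7),
      wc = .ln_(90, 83, 95), sbp = .n_(152.99, 22.83), dbp = .n_(89.52, 12.64),
      fbg = .ln_(5.61, 4.69, 6.89), tc = .ln_(4.44, 3.58, 5.61),
      tg = .ln_(2.06, 1.55, 2.96), hdl = .ln_(0.88, 0.75, 1.02),
      ldl = .ln_(2.62, 1.97, 3.48), creatinine = .ln_(159.55, 94.68, 285.93),
      uric_acid = .n_(420.95, 113.17), hemoglobin = .n_(122.39, 25.146),
      vfa = .ln_(119, 90, 148), sfa = .ln_(204, 168, 239)
    ),
    f_dm0_mets0 = list(
      age = .n_(46.26, 11.89), bmi = .n_(22.91, 3.78),
      wc = .ln_(76, 70, 81.5), sbp = .ln_(119, 108, 135),
      dbp = .ln_(76, 68.5, 83.5), fbg = .ln_(4.43, 4.03, 4.78),
      tc = .ln_(4.85, 4.15, 5.59), tg = .ln_(1.53, 1.17, 2.17),
      hdl = .ln_(1.37, 1.17, 1.65), ldl = .ln_(2.95, 2.48, 3.67),
      creatinine = .ln_(112.2, 68.5, 165.65), uric_acid = .n_(349.19, 96.79),
      hemoglobin = .n_(112.58, 15.83), vfa = .n_(66.22, 27.63),
      sfa = .ln_(149, 102.5, 199.5)
    ),
    f_dm0_mets1 = list(
      age = .n_(49.35, 13.28), bmi = .n_(26.16, 3.94),
      wc = .ln_(88.5, 80.75, 91.25), sbp = .ln_(129, 118.5, 139),
      dbp = .ln_(78, 71.5, 88.25), fbg = .ln_(4.57, 4.13, 4.87),
      tc = .ln_(4.34, 3.44, 5.15), tg = .ln_(2.39, 1.81, 3.39),
      hdl = .ln_(0.91, 0.87, 1.09), ldl = .ln_(2.69, 1.74, 3.45),
      creatinine = .ln_(159.75, 116.55, 215.63), uric_acid = .n_(382.84, 92.22),
      hemoglobin = .n_(108.12, 16.47), vfa = .n_(92.19, 31.32),
      sfa = .ln_(217.5, 162.75, 263.75)
    ),
    f_dm1_mets0 = list(
      age = .n_(56.82, 10.69), bmi = .n_(23.31, 2.65),
      wc = .n_(77.64, 6.31), sbp = .n_(134.55, 23.36), dbp = .n_(77.64, 12.53),
      fbg = .ln_(5.35, 4.79, 7.03), tc = .ln_(4.2, 3.77, 4.83),
      tg = .ln_(1.2, 1, 1.64), hdl = .ln_(1.26, 1.07, 1.54),
      ldl = .ln_(2.71, 2.14, 3.23), creatinine = .ln_(89.9, 59.1, 128.5),
      uric_acid = .ln_(348, 233.4, 385.6), hemoglobin = .n_(117.09, 18.43),
      vfa = .ln_(51, 34, 82), sfa = .n_(151.45, 56.73)
    ),
    f_dm1_mets1 = list(
      age = .n_(58.86, 9.11), bmi = .n_(26.06, 3.75),
      wc = .n_(87.19, 7.95), sbp = .n_(151.9, 24.07), dbp = .n_(85.63, 11.69),
      fbg = .ln_(5.91, 4.94, 7.1), tc = .ln_(5.11, 4.07, 6.17),
      tg = .ln_(2.43, 1.83, 3.72), hdl = .ln_(1.04, 0.85, 1.18),
      ldl = .ln_(3.02, 2.1, 3.96), creatinine = .ln_(103.5, 70.8, 156.3),
      uric_acid = .ln_(358.6, 287.7, 441.1), hemoglobin = .n_(115.71, 20.86),
      vfa = .ln_(99, 86.5, 119), sfa = .n_(204.26, 60.57)
    )
  )
  spec <- structure(
    list(
      strata = strata,
      params = params,
      copula_vars = c("bmi", "wc", "vfa", "sfa", "tg"),
      copula_rho = copula_rho,
      glucose_meds_prev = 0.8,
      height = list(male = c(mean = 1.72, sd = 0.06),
                    female = c(mean = 1.60, sd = 0.055))
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks stratum sizes, marginal parameters (positive SDs, ordered
#' quartiles) and positive-definiteness of the exchangeable copula
#' correlation, raising errors that name the offending stratum and
#' variable.
#'
#' @param spec A `cohort_spec`.
#' @return The spec, invisibly.
#' @export
validate_cohort_spec <- function(spec) {
  if (any(spec$strata$n < 0)) {
    abort("stratum sizes must be non-negative.", class = "metsindex_spec_error")
  }
  k <- length(spec$copula_vars)
  if (spec$copula_rho <= -1 / (k - 1) || spec$copula_rho >= 1) {
    abort("copula correlation is not positive definite for this dimension.",
          class = "metsindex_spec_error")
  }
  for (sid in names(spec$params)) {
    for (v in names(spec$params[[sid]])) {
      p <- spec$params[[sid]][[v]]
      if (p$dist == "normal" && p$sd <= 0) {
        abort(sprintf("non-positive sd for %s in stratum %s.", v, sid),
              class = "metsindex_spec_error")
      }
      if (p$dist == "lognormal" &&
          !(p$q1 > 0 && p$q1 < p$median && p$median < p$q3)) {
        abort(sprintf("quartiles not ordered for %s in stratum %s.", v, sid),
              class = "metsindex_spec_error")
      }
    }
  }
  invisible(spec)
}

# quantile transform from a standard-normal latent to the marginal
.latent_to_marginal <- function(z, p) {
  if (p$dist == "normal") {
    p$mean + p$sd * z
  } else {
    meanlog <- log(p$median)
    sdlog <- (log(p$q3) - log(p$q1)) / (2 * qnorm(0.75))
    exp(meanlog + sdlog * z)
  }
}

# one batch of k subjects from a stratum's continuous marginals
.draw_stratum <- function(k, pars, copula_vars, rho_latent) {
  vars <- names(pars)
  cvars <- intersect(copula_vars, vars)
  z <- matrix(rnorm(k * length(vars)), nrow = k,
              dimnames = list(NULL, vars))
  if (length(cvars) > 1L && rho_latent != 0) {
    R <- matrix(rho_latent, length(cvars), length(cvars))
    diag(R) <- 1
    z[, cvars] <- matrix(rnorm(k * length(cvars)), nrow = k) %*% chol(R)
  }
  out <- lapply(vars, function(v) .latent_to_marginal(z[, v], pars[[v]]))
  names(out) <- vars
  as_tibble(out)
}

# physiologic guard rails; rows failing are redrawn
.guard_bad <- function(d, t2dm) {
  bad <- d$age < 18 | d$wc < 40 | d$wc > 200 |
    d$sbp < 70 | d$sbp > 260 | d$dbp < 40 | d$dbp > 160 |
    d$bmi < 10 | d$bmi > 60 | d$fbg < 2 |
    d$vfa <= 0 | d$vfa > 400 | d$sfa <= 0 | d$sfa > 600 |
    d$hemoglobin < 40 | d$uric_acid < 50 | d$creatinine < 20 |
    d$height < 1.3 | d$height > 2.1
  if (!t2dm) bad <- bad | d$fbg >= 7 # non-diabetic strata stay below the T2DM glucose rule
  bad
}

#' Generate a synthetic CKD cohort
#'
#' Draws subject records stratum by stratum from a [default_cohort_spec()]
#' (or a modified spec): continuous variables come from a Gaussian
#' copula with the spec's rank correlation among adiposity variables,
#' transformed to the per-variable marginal; diagnosis and medication
#' flags are Bernoulli at the spec prevalences; ages are rounded to
#' whole years. Physiologic guard rails (age >= 18, positive
#' measurements, fasting glucose < 7 mmol/L in non-diabetic strata, ...)
#' are enforced by redrawing offending rows, up to `max_attempts`
#' rounds, after which an error names the stratum. Per-stratum sizes are
#' exact and output is deterministic given `seed`.
#'
#' @param spec A `cohort_spec`. Default [default_cohort_spec()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param max_attempts Redraw rounds for guard-rail violations.
#'
#' @return A tibble of subject records: identifiers, sex, age, weight,
#'   height, waist circumference, blood pressures, fasting glucose,
#'   lipids, creatinine, uric acid, hemoglobin, fat areas, flags
#'   (`diagnosed_t2dm`, `glucose_lowering_meds`,
#'   `diagnosed_hypertension`, `antihypertensive_meds`, `ckd`), and the
#'   generating stratum labels `stratum_t2dm`, `stratum_mets`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = NULL,
                            max_attempts = 100) {
  validate_cohort_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  # latent correlation chosen so the *Spearman* correlation hits the target
  rho_latent <- 2 * sin(pi * spec$copula_rho / 6)

  strata_rows <- purrr::pmap(spec$strata, function(stratum_id, sex, t2dm,
                                                   mets, n, hypertension) {
    if (n == 0L) return(NULL)
    pars <- spec$params[[stratum_id]]
    hs <- spec$height[[sex]]
    draw_rows <- function(k) {
      d <- .draw_stratum(k, pars, spec$copula_vars, rho_latent)
      d$age <- round(d$age)
      d$height <- rnorm(k, hs[["mean"]], hs[["sd"]])
      d
    }
    d <- draw_rows(n)
    attempts <- 0L
    repeat {
      bad <- .guard_bad(d, t2dm)
      if (!any(bad)) break
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(
          "guard-rail resampling exhausted after %d attempts in stratum %s; the spec's marginals appear infeasible.",
          max_attempts, stratum_id
        ), class = "metsindex_spec_error")
      }
      d[bad, ] <- draw_rows(sum(bad))
    }
    d$weight <- d$bmi * d$height^2
    d$sex <- sex
    d$diagnosed_t2dm <- rep(t2dm, n)
    d$glucose_lowering_meds <- if (t2dm) {
      rbinom(n, 1, spec$glucose_meds_prev) == 1
    } else {
      rep(FALSE, n)
    }
    d$diagnosed_hypertension <- rbinom(n, 1, hypertension) == 1
    d$antihypertensive_meds <- d$diagnosed_hypertension
    d$ckd <- TRUE
    d$stratum_t2dm <- t2dm
    d$stratum_mets <- mets
    d$bmi <- NULL # recomputed downstream from weight and height
    d
  })
  out <- list_rbind(strata_rows)
  out$subject_id <- sprintf("S%04d", seq_len(nrow(out)))
  select(
    out, "subject_id", "sex", "age", "weight", "height", "wc", "sbp", "dbp",
    "fbg", "tc", "tg", "hdl", "ldl", "creatinine", "uric_acid", "hemoglobin",
    "vfa", "sfa", "diagnosed_t2dm", "glucose_lowering_meds",
    "diagnosed_hypertension", "antihypertensive_meds", "ckd",
    "stratum_t2dm", "stratum_mets"
  )
}

#' Generate a bi-normal separable test cohort
#'
#' Emits `n` subjects split evenly between MetS classes with a single
#' score distributed N(0, 1) in the negative class and
#' N(`effect_size`, 1) in the positive class, together with the
#' ground-truth parameters: closed-form AUC `pnorm(effect_size /
#' sqrt(2))` and Youden-optimal cut-off `effect_size / 2`. Used to
#' validate ROC and cut-off recovery against closed forms.
#'
#' @param n Total subjects (>= 20; split as evenly as possible).
#' @param effect_size Mean shift of the positive class, in SD units.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return A list with `data` (tibble: `subject_id`, `mets`, `score`)
#'   and `truth` (list: `mu_neg`, `mu_pos`, `sd`, `effect_size`, `auc`,
#'   `optimal_cutoff`).
#' @export
generate_separable <- function(n, effect_size, seed = NULL) {
  if (n < 20) {
    abort("`n` must be at least 20.", class = "metsindex_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_pos <- n %/% 2
  n_neg <- n - n_pos
  data <- tibble(
    subject_id = sprintf("P%06d", seq_len(n)),
    mets = rep(c(FALSE, TRUE), c(n_neg, n_pos)),
    score = c(rnorm(n_neg, 0, 1), rnorm(n_pos, effect_size, 1))
  )
  truth <- list(
    mu_neg = 0, mu_pos = effect_size, sd = 1, effect_size = effect_size,
    auc = pnorm(effect_size / sqrt(2)),
    optimal_cutoff = effect_size / 2
  )
  list(data = data, truth = truth)
}

#' Generate a cohort with a planted VAI effect
#'
#' Builds a synthetic cohort from `spec`, derives the index panel, then
#' assigns MetS status from the within-stratum standardised log-VAI plus
#' Gaussian noise. VAI is therefore the strongest predictor by
#' construction while the other indices retain only the association they
#' inherit through shared measurements; used to check that the pipeline
#' ranks a genuinely dominant index first.
#'
#' @inheritParams generate_cohort
#' @param noise_sd SD of the label noise on the standardised log-VAI
#'   scale. Default 0.5.
#'
#' @return The index-augmented cohort with logical `t2dm` (stratum
#'   label) and planted `mets` columns.
#' @export
generate_planted <- function(spec = default_cohort_spec(), seed = NULL,
                             noise_sd = 0.5) {
  cohort <- generate_cohort(spec, seed = seed)
  panel <- add_indices(cohort, check_ranges = FALSE)
  panel$t2dm <- panel$stratum_t2dm
  panel <- panel |>
    group_by(.data$sex, .data$t2dm) |>
    mutate(mets = as.numeric(scale(log(.data$vai))) +
             rnorm(n(), 0, noise_sd) > 0) |>
    ungroup()
  panel
}
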