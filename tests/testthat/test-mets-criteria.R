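test_that("T2DM classification combines diagnosis, treatment and glucose", {
  expect_true(classify_t2dm(one_subject(fbg = 7.0))$t2dm)   # inclusive
  expect_false(classify_t2dm(one_subject(fbg = 6.9))$t2dm)
  expect_true(classify_t2dm(one_subject(fbg = 5.0, glucose_lowering_meds = TRUE))$t2dm)
  expect_true(classify_t2dm(one_subject(fbg = 5.0, diagnosed_t2dm = TRUE))$t2dm)
  # all three sources missing -> indeterminate
  no_info <- one_subject()
  no_info$fbg <- NA_real_
  no_info$diagnosed_t2dm <- NA
  no_info$glucose_lowering_meds <- NA
  expect_error(classify_t2dm(no_info), class = "metsindex_indeterminate")
})

test_that("china2020 components follow the printed thresholds", {
  rec <- one_subject(sex = "male", wc = 92, tg = 1.8, fbg = 6.5,
                     sbp = 120, dbp = 80, hdl = 1.2)
  comp <- mets_components(rec, "china2020")
  expect_equal(
    unlist(comp[1, c("central_obesity", "hyperglycemia", "elevated_bp",
                     "elevated_tg", "low_hdl")]),
    c(central_obesity = TRUE, hyperglycemia = TRUE, elevated_bp = FALSE,
      elevated_tg = TRUE, low_hdl = FALSE)
  )
  # inclusive WC threshold for women
  expect_true(mets_components(one_subject(sex = "female", wc = 85),
                              "china2020")$central_obesity)
  # strict < for low HDL
  expect_false(mets_components(one_subject(hdl = 1.04), "china2020")$low_hdl)
  # treated diagnosed diabetes counts as hyperglycemia
  expect_true(mets_components(
    one_subject(fbg = 5.0, diagnosed_t2dm = TRUE, glucose_lowering_meds = TRUE),
    "china2020"
  )$hyperglycemia)
  # treated hypertension counts as elevated BP
  expect_true(mets_components(
    one_subject(sbp = 120, dbp = 70, diagnosed_hypertension = TRUE,
                antihypertensive_meds = TRUE),
    "china2020"
  )$elevated_bp)
})

test_that("atpiii components use their revised thresholds", {
  expect_true(mets_components(one_subject(sex = "female", wc = 80),
                              "atpiii")$central_obesity)
  expect_false(mets_components(one_subject(sex = "male", hdl = 1.03),
                               "atpiii")$low_hdl)
  expect_true(mets_components(one_subject(sex = "female", hdl = 1.28),
                              "atpiii")$low_hdl)
  expect_true(mets_components(one_subject(fbg = 5.6), "atpiii")$hyperglycemia)
  expect_true(mets_components(one_subject(fbg = 5.0, diagnosed_t2dm = TRUE),
                              "atpiii")$hyperglycemia)
  # antihypertensive use alone suffices
  expect_true(mets_components(
    one_subject(sbp = 120, dbp = 70, antihypertensive_meds = TRUE),
    "atpiii"
  )$elevated_bp)
})

test_that("idf requires central obesity plus two further components", {
  expect_true(mets_components(one_subject(sex = "male", wc = 90),
                              "idf")$central_obesity)
  # everything but obesity -> not MetS
  all_but_obesity <- one_subject(wc = 80, tg = 2.5, hdl = 0.8, fbg = 6.5,
                                 sbp = 150, dbp = 95)
  expect_false(classify_mets(all_but_obesity, "idf")$mets)
  # obesity + exactly two others -> MetS
  two_others <- one_subject(wc = 95, tg = 2.5, hdl = 1.5, fbg = 6.5,
                            sbp = 110, dbp = 70)
  expect_true(classify_mets(two_others, "idf")$mets)
  # obesity + one other -> not MetS
  one_other <- one_subject(wc = 95, tg = 2.5, hdl = 1.5, fbg = 4.5,
                           sbp = 110, dbp = 70)
  expect_false(classify_mets(one_other, "idf")$mets)
})

test_that("the combination rules match the exhaustive truth table", {
  patterns <- expand.grid(central_obesity = c(FALSE, TRUE),
                          hyperglycemia = c(FALSE, TRUE),
                          elevated_bp = c(FALSE, TRUE),
                          elevated_tg = c(FALSE, TRUE),
                          low_hdl = c(FALSE, TRUE))
  for (crit in c("china2020", "atpiii", "idf")) {
    comp <- tibble::as_tibble(patterns)
    comp$criterion <- crit
    out <- diagnose_mets(comp)
    popcount <- rowSums(patterns)
    expect_equal(out$n_positive, as.integer(popcount))
    expected <- if (crit == "idf") {
      patterns$central_obesity & (popcount - patterns$central_obesity) >= 2
    } else {
      popcount >= 3
    }
    expect_equal(out$mets, as.vector(expected))
  }
})

test_that("turning a component on never revokes a diagnosis", {
  set.seed(7)
  flags <- c("central_obesity", "hyperglycemia", "elevated_bp",
             "elevated_tg", "low_hdl")
  for (crit in c("china2020", "atpiii", "idf")) {
    for (i in 1:20) {
      comp <- tibble::as_tibble(setNames(as.list(runif(5) > 0.5), flags))
      comp$criterion <- crit
      before <- diagnose_mets(comp)$mets
      off <- which(!unlist(comp[flags]))
      if (length(off) == 0) next
      j <- off[sample.int(length(off), 1)]
      comp[[flags[j]]] <- TRUE
      after <- diagnose_mets(comp)$mets
      expect_true(after >= before)
    }
  }
})

test_that("printed thresholds are honoured at the boundary, +/- epsilon", {
  eps <- 1e-6
  cases <- list(
    # variable, criterion, sex, threshold, component, inclusive
    list("wc", "china2020", "male", 90, "central_obesity", TRUE),
    list("wc", "china2020", "female", 85, "central_obesity", TRUE),
    list("wc", "atpiii", "female", 80, "central_obesity", TRUE),
    list("fbg", "china2020", "male", 6.1, "hyperglycemia", TRUE),
    list("fbg", "atpiii", "male", 5.6, "hyperglycemia", TRUE),
    list("tg", "china2020", "male", 1.70, "elevated_tg", TRUE),
    list("sbp", "china2020", "male", 130, "elevated_bp", TRUE),
    list("dbp", "china2020", "male", 85, "elevated_bp", TRUE),
    list("hdl", "china2020", "male", 1.04, "low_hdl", FALSE),
    list("hdl", "atpiii", "male", 1.03, "low_hdl", FALSE),
    list("hdl", "atpiii", "female", 1.29, "low_hdl", FALSE)
  )
  for (cs in cases) {
    var <- cs[[1]]; crit <- cs[[2]]; sex <- cs[[3]]; thr <- cs[[4]]
    comp_name <- cs[[5]]; inclusive <- cs[[6]]
    # neutral baseline so only the probed variable matters
    probe <- function(value) {
      args <- list(sex = sex, sbp = 100, dbp = 60, fbg = 4.5, tg = 1.0,
                   hdl = 1.5, wc = 70)
      args[[var]] <- value
      mets_components(do.call(one_subject, args), crit)[[comp_name]]
    }
    if (inclusive) {
      expect_true(probe(thr), label = sprintf("%s %s at threshold", crit, var))
      expect_true(probe(thr + eps))
      expect_false(probe(thr - eps))
    } else {
      expect_false(probe(thr), label = sprintf("%s %s at threshold", crit, var))
      expect_true(probe(thr - eps))
      expect_false(probe(thr + eps))
    }
  }
})

test_that("assessments are deterministic and audit counts are consistent", {
  set.seed(11)
  cohort <- generate_cohort(seed = 99)[1:50, ]
  for (crit in c("china2020", "atpiii", "idf")) {
    a <- classify_mets(cohort, crit)
    b <- classify_mets(cohort, crit)
    expect_identical(a, b)
    flags <- as.matrix(a[c("central_obesity", "hyperglycemia", "elevated_bp",
                           "elevated_tg", "low_hdl")])
    expect_equal(a$n_positive, as.integer(rowSums(flags)))
  }
})
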