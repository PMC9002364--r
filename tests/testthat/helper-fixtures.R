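# shared fixtures and independent oracles

# a single fully valid subject record
one_subject <- function(...) {
  base <- tibble::tibble(
    subject_id = "s1", sex = "male", age = 50, weight = 81, height = 1.8,
    wc = 90, sbp = 120, dbp = 80, fbg = 5.0, tc = 4.2, tg = 2.06,
    hdl = 0.88, ldl = 2.6, creatinine = 100, uric_acid = 400,
    hemoglobin = 130, vfa = 100, sfa = 180,
    diagnosed_t2dm = FALSE, glucose_lowering_meds = FALSE,
    diagnosed_hypertension = FALSE, antihypertensive_meds = FALSE,
    ckd = TRUE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# brute-force AUC: mean over all pos x neg pairs, ties count 1/2
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force Youden maximiser over the unique observed scores,
# positive call score >= threshold; ties: higher sens, then smaller threshold
cutoff_bruteforce <- function(scores, labels) {
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  j <- sens + spec - 1
  o <- order(-j, -sens, thr)
  list(threshold = thr[o[1]], youden = j[o[1]],
       sensitivity = sens[o[1]], specificity = spec[o[1]])
}

# penalized log-likelihood written independently of the package internals,
# for grid/optim oracles of the Firth fit
pll_oracle <- function(X, y) {
  function(beta) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    info <- crossprod(X, X * (mu * (1 - mu)))
    sum(y * log(mu) + (1 - y) * log(1 - mu)) +
      0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
  }
}
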