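# scores/labels extraction shared by the ROC functions
.roc_inputs <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    abort("`truth` must be logical or 0/1.", class = "metsindex_domain_error")
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("scores must be finite and non-missing.",
          class = "metsindex_domain_error")
  }
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length.",
          class = "metsindex_domain_error")
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be represented to build a ROC curve.",
          class = "metsindex_single_class")
  }
  list(scores = scores, labels = labels, n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve operating points
#'
#' One operating point per unique observed score plus the two degenerate
#' endpoints (`-Inf`: everyone called positive; `Inf`: no one). The
#' positive-call convention is **score >= threshold** (inclusive), so a
#' subject exactly at a reported cut-off is called positive.
#'
#' @param data A data frame.
#' @param score Unquoted column of real-valued predictor scores.
#' @param truth Unquoted column with the binary outcome (logical or 0/1).
#'
#' @return A tibble of class `mets_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, and attributes `n_pos`, `n_neg`.
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
#' roc_curve(d, s, y)
#' @export
roc_curve <- function(data, score, truth) {
  scores <- pull(data, {{ score }})
  labels <- pull(data, {{ truth }})
  inp <- .roc_inputs(scores, labels)
  pos <- sort(inp$scores[inp$labels == 1L])
  neg <- sort(inp$scores[inp$labels == 0L])
  thr <- c(-Inf, sort(unique(inp$scores)), Inf)
  # count of pos strictly below each threshold
  below_pos <- findInterval(thr, pos, left.open = TRUE)
  below_neg <- findInterval(thr, neg, left.open = TRUE)
  out <- tibble(
    threshold = thr,
    sensitivity = (inp$n_pos - below_pos) / inp$n_pos,
    specificity = below_neg / inp$n_neg
  )
  structure(out, n_pos = inp$n_pos, n_neg = inp$n_neg,
            class = c("mets_roc", class(out)))
}

# rank-based placement values: auc plus DeLong components
.auc_delong <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n          # P(X > Y) placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- mean(v10)
  # a singleton class contributes no estimable placement variance
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  list(auc = auc, se = se, n_pos = m, n_neg = n)
}

#' Area under the ROC curve with confidence interval
#'
#' The AUC is the pairwise concordance probability (ties count 1/2),
#' computed by rank placements; it equals the trapezoidal area under the
#' [roc_curve()] polyline. The 95% interval uses the DeLong variance by
#' default, or Hanley-McNeil via `ci_method = "hanley"`. The p-value
#' tests AUC = 0.5 by a normal approximation on the same variance.
#'
#' @inheritParams roc_curve
#' @param conf_level Confidence level, default 0.95.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#'
#' @return A one-row tibble of class `auc_estimate`: `auc`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `method`, `n_pos`, `n_neg`.
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 2, 3), y = c(0, 0, 1, 1))
#' roc_auc(d, s, y)
#' @export
roc_auc <- function(data, score, truth, conf_level = 0.95,
                    ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  scores <- pull(data, {{ score }})
  labels <- pull(data, {{ truth }})
  inp <- .roc_inputs(scores, labels)
  dl <- .auc_delong(inp$scores, inp$labels)
  auc <- dl$auc
  se <- if (ci_method == "delong") {
    dl$se
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    sqrt((auc * (1 - auc) + (dl$n_pos - 1) * (q1 - auc^2) +
            (dl$n_neg - 1) * (q2 - auc^2)) / (dl$n_pos * dl$n_neg))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  p_value <- if (se == 0) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * pnorm(-abs(auc - 0.5) / se)
  }
  out <- tibble(
    auc = auc,
    se = se,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    p_value = p_value,
    method = ci_method,
    n_pos = dl$n_pos,
    n_neg = dl$n_neg
  )
  class(out) <- c("auc_estimate", class(out))
  out
}

# trapezoidal area under a mets_roc polyline (used as the dual route to
# the rank-based AUC in tests)
.auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`, with both arguments given as
#' fractions in `[0, 1]`.
#'
#' @param sensitivity,specificity Fractions in `[0, 1]` (vectorised).
#'
#' @return Youden index in `[-1, 1]`.
#' @examples
#' youden_index(0.8684, 0.9118)
#' @export
youden_index <- function(sensitivity, specificity) {
  for (nm in c("sensitivity", "specificity")) {
    x <- get(nm)
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm),
            class = "metsindex_domain_error")
    }
  }
  sensitivity + specificity - 1
}

#' Youden-optimal cut-off
#'
#' Selects the threshold maximising Youden's J over the observed-score
#' operating points of a [roc_curve()]. Ties are broken first by higher
#' sensitivity, then by the smaller threshold. Sensitivity and
#' specificity are reported as percentages, matching the conventional
#' cut-off table layout; `youden` stays on the fraction scale.
#'
#' @param roc A `mets_roc` object.
#'
#' @return A one-row tibble of class `cutoff_result`: `threshold`,
#'   `youden`, `sensitivity`, `specificity` (the last two in percent).
#' @export
optimal_cutoff <- function(roc) {
  if (!inherits(roc, "mets_roc")) {
    abort("`roc` must be a `mets_roc` object from roc_curve().",
          class = "metsindex_domain_error")
  }
  pts <- roc[is.finite(roc$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) {
    abort("degenerate ROC curve: no finite operating points.",
          class = "metsindex_degenerate_roc")
  }
  j <- pts$sensitivity + pts$specificity - 1
  o <- order(-j, -pts$sensitivity, pts$threshold)
  best <- pts[o[1L], ]
  out <- tibble(
    threshold = best$threshold,
    youden = j[o[1L]],
    sensitivity = 100 * best$sensitivity,
    specificity = 100 * best$specificity
  )
  class(out) <- c("cutoff_result", class(out))
  out
}

#' Confusion-matrix summary at a fixed threshold
#'
#' Positive call iff score >= threshold (same convention as
#' [roc_curve()]).
#'
#' @inheritParams roc_curve
#' @param threshold Decision threshold on the score scale.
#'
#' @return A one-row tibble: `sensitivity`, `specificity` (fractions),
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(data, score, truth, threshold) {
  scores <- pull(data, {{ score }})
  labels <- pull(data, {{ truth }})
  inp <- .roc_inputs(scores, labels)
  call_pos <- inp$scores >= threshold
  tp <- sum(call_pos & inp$labels == 1L)
  fp <- sum(call_pos & inp$labels == 0L)
  fn <- inp$n_pos - tp
  tn <- inp$n_neg - fp
  tibble(
    sensitivity = tp / inp$n_pos,
    specificity = tn / inp$n_neg,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Plot a ROC curve
#'
#' @param object A `mets_roc` object.
#' @param ... Ignored.
#'
#' @return A ggplot.
#' @method autoplot mets_roc
#' @export
autoplot.mets_roc <- function(object, ...) {
  df <- as_tibble(object)
  df$fpr <- 1 - df$specificity
  df <- df[order(df$fpr, df$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}
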