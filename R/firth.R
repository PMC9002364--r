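# penalized log-likelihood: l(beta) + 0.5 * log det X'WX (Jeffreys prior)
.firth_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

# ordinary-ML separation heuristic: fitted probabilities collapsing to
# 0/1 (or a non-converged IRLS) signal (quasi-)complete separation
.separation_suspected <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 100))
  )
  !fit$converged || any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
}

#' Firth bias-reduced penalized logistic regression
#'
#' Maximises the Jeffreys-prior penalized log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` (with `I = X'WX` the Fisher
#' information) by modified-score Newton iterations with step-halving.
#' The modified score is `U*(beta) = X'(y - mu + h (1/2 - mu))` where `h`
#' holds the hat-diagonals; convergence is declared when
#' `max |U*| < tol`. Estimates remain finite under complete or
#' quasi-complete separation, where ordinary maximum likelihood
#' diverges; such data are detected and flagged via
#' `separation_suspected`.
#'
#' @param data A data frame holding outcome and covariates.
#' @param formula Model formula; the response must be logical, 0/1 or a
#'   two-level factor.
#' @param max_iter Maximum Newton iterations (default 50).
#' @param tol Convergence tolerance on the modified-score sup-norm
#'   (default 1e-6).
#' @param max_halving Maximum step-halvings per iteration (default 10).
#' @param conf_level Level for the Wald odds-ratio intervals.
#'
#' @return An object of class `firth_fit` with elements `coefficients`,
#'   `std_errors`, `vcov`, `odds_ratios`, `ci_low`, `ci_high`,
#'   `penalized_loglik`, `iterations`, `converged`,
#'   `separation_suspected`, `n`, `formula`, `conf_level`.
#' @examples
#' d <- tibble::tibble(y = rep(c(0, 1), each = 10), x = rnorm(20))
#' fit_firth(d, y ~ x)
#' @export
fit_firth <- function(data, formula, max_iter = 50, tol = 1e-6,
                      max_halving = 10, conf_level = 0.95) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) {
    abort("outcome must be binary (logical, 0/1 or two-level factor).",
          class = "metsindex_domain_error")
  }
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    abort(
      "design matrix is rank deficient; inspect collinearity() for the offending covariates.",
      class = "metsindex_rank_deficient"
    )
  }

  p <- ncol(X)
  beta <- rep(0, p)
  pll <- .firth_pll(X, y, beta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    inv_info <- chol2inv(chol(info))
    h <- rowSums((X %*% inv_info) * X) * w
    score_mod <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (max(abs(score_mod)) < tol) {
      converged <- TRUE
      break
    }
    step <- drop(inv_info %*% score_mod)
    # step-halving keeps the penalized log-likelihood non-decreasing
    lambda <- 1
    for (half in seq_len(max_halving + 1L)) {
      cand <- beta + lambda * step
      pll_cand <- .firth_pll(X, y, cand)
      if (pll_cand >= pll - 1e-10) break
      lambda <- lambda / 2
    }
    beta <- cand
    pll <- pll_cand
  }
  # refresh information at the final estimate
  mu <- pmin(pmax(plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  vcov <- chol2inv(chol(info))
  se <- sqrt(diag(vcov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  structure(
    list(
      coefficients = beta,
      std_errors = se,
      vcov = vcov,
      odds_ratios = exp(beta),
      ci_low = exp(beta - z * se),
      ci_high = exp(beta + z * se),
      penalized_loglik = pll,
      iterations = iter,
      converged = converged,
      separation_suspected = .separation_suspected(X, y),
      n = length(y),
      formula = formula,
      conf_level = conf_level
    ),
    class = "firth_fit"
  )
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth penalized logistic regression\n")
  cat(sprintf("n = %d, iterations = %d, converged = %s%s\n",
              x$n, x$iterations, x$converged,
              if (x$separation_suspected) " (separation suspected)" else ""))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_firth
#' @param x A `firth_fit` object.
#' @param conf.int,conf.level,exponentiate Standard broom arguments.
#' @param ... Ignored.
#' @method tidy firth_fit
#' @export
tidy.firth_fit <- function(x, conf.int = TRUE, conf.level = x$conf_level,
                           exponentiate = FALSE, ...) {
  z <- x$coefficients / x$std_errors
  out <- tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
  if (conf.int) {
    q <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - q * out$std.error
    out$conf.high <- out$estimate + q * out$std.error
  }
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    if (conf.int) {
      out$conf.low <- exp(out$conf.low)
      out$conf.high <- exp(out$conf.high)
    }
  }
  out
}

#' @rdname fit_firth
#' @method glance firth_fit
#' @export
glance.firth_fit <- function(x, ...) {
  tibble(
    penalized_loglik = x$penalized_loglik,
    iterations = x$iterations,
    converged = x$converged,
    separation_suspected = x$separation_suspected,
    nobs = x$n
  )
}

#' Wald odds-ratio intervals from a Firth fit
#'
#' `exp(beta +/- z * se)` per covariate.
#'
#' @param fit A converged `firth_fit`.
#' @param level Confidence level (default 0.95).
#'
#' @return A tibble: `term`, `estimate` (log-odds), `or`, `ci_low`,
#'   `ci_high`.
#' @export
wald_or_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "firth_fit")) {
    abort("`fit` must be a firth_fit.", class = "metsindex_domain_error")
  }
  if (!fit$converged) {
    abort("fit did not converge; intervals unavailable.",
          class = "metsindex_not_converged")
  }
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    or = unname(exp(fit$coefficients)),
    ci_low = unname(exp(fit$coefficients - z * fit$std_errors)),
    ci_high = unname(exp(fit$coefficients + z * fit$std_errors))
  )
}

#' Collinearity diagnostics
#'
#' Variance inflation factors from per-covariate auxiliary regressions,
#' plus Belsley condition indices and variance-decomposition proportions
#' from the singular values of the unit-length-scaled design (intercept
#' included). Covariates are flagged when VIF > 10, or when a condition
#' index > 30 concentrates more than 50% of the coefficient variance on
#' two or more covariates. A constant covariate is reported with
#' infinite VIF rather than raising an error.
#'
#' @param data A data frame of covariates.
#' @param vars Covariate columns to assess (character); defaults to all
#'   numeric columns.
#'
#' @return An object of class `collinearity_report`: a list with tibbles
#'   `vif` (`term`, `vif`, `tolerance`, `flagged`) and `condition`
#'   (`condition_index` plus one variance-proportion column per term),
#'   and `rank_deficient`.
#' @export
collinearity <- function(data, vars = NULL) {
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2L) {
    abort("collinearity diagnostics need at least two covariates.",
          class = "metsindex_domain_error")
  }
  check_required_columns(data, vars, "covariate data")
  X <- as.matrix(as.data.frame(data[vars]))

  vif <- vapply(seq_along(vars), function(j) {
    xj <- X[, j]
    if (var(xj) == 0) return(Inf)
    others <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(others, xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))

  # Belsley diagnostics on the intercept-augmented, column-equilibrated design
  Xd <- cbind(`(Intercept)` = 1, X)
  Xs <- sweep(Xd, 2, sqrt(colSums(Xd^2)), "/")
  sv <- svd(Xs)
  d <- pmax(sv$d, .Machine$double.eps)
  rank_deficient <- any(sv$d < max(sv$d) * 1e-10)
  cond_idx <- max(d) / d
  V <- sv$v
  comp <- sweep(V^2, 2, d^2, "/")     # (v_jk / d_k)^2 laid out terms x dims
  denom <- rowSums(comp)
  prop <- sweep(comp, 1, denom, "/")  # rows = terms, cols = dimensions
  o <- order(cond_idx)
  prop_t <- t(prop[, o, drop = FALSE])
  colnames(prop_t) <- colnames(Xd)
  cond_tbl <- bind_cols(tibble(condition_index = cond_idx[o]),
                        as_tibble(prop_t))

  high_dims <- which(cond_tbl$condition_index > 30)
  flagged_belsley <- rep(FALSE, length(vars))
  for (k in high_dims) {
    props <- as.numeric(cond_tbl[k, vars])
    involved <- props > 0.5
    if (sum(involved) >= 2L) flagged_belsley <- flagged_belsley | involved
  }
  vif_tbl <- tibble(
    term = vars,
    vif = vif,
    tolerance = 1 / vif,
    flagged = vif > 10 | flagged_belsley
  )
  structure(
    list(vif = vif_tbl, condition = cond_tbl, rank_deficient = rank_deficient),
    class = "collinearity_report"
  )
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity diagnostics\n")
  if (x$rank_deficient) cat("warning: design is (near) rank deficient\n")
  print(x$vif)
  cat("\nCondition indices and variance proportions:\n")
  print(x$condition)
  invisible(x)
}
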