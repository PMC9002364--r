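test_that("intercept-only fits land on the penalized-mode closed form", {
  for (case in list(c(10, 0), c(10, 10), c(20, 7))) {
    n <- case[1]; k <- case[2]
    d <- tibble::tibble(y = rep(c(1, 0), c(k, n - k)))
    fit <- fit_firth(d, y ~ 1)
    expect_true(fit$converged)
    expect_equal(fit$coefficients[["(Intercept)"]],
                 qlogis((k + 0.5) / (n + 1)), tolerance = 1e-4)
  }
})

test_that("saturated 2x2 fits equal the Haldane half-cell correction", {
  make_2x2 <- function(a, b, c, d) {
    # exposed: a events / a+b; unexposed: c events / c+d
    tibble::tibble(
      y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
      x = rep(c(1, 1, 0, 0), c(a, b, c, d))
    )
  }
  # symmetric table: slope exactly 0, OR exactly 1
  fit0 <- fit_firth(make_2x2(5, 5, 5, 5), y ~ x)
  expect_equal(unname(fit0$coefficients[["x"]]), 0, tolerance = 1e-6)
  expect_equal(unname(fit0$odds_ratios[["x"]]), 1, tolerance = 1e-6)
  # zero cell: Firth equals log of the Haldane-corrected odds ratio
  fit1 <- fit_firth(make_2x2(10, 0, 5, 5), y ~ x)
  expect_true(fit1$converged)
  expect_equal(unname(fit1$coefficients[["x"]]), log(21), tolerance = 1e-4)
  expect_true(fit1$separation_suspected)
  # a generic table against the same closed form
  fit2 <- fit_firth(make_2x2(12, 4, 6, 9), y ~ x)
  haldane <- log((12.5 * 9.5) / (4.5 * 6.5))
  expect_equal(unname(fit2$coefficients[["x"]]), haldane, tolerance = 1e-4)
  # and against an independent optimiser of the penalized likelihood
  d <- make_2x2(10, 0, 5, 5)
  X <- cbind(1, d$x)
  opt <- optim(c(0, 0), function(b) -pll_oracle(X, d$y)(b), method = "BFGS")
  expect_equal(unname(fit1$coefficients[["x"]]), opt$par[2], tolerance = 1e-4)
})

test_that("complete separation yields finite estimates and raises the flag", {
  d <- tibble::tibble(x = c(-3, -2, -1, -0.5, 0.5, 1, 2, 3),
                      y = c(0, 0, 0, 0, 1, 1, 1, 1))
  fit <- fit_firth(d, y ~ x)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(fit$std_errors)))
  expect_true(fit$separation_suspected)
  # a benign fit does not raise the flag
  set.seed(3)
  d2 <- tibble::tibble(x = rnorm(200), y = rbinom(200, 1, 0.5))
  expect_false(fit_firth(d2, y ~ x)$separation_suspected)
})

test_that("odds ratios are exp(coefficients) and intervals nest by level", {
  set.seed(8)
  d <- tibble::tibble(x = rnorm(100), z = rnorm(100),
                      y = rbinom(100, 1, plogis(0.5 * x)))
  fit <- fit_firth(d, y ~ x + z)
  expect_equal(fit$odds_ratios, exp(fit$coefficients))
  expect_true(all(fit$ci_low < fit$odds_ratios & fit$odds_ratios < fit$ci_high))
  wide <- wald_or_ci(fit, level = 0.99)
  narrow <- wald_or_ci(fit, level = 0.95)
  expect_true(all(wide$ci_low < narrow$ci_low))
  expect_true(all(wide$ci_high > narrow$ci_high))
})

test_that("wald_or_ci applies the normal quantile on the log-odds scale", {
  fake <- structure(
    list(coefficients = c(x = 0), std_errors = c(x = 0.5), converged = TRUE),
    class = "firth_fit"
  )
  ci <- wald_or_ci(fake)
  expect_equal(ci$or, 1)
  expect_equal(ci$ci_low, exp(-qnorm(0.975) * 0.5), tolerance = 1e-10)
  expect_equal(ci$ci_high, exp(qnorm(0.975) * 0.5), tolerance = 1e-10)
  expect_equal(ci$ci_low, 0.375, tolerance = 1e-2)
  expect_equal(ci$ci_high, 2.664, tolerance = 1e-2)
  fake$converged <- FALSE
  expect_error(wald_or_ci(fake), class = "metsindex_not_converged")
})

test_that("rank-deficient designs are rejected with a collinearity hint", {
  d <- tibble::tibble(x = rnorm(30), y = rbinom(30, 1, 0.5))
  d$x2 <- d$x
  expect_error(fit_firth(d, y ~ x + x2), "collinearity",
               class = "metsindex_rank_deficient")
})

test_that("Firth and ML agree on large, well-behaved samples", {
  set.seed(21)
  n <- 10000
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.6 * d$x1 - 0.3 * d$x2))
  firth <- fit_firth(d, y ~ x1 + x2)
  ml <- glm(y ~ x1 + x2, binomial(), data = d)
  expect_equal(unname(firth$coefficients), unname(coef(ml)), tolerance = 0.02)
})

test_that("tidy and glance expose the broom-style views", {
  set.seed(9)
  d <- tibble::tibble(x = rnorm(80), y = rbinom(80, 1, plogis(x)))
  fit <- fit_firth(d, y ~ x)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  expect_equal(exp(td$estimate), unname(fit$odds_ratios))
  td_or <- tidy(fit, exponentiate = TRUE)
  expect_equal(td_or$estimate, unname(fit$odds_ratios))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 80)
})

test_that("VIF matches the 1/(1 - r^2) closed form on constructed data", {
  set.seed(15)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n)
  # orthogonalise, then mix with exact sample correlation 0.9
  e1 <- scale(z1)[, 1]
  e2 <- scale(residuals(lm(z2 ~ z1)))[, 1]
  x1 <- e1
  x2 <- 0.9 * e1 + sqrt(1 - 0.81) * e2
  expect_equal(cor(x1, x2), 0.9, tolerance = 1e-10)
  rep <- collinearity(tibble::tibble(x1 = x1, x2 = x2))
  expect_equal(rep$vif$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
  expect_equal(rep$vif$tolerance, 1 / rep$vif$vif)
  expect_false(any(rep$vif$flagged))
})

test_that("collinearity report flags degenerate designs without crashing", {
  set.seed(16)
  x <- rnorm(50)
  # orthogonal covariates: VIF exactly 1
  e <- scale(residuals(lm(rnorm(50) ~ x)))[, 1]
  ortho <- collinearity(tibble::tibble(a = scale(x)[, 1], b = e))
  expect_equal(ortho$vif$vif, c(1, 1), tolerance = 1e-8)
  # duplicated covariate: unbounded VIF and rank alarm
  dup <- collinearity(tibble::tibble(a = x, b = x))
  expect_true(all(is.infinite(dup$vif$vif)))
  expect_true(all(dup$vif$flagged))
  expect_true(dup$rank_deficient)
  # constant covariate: flagged, not crashed
  const <- collinearity(tibble::tibble(a = x, b = rep(2, 50)))
  expect_true(is.infinite(const$vif$vif[const$vif$term == "b"]))
  # structural invariants of the condition table
  rep <- collinearity(tibble::tibble(a = x, b = x + rnorm(50, 0, 0.1)))
  expect_true(all(diff(rep$condition$condition_index) >= 0))
  prop_cols <- setdiff(names(rep$condition), "condition_index")
  for (cl in prop_cols) {
    expect_equal(sum(rep$condition[[cl]]), 1, tolerance = 1e-8)
  }
})
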