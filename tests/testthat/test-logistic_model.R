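test_that("intercept-only fit has the closed-form MLE and null fit statistics", {
  y <- c(rep(TRUE, 22), rep(FALSE, 26))
  fit <- fit_logistic(y, tol = 1e-12)
  expect_equal(unname(fit$coefficients), log(22 / 26), tolerance = 1e-8)
  expect_equal(fit$ll0, 22 * log(22 / 48) + 26 * log(26 / 48), tolerance = 1e-12)
  expect_equal(fit$ll, fit$ll0, tolerance = 1e-10)
  expect_equal(fit$model_chi2, 0, tolerance = 1e-8)
  expect_equal(fit$nagelkerke_r2, 0, tolerance = 1e-8)
  # majority-class prediction: all negative, accuracy 26/48
  expect_equal(fit$pct_correct, 26 / 48, tolerance = 1e-12)

  # score equations hold at the MLE: |X'(y - p)| < tol componentwise
  set.seed(61)
  xs <- cbind(a = stats::rnorm(120), b = stats::rlnorm(120))
  ys <- stats::runif(120) < stats::plogis(-0.5 + xs[, 1])
  f2 <- fit_logistic(ys, xs, tol = 1e-10)
  resid_score <- crossprod(f2$X, f2$y - stats::plogis(drop(f2$X %*% f2$coefficients)))
  expect_lt(max(abs(resid_score)), 1e-8)
  expect_true(f2$converged)
  expect_gte(f2$model_chi2, 0)
})

test_that("single-predictor MLE matches a refined grid-search oracle within 1e-3", {
  set.seed(62)
  n <- 200
  x <- stats::rnorm(n)
  y <- stats::runif(n) < stats::plogis(0.25 + 1 * x)
  fit <- fit_logistic(y, cbind(x = x), tol = 1e-12)

  loglik <- function(b0, b1) sum(y * (b0 + b1 * x) - log1p(exp(b0 + b1 * x)))
  centre <- c(0, 0); width <- 4
  for (stage in 1:6) {  # successive 41x41 grid refinement: final step 1e-4
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width / 10
  }
  expect_equal(unname(fit$coefficients), centre, tolerance = 1e-3)
})

test_that("fit matches glm() as an independent reference on a multi-predictor problem", {
  set.seed(63)
  n <- 150
  X <- cbind(score = sample(0:4, n, TRUE), weight = stats::rnorm(n, 70, 10))
  y <- stats::runif(n) < stats::plogis(-2 + 0.8 * X[, 1] + 0.02 * X[, 2])
  fit <- fit_logistic(y, X, tol = 1e-10)
  ref <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]), tolerance = 1e-5)
  expect_equal(fit$ll, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$model_chi2, unname(ref$null.deviance - ref$deviance), tolerance = 1e-6)
})

test_that("perfect separation is detected and flagged, not crashed", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  expect_warning(fit <- fit_logistic(y, cbind(x = x)), "separation")
  expect_false(fit$converged)
  expect_true(fit$separation)
  # its own training data are still classified perfectly
  expect_equal(classification_accuracy(fit), 1)
})

test_that("design-matrix validation: constants, collinearity, class balance", {
  y <- rep(c(TRUE, FALSE), 10)
  expect_th2_error(fit_logistic(y, cbind(c = rep(1, 20))), "th2_argument_error")
  x <- stats::rnorm(20)
  expect_th2_error(fit_logistic(y, cbind(a = x, b = 2 * x)), "th2_argument_error")
  expect_th2_error(fit_logistic(rep(TRUE, 20), cbind(a = x)), "th2_argument_error")
})

test_that("nagelkerke_r2: boundary cases and direct formula evaluation", {
  expect_equal(nagelkerke_r2(-10, -10, 50), 0)
  expect_equal(nagelkerke_r2(0, -20, 30), 1)  # perfect fit saturates at 1
  # direct evaluation of the rescaled Cox-Snell formula
  r2cs <- 1 - exp(2 * (-33.27 - (-20)) / 48)
  expect_equal(nagelkerke_r2(-20, -33.27, 48), r2cs / (1 - exp(2 * -33.27 / 48)),
               tolerance = 1e-12)
  expect_equal(nagelkerke_r2(-20, -33.27, 48), 0.5663157, tolerance = 1e-6)
  expect_th2_error(nagelkerke_r2(-30, -20, 48), "th2_argument_error")
})

test_that("classification accuracy evaluates held-out data through predict()", {
  set.seed(64)
  n <- 200
  X <- cbind(x = stats::rnorm(n))
  y <- stats::runif(n) < stats::plogis(2 * X[, 1])
  fit <- fit_logistic(y[1:150], X[1:150, , drop = FALSE])
  acc_new <- classification_accuracy(fit, X[151:200, , drop = FALSE], y[151:200])
  manual <- mean((stats::plogis(fit$coefficients[1] +
                                  fit$coefficients[2] * X[151:200, 1]) >= 0.5) == y[151:200])
  expect_equal(acc_new, manual, tolerance = 1e-12)
  expect_gt(acc_new, 0.5)  # a strong true effect classifies well out of sample
})

test_that("rescaling a predictor rescales its coefficient and keeps Wald p", {
  set.seed(65)
  n <- 120
  X <- cbind(a = stats::rnorm(n, 0, 2), b = stats::rlnorm(n))
  y <- stats::runif(n) < stats::plogis(0.3 + 0.7 * X[, 1] - 0.2 * X[, 2])
  f1 <- fit_logistic(y, X, tol = 1e-10)
  X2 <- X; X2[, "a"] <- X2[, "a"] * 10
  f2 <- fit_logistic(y, X2, tol = 1e-10)
  expect_equal(f2$coefficients[["a"]], f1$coefficients[["a"]] / 10, tolerance = 1e-6)
  expect_equal(f2$wald_p[["a"]], f1$wald_p[["a"]], tolerance = 1e-6)
})
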