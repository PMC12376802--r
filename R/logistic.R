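#' Binomial logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted from scratch with
#' iteratively reweighted least squares (Newton-Raphson on the binomial
#' log-likelihood), with step-halving whenever a full Newton step would
#' decrease the likelihood. Standard errors come from the inverse observed
#' information at the MLE; Wald p-values use the normal reference; odds
#' ratios and their confidence intervals are the exponentiated Wald
#' intervals on the log-odds scale. Quasi-separation (diverging
#' coefficients, fitted probabilities collapsing to 0/1) is detected and
#' reported via `converged = FALSE` plus a `separation` flag rather than a
#' crash.
#'
#' @param y logical (or 0/1) response with both classes present.
#' @param x numeric matrix or data frame of predictors (no intercept
#'   column; one is added and reported as `(Intercept)`). Columns must be
#'   named, non-constant, and jointly full rank. `NULL` fits the
#'   intercept-only model, whose MLE is the log-odds of the observed
#'   prevalence.
#' @param max_iter maximum IRLS iterations (default 50).
#' @param tol convergence tolerance on the score norm and coefficient change
#'   (default 1e-8).
#' @param conf_level confidence level for odds-ratio intervals.
#' @return object of class `th2_logit`: coefficients, standard errors, Wald
#'   z and p, odds ratios with CIs, log-likelihoods (`ll`, `ll0`), LRT
#'   `model_chi2` with `model_df` and `model_p`, `nagelkerke_r2`,
#'   `pct_correct` (probability threshold 0.5), `converged`, `separation`,
#'   `n_iter`, and the training data for prediction.
#' @export
fit_logistic <- function(y, x = NULL, max_iter = 50, tol = 1e-8, conf_level = 0.95) {
  y <- as.numeric(as.logical(y))
  if (anyNA(y)) th2_stop("NA in response", "th2_row_error")
  if (all(y == 0) || all(y == 1)) th2_stop("response must contain both classes", "th2_argument_error")

  if (is.null(x)) {
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    if (anyNA(x)) th2_stop("NA in predictors", "th2_row_error")
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    constant <- apply(x, 2, function(col) length(unique(col)) == 1L)
    if (any(constant)) {
      th2_stop(sprintf("constant predictor(s): %s",
                       paste(colnames(x)[constant], collapse = ", ")), "th2_argument_error")
    }
    X <- cbind(`(Intercept)` = 1, x)
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) th2_stop("need more observations than coefficients", "th2_argument_error")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    th2_stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                     paste(dropped, collapse = ", ")), "th2_argument_error")
  }

  loglik <- function(eta) sum(y * eta - log1p(exp(eta)))
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    info <- crossprod(X * sqrt(w))
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) break  # information singular: separation-degenerate
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      eta_new <- drop(X %*% beta_new)
      ll_new <- loglik(eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 2^-20) { beta_new <- beta; eta_new <- eta; ll_new <- ll; break }
    }
    moved <- max(abs(beta_new - beta))
    beta <- beta_new; eta <- eta_new; ll <- ll_new
    if (moved < tol) {
      converged <- max(abs(drop(crossprod(X, y - stats::plogis(eta))))) < sqrt(tol)
      break
    }
  }

  mu <- stats::plogis(eta)
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10) || max(abs(beta)) > 15
  if (separation) {
    # diverging coefficients: the likelihood has no interior maximum, so a
    # stationary score is spurious — report non-convergence with diagnostics
    converged <- FALSE
    warning("possible (quasi-)separation: coefficients diverged; estimates unreliable",
            call. = FALSE)
  }
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w))
  cov_beta <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(cov_beta))
  zval <- beta / se
  wald_p <- 2 * stats::pnorm(-abs(zval))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- exp(beta)
  or_ci <- cbind(lo = exp(beta - zq * se), hi = exp(beta + zq * se))

  p_null <- mean(y)
  ll0 <- sum(y) * log(p_null) + sum(1 - y) * log(1 - p_null)
  model_chi2 <- max(0, 2 * (ll - ll0))
  model_df <- p - 1L
  names(beta) <- names(se) <- names(zval) <- names(wald_p) <- names(or) <- colnames(X)
  rownames(or_ci) <- colnames(X)

  fit <- structure(list(
    coefficients = beta, standard_errors = se, z = zval, wald_p = wald_p,
    odds_ratios = or, or_ci = or_ci, conf_level = conf_level,
    ll = ll, ll0 = ll0, model_chi2 = model_chi2, model_df = model_df,
    model_p = stats::pchisq(model_chi2, model_df, lower.tail = FALSE),
    nagelkerke_r2 = nagelkerke_r2(ll, ll0, n),
    converged = converged, separation = separation, n_iter = iter,
    n = n, X = X, y = y
  ), class = "th2_logit")
  fit$pct_correct <- classification_accuracy(fit)
  fit
}

#' @export
print.th2_logit <- function(x, ...) {
  tab <- data.frame(
    OR = round(x$odds_ratios, 3),
    lo = round(x$or_ci[, "lo"], 3), hi = round(x$or_ci[, "hi"], 3),
    p = signif(x$wald_p, 3)
  )
  names(tab)[2:3] <- paste0(round(100 * x$conf_level), "%CI_", c("lo", "hi"))
  cat(sprintf("Binomial logistic regression (IRLS, %d iter, converged = %s%s)\n",
              x$n_iter, x$converged, if (x$separation) ", SEPARATION SUSPECTED" else ""))
  print(tab)
  cat(sprintf("model chi2 = %.3f on %d df (p = %.3g) | Nagelkerke R2 = %.3f | %.1f%% correctly classified\n",
              x$model_chi2, x$model_df, x$model_p, x$nagelkerke_r2,
              100 * x$pct_correct))
  invisible(x)
}

#' Predicted probabilities from a logistic fit
#' @param object a `th2_logit`.
#' @param newdata optional predictor matrix/data frame (no intercept column);
#'   defaults to the training predictors.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.th2_logit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    object$X
  } else {
    m <- as.matrix(newdata)
    cbind(1, m[, setdiff(colnames(object$X), "(Intercept)"), drop = FALSE])
  }
  stats::plogis(drop(X %*% object$coefficients))
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R2 = 1 - exp(2 (ll0 - ll) / n), rescaled by its maximum
#' 1 - exp(2 ll0 / n) so that a saturated fit reaches 1.
#'
#' @param ll model log-likelihood at the MLE.
#' @param ll0 intercept-only log-likelihood.
#' @param n number of observations.
#' @return R-squared in \[0, 1\].
#' @export
#' @examples
#' nagelkerke_r2(-20, -33.27, 48)  # 0.5663
nagelkerke_r2 <- function(ll, ll0, n) {
  if (ll < ll0 - 1e-8) th2_stop("ll < ll0: not a maximum-likelihood fit", "th2_argument_error")
  r2_cs <- 1 - exp(2 * (ll0 - ll) / n)
  denom <- 1 - exp(2 * ll0 / n)
  if (denom <= 0) return(0)
  min(1, max(0, r2_cs / denom))
}

#' Classification accuracy of a logistic fit
#'
#' Fraction of observations whose predicted probability, dichotomized at
#' `threshold`, matches the observed response.
#'
#' @param fit a `th2_logit`.
#' @param x optional predictor matrix (defaults to training predictors).
#' @param y optional response (defaults to training response).
#' @param threshold probability cut (default 0.5).
#' @return proportion correctly classified.
#' @export
classification_accuracy <- function(fit, x = NULL, y = NULL, threshold = 0.5) {
  stopifnot(inherits(fit, "th2_logit"))
  prob <- predict(fit, newdata = x)
  y <- if (is.null(y)) fit$y else as.numeric(as.logical(y))
  if (length(prob) != length(y)) th2_stop("x and y sizes disagree", "th2_argument_error")
  mean((prob >= threshold) == (y == 1))
}
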