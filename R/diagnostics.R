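#' Build a 2x2 confusion table from predictions and truths
#'
#' @param predictions logical vector of test results (TRUE = positive).
#' @param truths logical vector of reference-standard diagnoses.
#' @return object of class `confusion_table`: list with integer counts
#'   `tp, fp, fn, tn` and `n`.
#' @export
#' @examples
#' confusion_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusion_table <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    th2_stop("predictions and truths must have equal length", "th2_argument_error")
  }
  if (length(predictions) == 0L) th2_stop("empty input", "th2_empty_input")
  predictions <- as.logical(predictions); truths <- as.logical(truths)
  if (anyNA(predictions) || anyNA(truths)) th2_stop("NA in predictions or truths", "th2_row_error")
  new_confusion_table(
    tp = sum(predictions & truths), fp = sum(predictions & !truths),
    fn = sum(!predictions & truths), tn = sum(!predictions & !truths)
  )
}

#' Construct a confusion table directly from counts
#' @param tp,fp,fn,tn non-negative integer counts, n >= 1.
#' @return a `confusion_table`.
#' @export
new_confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    th2_stop("counts must be non-negative integers", "th2_argument_error")
  }
  if (sum(counts) < 1) th2_stop("table must contain at least one observation", "th2_argument_error")
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(as.list(c(as.list(counts), n = as.integer(sum(counts)))),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("positive", "negative"),
                              truth = c("disease", "no disease")))
  print(m)
  invisible(x)
}

# ---- confidence intervals for a binomial proportion ------------------------

#' Wilson score interval for a binomial proportion
#' @param x successes; @param n trials; @param conf_level confidence level.
#' @return numeric `c(lo, hi)`.
#' @export
ci_wilson <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Clopper-Pearson exact interval for a binomial proportion
#' @inheritParams ci_wilson
#' @return numeric `c(lo, hi)`.
#' @export
ci_clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

# internal: proportion + CI, or the undefined marker when the denominator is 0
prop_with_ci <- function(x, n, ci_method, conf_level, label) {
  if (n == 0) {
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                defined = FALSE, reason = sprintf("%s denominator is zero", label)))
  }
  ci_fun <- switch(ci_method, wilson = ci_wilson, clopper_pearson = ci_clopper_pearson)
  list(estimate = x / n, ci = ci_fun(x, n, conf_level), defined = TRUE, reason = NULL)
}

# internal: likelihood-ratio CI on the log scale (Simel et al. construction)
lr_ci <- function(lr, num_x, num_n, den_x, den_n, conf_level) {
  if (!is.finite(lr) || lr <= 0 || num_x == 0 || den_x == 0) {
    return(c(NA_real_, NA_real_))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt((1 - num_x / num_n) / num_x + (1 - den_x / den_n) / den_x)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Full diagnostic-accuracy metric panel from a 2x2 table
#'
#' Sensitivity, specificity, PPV, NPV (each with a confidence interval),
#' positive/negative likelihood ratios (log-method CIs), accuracy and
#' Youden's J. Any metric whose denominator is zero is flagged undefined
#' (`NA` with a reason) rather than fabricated; LR+ is undefined at
#' specificity 1 and LR- at specificity 0.
#'
#' @param ct a `confusion_table`.
#' @param ci_method `"wilson"` (default) or `"clopper_pearson"`.
#' @param conf_level confidence level for all intervals (default 0.95).
#' @return object of class `diagnostic_metrics`: a list of metric entries
#'   (each `list(estimate, ci, defined, reason)`) plus `accuracy`,
#'   `youden_j`, the source table, and rendering helpers via `print()`.
#' @export
#' @examples
#' ct <- new_confusion_table(tp = 8, fp = 1, fn = 14, tn = 25)
#' m <- diagnostic_metrics(ct)
#' m$sensitivity$estimate  # 0.3636...
#' m$lr_pos$estimate       # 9.4545...
diagnostic_metrics <- function(ct, ci_method = c("wilson", "clopper_pearson"),
                               conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  ci_method <- match.arg(ci_method)
  sens <- prop_with_ci(ct$tp, ct$tp + ct$fn, ci_method, conf_level, "sensitivity")
  spec <- prop_with_ci(ct$tn, ct$tn + ct$fp, ci_method, conf_level, "specificity")
  ppv <- prop_with_ci(ct$tp, ct$tp + ct$fp, ci_method, conf_level, "PPV")
  npv <- prop_with_ci(ct$tn, ct$tn + ct$fn, ci_method, conf_level, "NPV")

  lr_pos <- list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                 defined = FALSE, reason = NULL)
  if (!sens$defined || !spec$defined) {
    lr_pos$reason <- "sensitivity or specificity undefined"
  } else if (spec$estimate == 1) {
    lr_pos$reason <- "specificity is 1 (no false positives)"
  } else {
    lr_pos <- list(
      estimate = sens$estimate / (1 - spec$estimate),
      ci = lr_ci(sens$estimate / (1 - spec$estimate),
                 ct$tp, ct$tp + ct$fn, ct$fp, ct$fp + ct$tn, conf_level),
      defined = TRUE, reason = NULL
    )
  }
  lr_neg <- list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                 defined = FALSE, reason = NULL)
  if (!sens$defined || !spec$defined) {
    lr_neg$reason <- "sensitivity or specificity undefined"
  } else if (spec$estimate == 0) {
    lr_neg$reason <- "specificity is 0"
  } else {
    lr_neg <- list(
      estimate = (1 - sens$estimate) / spec$estimate,
      ci = lr_ci((1 - sens$estimate) / spec$estimate,
                 ct$fn, ct$tp + ct$fn, ct$tn, ct$fp + ct$tn, conf_level),
      defined = TRUE, reason = NULL
    )
  }

  youden <- if (sens$defined && spec$defined) sens$estimate + spec$estimate - 1 else NA_real_
  structure(list(
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    lr_pos = lr_pos, lr_neg = lr_neg,
    accuracy = (ct$tp + ct$tn) / ct$n,
    youden_j = youden,
    table = ct, ci_method = ci_method, conf_level = conf_level
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(m, pct = TRUE) {
    if (!m$defined) return(sprintf("undefined (%s)", m$reason))
    if (pct) {
      sprintf("%s (%s CI %s-%s)", render_percent(m$estimate),
              paste0(round(100 * x$conf_level), "%"),
              render_percent(m$ci[1]), render_percent(m$ci[2]))
    } else {
      sprintf("%s (CI %s-%s)", render_ratio(m$estimate),
              render_ratio(m$ci[1]), render_ratio(m$ci[2]))
    }
  }
  cat("Diagnostic accuracy (", x$ci_method, " CIs)\n", sep = "")
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  cat("  LR+:        ", fmt(x$lr_pos, pct = FALSE), "\n")
  cat("  LR-:        ", fmt(x$lr_neg, pct = FALSE), "\n")
  cat("  accuracy:   ", render_percent(x$accuracy), " | Youden J: ",
      round(x$youden_j, 3), "\n", sep = "")
  invisible(x)
}

#' Reconstruct a 2x2 table and predictive values from reported rates
#'
#' Given published sensitivity/specificity and the two group sizes, rebuilds
#' the implied integer table (`tp = round(sens * n_pos)` half-up, `tn`
#' likewise) and computes PPV/NPV/LR+ from those integer counts — the way a
#' reader recovers unpublished predictive values from a printed accuracy
#' pair.
#'
#' @param sens,spec proportions in \[0, 1\].
#' @param n_pos,n_neg diseased / non-diseased group sizes (>= 1).
#' @return list with `table` (a `confusion_table`), `ppv`, `npv`, `lr_pos`
#'   (NA with `ppv_defined = FALSE` when the implied positive margin is 0).
#' @export
#' @examples
#' metrics_from_rates(0.545, 0.808, 22, 26)  # tp 12, tn 21; PPV 0.706
metrics_from_rates <- function(sens, spec, n_pos, n_neg) {
  if (!is_scalar_number(sens) || sens < 0 || sens > 1 ||
      !is_scalar_number(spec) || spec < 0 || spec > 1) {
    th2_stop("sens and spec must be proportions in [0,1]", "th2_argument_error")
  }
  if (n_pos < 1 || n_neg < 1) th2_stop("group sizes must be >= 1", "th2_argument_error")
  tp <- round_half_up(sens * n_pos); fn <- n_pos - tp
  tn <- round_half_up(spec * n_neg); fp <- n_neg - tn
  ct <- new_confusion_table(tp = tp, fp = fp, fn = fn, tn = tn)
  ppv_defined <- (tp + fp) > 0
  list(
    table = ct,
    ppv = if (ppv_defined) tp / (tp + fp) else NA_real_,
    npv = if ((tn + fn) > 0) tn / (tn + fn) else NA_real_,
    lr_pos = if (fp > 0) (tp / n_pos) / (fp / n_neg) else NA_real_,
    ppv_defined = ppv_defined
  )
}

# internal: coerce a confusion_table / matrix / length-4 vector to 2x2 counts
as_counts_2x2 <- function(x) {
  if (inherits(x, "confusion_table")) {
    m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2)
  } else {
    m <- as.matrix(x)
    if (length(m) == 4L && (nrow(m) != 2L || ncol(m) != 2L)) m <- matrix(m, 2, 2)
  }
  if (!all(dim(m) == c(2L, 2L))) th2_stop("need a 2x2 table", "th2_argument_error")
  if (any(m < 0) || any(m != round(m))) th2_stop("counts must be non-negative integers", "th2_argument_error")
  storage.mode(m) <- "double"
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by full enumeration: with both margins fixed, sums the
#' hypergeometric probabilities of every feasible table whose probability is
#' at most that of the observed table (a relative tolerance of 1e-7 absorbs
#' floating-point ties) — the convention used by standard implementations.
#'
#' @param x a `confusion_table`, 2x2 matrix, or length-4 count vector
#'   (filled column-wise).
#' @return list with `p` (two-sided), `odds_ratio` (sample cross-product
#'   ratio, `Inf`/0 allowed), and the margins used.
#' @export
#' @examples
#' fisher_exact(matrix(c(25, 1, 14, 8), 2, 2))$p  # 0.00712
fisher_exact <- function(x) {
  m <- as_counts_2x2(x)
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margin: Fisher p set to 1", call. = FALSE)
    return(list(p = 1, odds_ratio = NA_real_, margins = list(row1 = r1, col1 = c1, n = n)))
  }
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- probs[k == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p = min(1, p), odds_ratio = or, margins = list(row1 = r1, col1 = c1, n = n))
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Statistic without continuity correction by default (Yates correction
#' available for 2x2), df = (r-1)(c-1), p from the upper tail.
#'
#' @param x matrix of counts (or `confusion_table`).
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p`, and `expected` counts.
#' @export
chi_square_test <- function(x, correct = FALSE) {
  m <- if (inherits(x, "confusion_table")) as_counts_2x2(x) else as.matrix(x)
  if (any(m < 0)) th2_stop("counts must be non-negative", "th2_argument_error")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    th2_stop("degenerate table: zero row or column margin", "th2_degenerate_table")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(m - expected)
  if (correct) {
    if (!all(dim(m) == c(2L, 2L))) {
      th2_stop("continuity correction applies to 2x2 tables only", "th2_argument_error")
    }
    dev <- pmax(0, dev - 0.5)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Diagnostic metrics across score thresholds
#'
#' Runs [classify()] + [confusion_table()] + [diagnostic_metrics()] for each
#' requested threshold over a scored cohort.
#'
#' @param scored a cohort from [score_cohort()] (needs `composite_score` and
#'   `asthma` columns).
#' @param thresholds integer thresholds to evaluate (default 1:4).
#' @param ... passed to [diagnostic_metrics()].
#' @return data frame, one row per threshold, with counts and metric columns
#'   (`NA` where a metric is undefined), plus a `metrics` list attribute
#'   holding the full `diagnostic_metrics` objects.
#' @export
threshold_metrics <- function(scored, thresholds = 1:4, ...) {
  if (!"composite_score" %in% names(scored)) {
    th2_stop("cohort is not scored; run score_cohort() first", "th2_argument_error")
  }
  full <- lapply(thresholds, function(t) {
    ct <- confusion_table(classify(scored$composite_score, t), scored$asthma)
    diagnostic_metrics(ct, ...)
  })
  est <- function(m) if (m$defined) m$estimate else NA_real_
  out <- data.frame(
    threshold = thresholds,
    tp = vapply(full, function(m) m$table$tp, numeric(1)),
    fp = vapply(full, function(m) m$table$fp, numeric(1)),
    fn = vapply(full, function(m) m$table$fn, numeric(1)),
    tn = vapply(full, function(m) m$table$tn, numeric(1)),
    sensitivity = vapply(full, function(m) est(m$sensitivity), numeric(1)),
    specificity = vapply(full, function(m) est(m$specificity), numeric(1)),
    ppv = vapply(full, function(m) est(m$ppv), numeric(1)),
    npv = vapply(full, function(m) est(m$npv), numeric(1)),
    lr_pos = vapply(full, function(m) est(m$lr_pos), numeric(1)),
    youden_j = vapply(full, function(m) m$youden_j, numeric(1)),
    accuracy = vapply(full, function(m) m$accuracy, numeric(1))
  )
  attr(out, "metrics") <- full
  out
}
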