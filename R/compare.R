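#' Two-sample t test
#'
#' Unpaired t comparison of two groups; Welch (unequal variances, default)
#' or Student (pooled) variant. Thin wrapper over [stats::t.test()] exposing
#' the package's comparison-result contract.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @return object of class `comparison_result`: list with `test_name`,
#'   `statistic`, `df`, `p`, `group_summaries`.
#' @export
#' @examples
#' t_test(c(1, 2, 3), c(4, 5, 6), variant = "student")  # t = -3.674
t_test <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    th2_stop("each group needs at least 2 observations", "th2_argument_error")
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  structure(list(
    test_name = if (variant == "student") "student_t" else "welch_t",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value,
    group_summaries = list(a = summarize_group(a), b = summarize_group(b))
  ), class = "comparison_result")
}

# cache of exact Mann-Whitney null distributions, keyed by "m,n"
.mw_null_cache <- new.env(parent = emptyenv())

# internal: exact null distribution of U for group sizes m, n (no ties),
# by full enumeration of all C(m+n, m) rank assignments
mw_null_distribution <- function(m, n) {
  key <- paste(m, n, sep = ",")
  if (!is.null(.mw_null_cache[[key]])) return(.mw_null_cache[[key]])
  combos <- utils::combn(m + n, m)
  u <- colSums(combos) - m * (m + 1) / 2
  dist <- tabulate(u + 1L, nbins = m * n + 1L) / ncol(combos)
  .mw_null_cache[[key]] <- dist
  dist
}

#' Mann-Whitney U test
#'
#' U is computed with midranks (ties count 1/2). The exact two-sided p-value
#' enumerates the full null distribution of U over all rank assignments and
#' sums both tails at least as extreme as observed; it is used when there
#' are no ties and `n_a * n_b <= exact_limit`. Otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param a,b numeric vectors, each of length >= 1.
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @param exact_limit largest `n_a * n_b` for which full enumeration is
#'   attempted in auto mode (default 100).
#' @return a `comparison_result` with `statistic` = U (for group `a`),
#'   `p`, and `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # exact: 1/3
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                           exact_limit = 100) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) th2_stop("both groups must be non-empty", "th2_argument_error")
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = !has_ties && m * n <= exact_limit
  )
  if (use_exact && has_ties) {
    th2_stop("exact Mann-Whitney p is unavailable with ties; use normal_approx",
             "th2_argument_error")
  }

  if (use_exact) {
    dist <- mw_null_distribution(m, n)
    dev <- abs(u - m * n / 2)
    support <- 0:(m * n)
    p <- sum(dist[abs(support - m * n / 2) >= dev - 1e-9])
    method <- "exact"
  } else {
    N <- m + n
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    v <- m * n / 12 * ((N + 1) - tie_corr)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u - m * n / 2)
      z <- (z - sign(z) * 0.5) / sqrt(v)  # continuity correction toward the mean
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(
    test_name = "mann_whitney", statistic = u, p = p, method = method,
    group_summaries = list(a = summarize_group(a), b = summarize_group(b))
  ), class = "comparison_result")
}

#' Compare two groups with automatic test selection
#'
#' The `auto_shapiro` policy applies a Shapiro-Wilk normality gate at
#' alpha = 0.05 to each group and uses the t test when both pass (groups of
#' fewer than 3, where Shapiro-Wilk is undefined, fail the gate), otherwise
#' the Mann-Whitney U test. `force_t` / `force_mw` bypass the gate. The
#' chosen test and policy are recorded in the result.
#'
#' @param a,b numeric vectors.
#' @param policy `"auto_shapiro"` (default), `"force_t"`, or `"force_mw"`.
#' @param t_variant t-test variant when the t branch is taken.
#' @return a `comparison_result` with an added `policy` field.
#' @export
select_and_compare <- function(a, b,
                               policy = c("auto_shapiro", "force_t", "force_mw"),
                               t_variant = c("welch", "student")) {
  policy <- match.arg(policy)
  t_variant <- match.arg(t_variant)
  use_t <- switch(policy,
    force_t = TRUE,
    force_mw = FALSE,
    auto_shapiro = {
      normal_enough <- function(x) {
        length(x) >= 3L && length(unique(x)) > 1L &&
          stats::shapiro.test(x)$p.value >= 0.05
      }
      normal_enough(a) && normal_enough(b)
    }
  )
  res <- if (use_t) t_test(a, b, variant = t_variant) else mann_whitney_u(a, b)
  res$policy <- policy
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_name, x$statistic, x$p))
  cat("  group a: "); print(x$group_summaries$a)
  cat("  group b: "); print(x$group_summaries$b)
  invisible(x)
}

#' Characteristics-table comparison of cohort variables by diagnosis
#'
#' For each requested numeric variable, compares the two diagnosis groups
#' with [select_and_compare()] and reports per-group mean +/- SD and
#' median (IQR) alongside the chosen test and its p-value. Binary variables
#' (`prick`) are compared with Fisher's exact test.
#'
#' @param cohort a `th2_cohort`.
#' @param variables character vector of cohort column names (default the
#'   biomarker panel plus any present covariates).
#' @param policy test-selection policy, see [select_and_compare()].
#' @return data frame, one row per variable.
#' @export
compare_groups <- function(cohort, variables = NULL,
                           policy = "auto_shapiro") {
  if (!inherits(cohort, "th2_cohort")) cohort <- as_cohort(cohort)
  if (!any(cohort$asthma) || all(cohort$asthma)) {
    th2_stop("both diagnosis groups must be present", "th2_argument_error")
  }
  if (is.null(variables)) {
    variables <- intersect(c("feno", "ige", "bec", "prick", "weight", "fev1_pct",
                             "composite_score"),
                           names(cohort))
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.logical(x)) {
      tab <- table(factor(!cohort$asthma, c(TRUE, FALSE)), factor(!x, c(TRUE, FALSE)))
      ft <- fisher_exact(matrix(as.numeric(tab), 2, 2))
      pos <- tapply(x, cohort$asthma, sum)
      n <- tapply(x, cohort$asthma, length)
      data.frame(
        variable = v, test = "fisher", p = ft$p,
        no_asthma = sprintf("%d/%d (%s)", pos[["FALSE"]], n[["FALSE"]],
                            render_percent(pos[["FALSE"]] / n[["FALSE"]], 0)),
        asthma = sprintf("%d/%d (%s)", pos[["TRUE"]], n[["TRUE"]],
                         render_percent(pos[["TRUE"]] / n[["TRUE"]], 0))
      )
    } else {
      keep <- !is.na(x)
      a <- x[keep & cohort$asthma]; b <- x[keep & !cohort$asthma]
      if (length(a) < 2L || length(b) < 2L) {
        th2_stop(sprintf("variable '%s' lacks data in one group", v),
                 "th2_missing_data")
      }
      res <- select_and_compare(b, a, policy = policy)  # no-asthma first
      fmt <- function(s) sprintf("%.3g +/- %.3g | %.3g (%.3g-%.3g)",
                                 s$mean, s$sd, s$median, s$q1, s$q3)
      data.frame(
        variable = v, test = res$test_name, p = res$p,
        no_asthma = fmt(res$group_summaries$a),
        asthma = fmt(res$group_summaries$b)
      )
    }
  })
  do.call(rbind, rows)
}
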