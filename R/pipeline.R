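#' Configuration for a full analysis run
#'
#' Exactly one input source: a cohort CSV path (`input`) or a synthetic
#' spec (`synthetic`). All downstream knobs are centralized here so a run
#' is fully described by its config + seed (see the manifest written by
#' [run_analysis()]).
#'
#' @param input path to a cohort CSV, or NULL.
#' @param synthetic a [cohort_spec()], or NULL.
#' @param cutoffs a [cutoff_config()].
#' @param thresholds score thresholds to report (default 1:4).
#' @param ci_method `"wilson"` or `"clopper_pearson"`.
#' @param conf_level confidence level.
#' @param policy group-comparison test-selection policy.
#' @param roc_markers cohort columns to run ROC analysis on.
#' @param logit_predictors predictor columns for the logistic model
#'   (`"sex"` is coded as female = 1).
#' @param out_dir output directory (created; must not be an existing
#'   non-empty run).
#' @param seed integer seed for cohort generation.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       cutoffs = cutoff_config(), thresholds = 1:4,
                       ci_method = "wilson", conf_level = 0.95,
                       policy = "auto_shapiro",
                       roc_markers = c("feno", "ige", "bec", "composite_score"),
                       logit_predictors = c("sex", "weight", "fev1_pct", "composite_score"),
                       out_dir, seed = 1L) {
  if (is.null(input) == is.null(synthetic)) {
    th2_stop("exactly one of `input` (CSV path) or `synthetic` (cohort_spec) is required",
             "th2_config_error")
  }
  known <- c("feno", "ige", "bec", "composite_score", "weight", "fev1_pct")
  bad <- setdiff(roc_markers, known)
  if (length(bad)) {
    th2_stop(sprintf("unknown ROC marker(s): %s", paste(bad, collapse = ", ")),
             "th2_config_error")
  }
  structure(list(input = input, synthetic = synthetic, cutoffs = cutoffs,
                 thresholds = thresholds, ci_method = ci_method,
                 conf_level = conf_level, policy = policy,
                 roc_markers = roc_markers, logit_predictors = logit_predictors,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# internal: serializable view of a config (for the manifest)
config_as_list <- function(cfg) {
  list(
    input = cfg$input,
    synthetic = if (!is.null(cfg$synthetic)) unclass_deep(cfg$synthetic),
    cutoffs = unclass(cfg$cutoffs), thresholds = cfg$thresholds,
    ci_method = cfg$ci_method, conf_level = cfg$conf_level,
    policy = cfg$policy, roc_markers = cfg$roc_markers,
    logit_predictors = cfg$logit_predictors, seed = cfg$seed
  )
}

# internal: recursively strip classes for JSON serialization
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full analysis pipeline
#'
#' Load or generate the cohort, score it, and produce the standard report:
#' group-comparison table, score-by-diagnosis cross-tabulations (full 0-4
#' table and the dichotomized table at each reporting threshold),
#' diagnostic metrics per threshold, per-marker AUC table with DeLong CIs
#' and Youden-optimal cutoffs, and the logistic model (when covariates are
#' available). Everything is written to `cfg$out_dir` as CSV plus a
#' human-readable `report.txt`, together with `manifest.json` (config,
#' seed, versions, config hash) from which the run can be regenerated
#' bit-identically. On error, partial outputs are removed.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) object of class `analysis_report` with all tables.
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- list.files(cfg$out_dir)
  if (length(created)) th2_stop("output directory is not empty", "th2_config_error")

  ok <- FALSE
  on.exit(if (!ok) unlink(cfg$out_dir, recursive = TRUE), add = TRUE)

  cohort <- if (!is.null(cfg$input)) {
    say("reading cohort from %s", cfg$input)
    read_cohort(cfg$input)
  } else {
    say("generating synthetic cohort (seed %d)", cfg$seed)
    generate_cohort(cfg$synthetic, seed = cfg$seed)
  }
  cc <- cohort_counts(cohort)
  say("cohort: %d participants, %d asthma (%s)", cc$n_total, cc$n_pos, cc$prevalence_pct)

  scored <- score_cohort(cohort, cfg$cutoffs)
  write_cohort(scored, file.path(cfg$out_dir, "scored_cohort.csv"))

  # full score x diagnosis cross-tab and per-threshold dichotomized tables
  xtab <- table(score = factor(scored$composite_score, levels = 0:4),
                asthma = scored$asthma)
  metrics <- threshold_metrics(scored, cfg$thresholds,
                               ci_method = cfg$ci_method, conf_level = cfg$conf_level)
  utils::write.csv(metrics, file.path(cfg$out_dir, "diagnostic_metrics.csv"),
                   row.names = FALSE)
  say("diagnostic metrics at thresholds %s written", paste(cfg$thresholds, collapse = ","))

  comparison <- compare_groups(scored, policy = cfg$policy)
  utils::write.csv(comparison, file.path(cfg$out_dir, "group_comparison.csv"),
                   row.names = FALSE)

  roc_rows <- lapply(cfg$roc_markers, function(mk) {
    res <- roc_auc(scored[[mk]], scored$asthma, conf_level = cfg$conf_level)
    opt <- youden_optimal(res$roc)
    data.frame(marker = mk, auc = res$auc, ci_lo = res$ci[1], ci_hi = res$ci[2],
               p = res$p, youden_cutoff = opt$cutoff, youden_j = opt$j,
               youden_sens = opt$sens, youden_spec = opt$spec)
  })
  auc_table <- do.call(rbind, roc_rows)
  utils::write.csv(auc_table, file.path(cfg$out_dir, "auc_table.csv"), row.names = FALSE)

  logit <- NULL
  predictors <- intersect(cfg$logit_predictors, names(scored))
  have <- predictors[vapply(predictors, function(v) !anyNA(scored[[v]]), logical(1))]
  if (setequal(have, cfg$logit_predictors)) {
    X <- build_design(scored, cfg$logit_predictors)
    logit <- fit_logistic(scored$asthma, X)
    logit_tab <- data.frame(
      predictor = names(logit$odds_ratios), or = logit$odds_ratios,
      ci_lo = logit$or_ci[, "lo"], ci_hi = logit$or_ci[, "hi"], wald_p = logit$wald_p
    )
    utils::write.csv(logit_tab, file.path(cfg$out_dir, "logistic_model.csv"),
                     row.names = FALSE)
    say("logistic model: chi2 %.2f on %d df, Nagelkerke R2 %.2f, %.1f%% correct",
        logit$model_chi2, logit$model_df, logit$nagelkerke_r2, 100 * logit$pct_correct)
  } else {
    say("skipping logistic model: predictor(s) missing or incomplete (%s)",
        paste(setdiff(cfg$logit_predictors, have), collapse = ", "))
  }

  manifest <- list(
    package = "th2score",
    version = as.character(utils::packageVersion("th2score")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = config_as_list(cfg),
    cohort = list(n_total = cc$n_total, n_pos = cc$n_pos, n_neg = cc$n_neg)
  )
  cfg_json <- jsonlite::toJSON(manifest$config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  report <- structure(list(
    counts = cc, cross_tab = xtab, metrics = metrics, comparison = comparison,
    auc_table = auc_table, logit = logit, manifest = manifest
  ), class = "analysis_report")
  render_report_text(report, file.path(cfg$out_dir, "report.txt"))
  ok <- TRUE
  invisible(report)
}

# internal: numeric design matrix for the logistic model (sex -> female = 1)
build_design <- function(scored, predictors) {
  cols <- lapply(predictors, function(v) {
    if (v == "sex") as.numeric(scored$sex == "female") else as.numeric(scored[[v]])
  })
  X <- do.call(cbind, cols)
  colnames(X) <- ifelse(predictors == "sex", "sex_female", predictors)
  X
}

# internal: plain-text rendering with the table conventions (percent
# one-decimal half-up, ratios one decimal)
render_report_text <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Composite Th2 score analysis report")
  w("cohort: %d participants, %d asthma (%s prevalence)",
    report$counts$n_total, report$counts$n_pos, report$counts$prevalence_pct)
  w("")
  w("Score x diagnosis cross-tabulation:")
  writeLines(utils::capture.output(print(report$cross_tab)), con)
  w("")
  w("Diagnostic metrics by threshold (percent, half-up; LR+ one decimal):")
  m <- report$metrics
  for (i in seq_len(nrow(m))) {
    w("  score >= %d: sens %s spec %s PPV %s NPV %s LR+ %s",
      m$threshold[i], render_percent(m$sensitivity[i]), render_percent(m$specificity[i]),
      render_percent(m$ppv[i]), render_percent(m$npv[i]),
      if (is.na(m$lr_pos[i])) "undef" else render_ratio(m$lr_pos[i]))
  }
  w("")
  w("AUC table:")
  a <- report$auc_table
  for (i in seq_len(nrow(a))) {
    w("  %s: AUC %.2f (CI %.2f-%.2f, p = %.3g), Youden cutoff %.4g (sens %s, spec %s)",
      a$marker[i], a$auc[i], a$ci_lo[i], a$ci_hi[i], a$p[i], a$youden_cutoff[i],
      render_percent(a$youden_sens[i], 0), render_percent(a$youden_spec[i], 0))
  }
  if (!is.null(report$logit)) {
    w("")
    w("Logistic model (OR, CI, Wald p):")
    or <- report$logit$odds_ratios; ci <- report$logit$or_ci; p <- report$logit$wald_p
    for (nm in names(or)) {
      w("  %s: OR %.2f (%.2f-%.2f), p = %.3g", nm, or[nm], ci[nm, 1], ci[nm, 2], p[nm])
    }
    w("model chi2 = %.1f on %d df (p = %.3g), Nagelkerke R2 = %.2f, %s correctly classified",
      report$logit$model_chi2, report$logit$model_df, report$logit$model_p,
      report$logit$nagelkerke_r2, render_percent(report$logit$pct_correct))
  }
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> n = %d (%d asthma) | %d thresholds | %d ROC markers%s\n",
              x$counts$n_total, x$counts$n_pos, nrow(x$metrics), nrow(x$auc_table),
              if (is.null(x$logit)) "" else " | logistic model fitted"))
  invisible(x)
}

#' Plot an empirical ROC curve
#' @param x a `roc_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$spec, x$sens, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
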