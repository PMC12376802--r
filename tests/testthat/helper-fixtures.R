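# Fixture builders shared across test files. Everything is constructed in
# code; no data files are read.

# Participants with prescribed composite scores: elevates the first `score`
# components of (feno, ige, bec, prick) so dichotomization at the default
# cutoffs reproduces the requested score exactly.
participants_with_scores <- function(scores, asthma, id_prefix = "P") {
  stopifnot(length(scores) == length(asthma), all(scores %in% 0:4))
  n <- length(scores)
  data.frame(
    id = sprintf("%s%03d", id_prefix, seq_len(n)),
    asthma = asthma,
    feno = ifelse(scores >= 1, 30, 10),
    ige = ifelse(scores >= 2, 150, 50),
    bec = ifelse(scores >= 3, 200, 100),
    prick = scores >= 4,
    stringsAsFactors = FALSE
  )
}

# 48-participant cohort whose score/diagnosis cross-tab at threshold 3 is
# (tn 25, fn 14 / fp 1, tp 8): 25 non-asthmatic at score <= 2 plus 1 at
# score 3; 14 asthmatic at score <= 2 plus 8 at score >= 3.
table2_cohort <- function(covariates = FALSE) {
  scores_neg <- c(rep(0, 10), rep(1, 10), rep(2, 5), 3)
  scores_pos <- c(rep(0, 4), rep(1, 5), rep(2, 5), rep(3, 6), rep(4, 2))
  df <- participants_with_scores(
    c(scores_neg, scores_pos),
    c(rep(FALSE, length(scores_neg)), rep(TRUE, length(scores_pos)))
  )
  if (covariates) {
    n <- nrow(df)
    df$sex <- rep(c("male", "female"), length.out = n)
    df$weight <- 60 + (seq_len(n) * 7) %% 25
    df$fev1_pct <- 95 + (seq_len(n) * 11) %% 35
  }
  as_cohort(df, provenance = "table2 fixture")
}

# brute-force two-sided Fisher p: lchoose tail summation, independent of the
# dhyper-based implementation
fisher_oracle <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  p <- exp(logp)
  sum(p[p <= p[k == a] * (1 + 1e-7)])
}

# brute-force AUC by pairwise comparison (ties count 1/2)
auc_pairwise_oracle <- function(values, labels) {
  pos <- values[labels]; neg <- values[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# brute-force ROC operating points: per-threshold counting
roc_sweep_oracle <- function(values, labels, thresholds) {
  pos <- values[labels]; neg <- values[!labels]
  data.frame(
    threshold = thresholds,
    sens = vapply(thresholds, function(t) mean(pos >= t), numeric(1)),
    spec = vapply(thresholds, function(t) mean(neg < t), numeric(1))
  )
}

expect_th2_error <- function(expr, class) {
  expect_error(expr, class = class)
}
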