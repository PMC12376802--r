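test_that("confusion_table counts the four cells and preserves margins", {
  scored <- score_cohort(table2_cohort())
  ct <- confusion_table(classify(scored$composite_score, 3), scored$asthma)
  expect_equal(ct$tp, 8L); expect_equal(ct$fn, 14L)
  expect_equal(ct$fp, 1L); expect_equal(ct$tn, 25L)
  expect_equal(ct$n, 48L)

  truth <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  perfect <- confusion_table(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0L)
  none <- confusion_table(rep(FALSE, 5), truth)
  expect_equal(none$tp + none$fp, 0L)
  expect_th2_error(confusion_table(c(TRUE, FALSE), TRUE), "th2_argument_error")
})

test_that("diagnostic_metrics reproduces the score >2 operating point and a hand oracle", {
  m <- diagnostic_metrics(new_confusion_table(tp = 8, fp = 1, fn = 14, tn = 25))
  expect_equal(m$sensitivity$estimate, 8 / 22, tolerance = 1e-12)
  expect_equal(m$specificity$estimate, 25 / 26, tolerance = 1e-12)
  expect_equal(m$ppv$estimate, 8 / 9, tolerance = 1e-12)
  expect_equal(m$npv$estimate, 25 / 39, tolerance = 1e-12)
  expect_equal(m$lr_pos$estimate, (8 / 22) / (1 / 26), tolerance = 1e-12)
  # one-decimal half-up rendering matches the published presentation
  expect_equal(render_percent(m$sensitivity$estimate), "36.4%")
  expect_equal(render_percent(m$specificity$estimate), "96.2%")
  expect_equal(render_percent(m$ppv$estimate), "88.9%")
  expect_equal(render_percent(m$npv$estimate), "64.1%")
  expect_equal(render_ratio(m$lr_pos$estimate), "9.5")

  # hand-arithmetic oracle
  h <- diagnostic_metrics(new_confusion_table(tp = 3, fp = 2, fn = 1, tn = 4))
  expect_equal(h$sensitivity$estimate, 0.75)
  expect_equal(h$specificity$estimate, 2 / 3)
  expect_equal(h$ppv$estimate, 0.6)
  expect_equal(h$npv$estimate, 0.8)
  expect_equal(h$lr_pos$estimate, 2.25)
  expect_equal(h$youden_j, 0.75 + 2 / 3 - 1)

  # perfect classifier: LR+ undefined at specificity 1, flagged not fabricated
  p <- diagnostic_metrics(new_confusion_table(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(p$sensitivity$estimate, 1)
  expect_equal(p$specificity$estimate, 1)
  expect_equal(p$youden_j, 1)
  expect_false(p$lr_pos$defined)
  expect_match(p$lr_pos$reason, "specificity is 1")
})

test_that("Bayes consistency: PPV equals the prevalence-weighted form; LR+ vs J", {
  set.seed(31)
  for (i in 1:200) {
    cells <- as.integer(stats::rmultinom(1, sample(8:80, 1), stats::runif(4, 0.05, 1)))
    if (any(c(cells[1] + cells[3], cells[2] + cells[4],
              cells[1] + cells[2], cells[3] + cells[4]) == 0)) next
    ct <- new_confusion_table(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4])
    m <- diagnostic_metrics(ct)
    prev <- (ct$tp + ct$fn) / ct$n
    sens <- m$sensitivity$estimate; spec <- m$specificity$estimate
    if (m$ppv$defined && sens * prev + (1 - spec) * (1 - prev) > 0) {
      expect_equal(m$ppv$estimate,
                   sens * prev / (sens * prev + (1 - spec) * (1 - prev)),
                   tolerance = 1e-12)
    }
    if (m$lr_pos$defined) {
      expect_equal(m$lr_pos$estimate >= 1, m$youden_j >= 0)
    }
  }
})

test_that("Wilson and Clopper-Pearson contain the point estimate; CP never narrower inside", {
  # the width ordering holds for interior counts; at x = 0 or x = n with
  # n >= 46 the exact one-sided bound 1 - (alpha/2)^(1/n) ~ 3.69/n is
  # genuinely tighter than Wilson's z^2/(n + z^2) ~ 3.84/n, so the boundary
  # is excluded from the width comparison (containment still checked)
  set.seed(32)
  for (i in 1:100) {
    n <- sample(1:60, 1); x <- sample(0:n, 1)
    w <- ci_wilson(x, n); cp <- ci_clopper_pearson(x, n)
    expect_true(w[1] <= x / n + 1e-12 && x / n <= w[2] + 1e-12)
    expect_true(cp[1] <= x / n + 1e-12 && x / n <= cp[2] + 1e-12)
    if (x > 0 && x < n) {
      expect_gte((cp[2] - cp[1]) - (w[2] - w[1]), -1e-9)
    }
  }
})

test_that("metrics_from_rates reconstructs integer tables half-up", {
  r <- metrics_from_rates(0.545, 0.808, 22, 26)
  expect_equal(unlist(r$table[c("tp", "fn", "fp", "tn")]),
               c(tp = 12L, fn = 10L, fp = 5L, tn = 21L))
  expect_equal(render_percent(r$ppv), "70.6%")
  expect_equal(render_percent(r$npv), "67.7%")
  expect_equal(render_ratio(r$lr_pos), "2.8")

  perfect <- metrics_from_rates(1, 1, 5, 5)
  expect_equal(perfect$ppv, 1); expect_equal(perfect$npv, 1)

  h <- metrics_from_rates(0.6, 0.7, 10, 10)
  expect_equal(h$table$tp, 6L); expect_equal(h$table$fp, 3L)
  expect_equal(h$ppv, 6 / 9, tolerance = 1e-12)

  # empty predicted-positive margin flags PPV undefined
  z <- metrics_from_rates(0, 1, 5, 5)
  expect_false(z$ppv_defined)
  expect_true(is.na(z$ppv))
})

test_that("fisher_exact: known tables and degenerate margins", {
  t2 <- fisher_exact(matrix(c(25, 1, 14, 8), 2, 2))
  expect_lt(t2$p, 0.01)
  expect_equal(t2$p, fisher_oracle(matrix(c(25, 1, 14, 8), 2, 2)), tolerance = 1e-12)

  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p, 1)
  # doubled-tail 3,0 / 0,3: 2 * C(3,3)C(3,0)/C(6,3) = 0.1
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2, 2))$p, 0.1, tolerance = 1e-12)

  expect_warning(deg <- fisher_exact(matrix(c(0, 0, 3, 4), 2, 2)), "degenerate")
  expect_equal(deg$p, 1)
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  set.seed(33)
  for (i in 1:150) {
    m <- matrix(sample(0:25, 4, TRUE), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("chi_square_test: closed forms, published prick comparison, reference match", {
  flat <- chi_square_test(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(flat$statistic, 0); expect_equal(flat$p, 1)

  h <- chi_square_test(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(h$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)  # 6.667 on df 1
  expect_equal(h$df, 1L)

  # prick-positivity contrast between the groups (2/24 vs 12/10)
  prick <- chi_square_test(matrix(c(2, 12, 24, 10), 2, 2))
  expect_lt(prick$p, 0.01)

  set.seed(34)
  for (i in 1:50) {
    m <- matrix(sample(1:30, 6, TRUE), 2, 3)
    ours <- chi_square_test(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # Yates correction against the reference implementation
  m <- matrix(c(12, 5, 6, 14), 2, 2)
  expect_equal(chi_square_test(m, correct = TRUE)$statistic,
               unname(stats::chisq.test(m, correct = TRUE)$statistic),
               tolerance = 1e-10)
  expect_th2_error(chi_square_test(matrix(c(0, 0, 1, 2), 2, 2)), "th2_degenerate_table")
})

test_that("threshold_metrics lays out one row per threshold with undefineds as NA", {
  tm <- threshold_metrics(score_cohort(table2_cohort()))
  expect_equal(tm$threshold, 1:4)
  expect_equal(tm$tp[3], 8)
  expect_equal(tm$sensitivity[3], 8 / 22, tolerance = 1e-12)
  expect_true(is.na(tm$lr_pos[4]))  # specificity 1 at threshold 4 here
})
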