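test_that("lognormal_from_quartiles: closed-form fits and degenerate input", {
  f <- lognormal_from_quartiles(24.1, 11.2, 43.9)
  expect_equal(f$mu, log(24.1), tolerance = 1e-12)
  expect_equal(f$sigma, log(43.9 / 11.2) / (2 * stats::qnorm(0.75)), tolerance = 1e-12)
  expect_equal(f$mu, 3.182, tolerance = 1e-3)
  expect_equal(f$sigma, 1.013, tolerance = 1e-3)

  g <- lognormal_from_quartiles(20, 17, 26)
  expect_equal(g$mu, 2.996, tolerance = 1e-3)
  expect_equal(g$sigma, 0.315, tolerance = 1e-3)

  expect_warning(d <- lognormal_from_quartiles(5, 5, 5), "degenerate")
  expect_equal(d$sigma, 0)

  expect_th2_error(lognormal_from_quartiles(-1, 1, 2), "th2_argument_error")
  expect_th2_error(lognormal_from_quartiles(10, 12, 14), "th2_argument_error")
})

test_that("quartile round trip: median always, quartiles exactly when log-symmetric", {
  set.seed(71)
  for (i in 1:20) {
    med <- stats::runif(1, 5, 200)
    ratio <- stats::runif(1, 1.1, 4)
    q1 <- med / ratio; q3 <- med * ratio  # log-symmetric triple
    f <- lognormal_from_quartiles(med, q1, q3)
    expect_equal(exp(f$mu), med, tolerance = 1e-10)
    expect_equal(f$log_asymmetry, 0, tolerance = 1e-10)
    expect_equal(stats::qlnorm(0.25, f$mu, f$sigma), q1, tolerance = 1e-8)
    expect_equal(stats::qlnorm(0.75, f$mu, f$sigma), q3, tolerance = 1e-8)
  }
  # asymmetric printed quartiles: median preserved, asymmetry diagnosed
  f <- lognormal_from_quartiles(15, 11, 22)
  expect_equal(exp(f$mu), 15, tolerance = 1e-10)
  expect_gt(abs(f$log_asymmetry), 0)
})

test_that("generate_cohort is deterministic and structurally valid", {
  spec <- cohort_spec(seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_s3_class(c1, "th2_cohort")
  expect_equal(nrow(c1), 48L)
  expect_equal(sum(c1$asthma), 22L)
  expect_true(all(c1$feno > 0 & c1$ige > 0 & c1$bec > 0))
  # a different seed changes the draw
  expect_false(identical(c1$ige, generate_cohort(spec, seed = 100)$ige))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_cohort(spec)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("generated marginals recover the specified medians and prick rates", {
  # scaled to n = 2e5 per group: median tolerance scales as ~1/sqrt(n) from
  # the stated (1e6, +/-0.5) contract; prick rate checked at +/-0.004
  spec <- cohort_spec(n_no_asthma = 2e5, n_asthma = 2e5, covariates = FALSE, seed = 123)
  big <- generate_cohort(spec)
  neg <- big[!big$asthma, ]; pos <- big[big$asthma, ]
  expect_equal(stats::median(neg$ige), 24.1, tolerance = 0.5 / 24.1)
  expect_equal(stats::median(pos$ige), 67.7, tolerance = 1.5 / 67.7)
  expect_equal(stats::median(neg$feno), 15, tolerance = 0.3 / 15)
  expect_equal(stats::median(pos$feno), 20, tolerance = 0.3 / 20)
  expect_equal(mean(neg$prick), 2 / 26, tolerance = 0.004 / (2 / 26))
  expect_equal(mean(pos$prick), 12 / 22, tolerance = 0.004 / (12 / 22))

  # rho = 0: log-marker correlations vanish
  lm_cor <- stats::cor(cbind(log(neg$feno), log(neg$ige), log(neg$bec)))
  expect_lt(max(abs(lm_cor[upper.tri(lm_cor)])), 0.01)
})

test_that("positive copula rho induces the requested latent correlation", {
  spec <- cohort_spec(n_no_asthma = 5e4, n_asthma = 1, copula_rho = 0.3,
                      covariates = FALSE, seed = 7)
  co <- generate_cohort(spec)
  neg <- co[!co$asthma, ]
  r <- stats::cor(log(neg$feno), log(neg$ige))
  expect_equal(r, 0.3, tolerance = 0.05)
  expect_th2_error(cohort_spec(copula_rho = -0.5), "th2_argument_error")
})

test_that("closed-form AUC matches analytic examples and the degenerate branch", {
  f0 <- lognormal_from_quartiles(24.1, 11.2, 43.9)
  f1 <- lognormal_from_quartiles(67.7, 27.4, 175.8)
  expect_equal(expected_auc_lognormal(f0, f0), 0.5)
  expect_equal(expected_auc_lognormal(f0, f1), 0.727, tolerance = 1e-3)
  e0 <- lognormal_from_quartiles(15, 11, 22)
  e1 <- lognormal_from_quartiles(20, 17, 26)
  expect_equal(expected_auc_lognormal(e0, e1), 0.683, tolerance = 1e-3)

  suppressWarnings({
    p5 <- lognormal_from_quartiles(5, 5, 5)
    p9 <- lognormal_from_quartiles(9, 9, 9)
  })
  expect_equal(expected_auc_lognormal(p5, p9), 1)
  expect_equal(expected_auc_lognormal(p9, p5), 0)
  expect_equal(expected_auc_lognormal(p5, p5), 0.5)
})

test_that("empirical AUC on generated data converges to the closed form", {
  spec <- cohort_spec(n_no_asthma = 1e5, n_asthma = 1e5, covariates = FALSE, seed = 31)
  co <- generate_cohort(spec)
  fits <- default_marker_fits()
  for (mk in c("ige", "feno", "bec")) {
    emp <- roc_auc(co[[mk]], co$asthma)$auc
    expect_equal(emp, expected_auc_lognormal(fits$no_asthma[[mk]], fits$asthma[[mk]]),
                 tolerance = 0.01)
  }
})

test_that("score separation at defaults: medians ordered, specificity monotone", {
  # composite-score median (asthma) >= median (no asthma) at default settings
  spec_med <- cohort_spec(n_no_asthma = 2e4, n_asthma = 2e4, covariates = FALSE, seed = 5)
  sc <- score_cohort(generate_cohort(spec_med))
  expect_gte(stats::median(sc$composite_score[sc$asthma]),
             stats::median(sc$composite_score[!sc$asthma]))

  # full-pipeline smoke property at study size: spec(t=3) >= spec(t=2) for
  # every seed, strictly greater in >= 95% of seeds
  strict <- logical(200)
  for (s in seq_len(200)) {
    sc <- score_cohort(generate_cohort(cohort_spec(covariates = FALSE), seed = s))
    tm <- threshold_metrics(sc, thresholds = c(2, 3))
    expect_gte(tm$specificity[2], tm$specificity[1])
    strict[s] <- tm$specificity[2] > tm$specificity[1]
  }
  expect_gte(mean(strict), 0.95)
})
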