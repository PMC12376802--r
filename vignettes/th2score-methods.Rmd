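---
title: "Methods: the composite Th2 score, its evaluation battery, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the composite Th2 score, its evaluation battery, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(th2score)
```

## The model

Asthma screening in elite aquatic athletes relies on four markers of
T-helper-2 (Th2) airway inflammation that are accessible outside specialist
centres: blood eosinophil count (BEC, cells/µL), total serum IgE (IU/mL),
fractional exhaled nitric oxide (FENO, ppb), and skin prick positivity.
`th2score` implements the composite rule

$$S = \mathbf{1}[\mathrm{BEC} \ge 150] + \mathbf{1}[\mathrm{IgE} \ge 100] +
      \mathbf{1}[\mathrm{FENO} \ge 25] + \mathbf{1}[\text{prick positive}]
      \in \{0, \dots, 4\},$$

with test-positivity defined as $S \ge t$. All cutoff comparisons are
inclusive: a value exactly at the cutoff scores 1. Representing the decision
rule as "$\ge t$" resolves the ">2 points" vs "2 points" ambiguity once at
the API boundary: the balanced operating point is $t = 2$ and the rule-in
point is $t = 3$. The cutoffs are clinical conventions (the FENO cutoff of
25 ppb is the lower edge of the "intermediate" band in respiratory practice
guidelines, chosen to catch even mild eosinophilic inflammation in athletes
whose performance is sensitive to small impairments), not fitted
quantities; they are configurable through `cutoff_config()`.

Participants missing any panel component are excluded from score-based
analyses with a logged count, never imputed: a partial sum of indicators
would silently change the meaning of every threshold.

## Diagnostic accuracy machinery

`confusion_table()` + `diagnostic_metrics()` compute the standard panel
from 2×2 counts: sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$, PPV,
NPV, LR+ $= \mathrm{sens}/(1-\mathrm{spec})$, LR−, accuracy, Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$. Any ratio with a zero denominator
(e.g. LR+ of a perfectly specific test) is flagged `undefined` with a
reason rather than given a fabricated value.

Proportion intervals default to Wilson at 95% (Clopper–Pearson available);
the source study reported no intervals, so the choice is free and surfaced
in configuration. One point discovered by the property suite is worth
recording: Clopper–Pearson is *not* universally at least as wide as Wilson
— at boundary counts ($x = 0$ or $x = n$) with $n \ge 46$ the exact
one-sided bound $1 - (\alpha/2)^{1/n} \approx 3.69/n$ undercuts Wilson's
$z^2/(n + z^2) \approx 3.84/n$. The width-ordering test therefore covers
interior counts only. Likelihood-ratio intervals use the usual log-scale
normal construction.

`metrics_from_rates()` answers a reader's problem: given only printed
sensitivity/specificity and the group sizes, rebuild the implied integer
2×2 table (rounding half up, which is how 0.545·22 becomes 12 of 22) and
derive the predictive values and LR+ from those integers. Rounding half
*up* rather than R's round-half-even is deliberate and centralized
(`round_half_up()`, `render_percent()`): clinical tables round 45.83% to
46%, and 11.99 to 12.

`fisher_exact()` computes the two-sided p by full enumeration over the
feasible cell range with fixed margins, summing hypergeometric
probabilities at most that of the observed table (relative tolerance 1e-7
for float ties) — the "sum of less-probable tables" convention of standard
software. The acceptance suite sweeps *every* 2×2 table with $n \le 60$
against an independent `lchoose`-based oracle. `chi_square_test()` is the
Pearson statistic without continuity correction by default (Yates
available for 2×2).

## ROC and Youden analysis

`empirical_roc()` uses the unique observed values (plus a $+\infty$
sentinel) as candidate cutoffs with the same inclusive "$\ge$" rule as the
score — no midpoint interpolation, so integer markers yield integer
cutoffs. Tied values collapse to one operating point. `roc_auc()` computes
the area twice, by trapezoidal integration of that curve and by the
Mann–Whitney pair statistic with ties counting ½, and *errors* if the two
disagree beyond 1e-10: the identity is an internal consistency contract,
not just a test. The DeLong placement variance gives the default CI and
the p-value against AUC = 0.5; a stratified bootstrap percentile interval
is optional. Orientation defaults to higher-positive for all four markers
— including BEC, whose near-chance AUC in this population is reported as
observed rather than flipped.

`youden_optimal()` maximizes $J$ over the curve's cutoffs with a fixed,
documented tie-break: higher specificity first, then the lower threshold.
The source data are silent on tie handling; determinism matters more here
than the particular choice.

## Group comparisons

`select_and_compare()` implements the "t test or Mann–Whitney according to
distribution" policy explicitly: a Shapiro–Wilk gate at α = 0.05 per group
(groups smaller than 3 fail the gate) selects Welch's t (Student optional —
the source does not say which unpaired t was used) or the Mann–Whitney U.
The Mann–Whitney implementation computes U with midranks; the exact
two-sided p enumerates the complete null distribution of U over all
$\binom{m+n}{m}$ rank assignments (cached per $(m, n)$) when there are no
ties and $mn \le 100$, and otherwise uses the normal approximation with
tie-corrected variance and continuity correction. Because the null
distribution of U is symmetric, the "both tails at least as extreme"
definition used here coincides with the doubled-tail convention. Published
per-variable p-values are not reproduction targets: they require the
individual-level data.

## Logistic regression

`fit_logistic()` is a from-scratch IRLS (Newton–Raphson on the binomial
log-likelihood) with step-halving whenever a full step would decrease the
likelihood; convergence requires the score norm below `tol` (default 1e-8,
`max_iter` 50). Standard errors come from the inverse observed information;
odds-ratio CIs are exponentiated Wald intervals; model-level statistics are
the LRT chi-square against the intercept-only model (whose MLE has the
closed form $\mathrm{logit}(\bar y)$), Nagelkerke's
$R^2 = R^2_{CS} / (1 - e^{2\ell_0/n})$ with
$R^2_{CS} = 1 - e^{2(\ell_0-\ell)/n}$, and the fraction correctly
classified at probability 0.5. Quasi-separation (fitted probabilities at
the 1e-10 boundaries, or coefficients beyond ±15 on the log-odds scale) is
reported as `converged = FALSE` with a warning: a stalled score at
saturated probabilities is not an interior maximum. The composite score
enters models as a single numeric predictor — each increment multiplies the
odds by a constant factor — matching how the score is interpreted
clinically; dummy-coding the five levels is deliberately not offered.

One internal inconsistency in the source results is worth noting: a model
chi-square of 14.5 on 4 predictors implies p ≈ 0.006, not the printed 0.04.
The package always reports the LRT statistic together with its df and the
implied p, and the printed pair is not a target anywhere.

## The synthetic cohort: a stated world

Published results give only group-level summaries, so the generator
reconstructs a population consistent with them and nothing more:

* **Marginals.** IgE, FENO and BEC are right-skewed and reported as
  median (IQR), so each group-marker pair gets a log-normal with
  $\mu = \ln(\text{median})$ (median preserved exactly) and
  $\sigma = \ln(q_3/q_1) / (2 z_{0.75})$ (log-IQR width matched). When the
  printed quartiles are not log-symmetric the residual is quantified by the
  `log_asymmetry` diagnostic rather than hidden. Calibration values
  (defaults of `cohort_spec()`): IgE 24.1 (11.2–43.9) vs 67.7 (27.4–175.8)
  IU/mL, FENO 15 (11–22) vs 20 (17–26) ppb, BEC 140 (80–190) vs
  110 (80–190) cells/µL for the non-asthmatic vs asthmatic groups.
* **Prick positivity.** Bernoulli at the printed group rates 2/26 and
  12/22.
* **Dependence.** A Gaussian copula over the three log-markers and the
  latent prick variable, exchangeable correlation `copula_rho`. The true
  dependence is unknowable from group summaries, so the default is 0; 0.3
  is a plausible positive preset (the markers share the Th2 pathway) and is
  flagged as an assumption wherever it is used.
* **Covariates.** Sex Bernoulli(½); weight and baseline FEV₁ %pred
  Gaussian at the printed group means ± SD (66.1 ± 11 / 73.0 ± 13 kg and
  116.0 ± 14.3 / 104.7 ± 10.5%), truncated at physiologic floors. These
  exist to exercise the logistic model, not to model athlete physiology.
* **Sizes and seed.** Defaults 26 + 22, the study's group sizes. Every draw
  is seeded; the caller's RNG state is restored afterwards.

The closed-form check `expected_auc_lognormal()` —
$\Phi\big((\mu_1-\mu_0)/\sqrt{\sigma_0^2+\sigma_1^2}\big)$ — gives 0.727
for the IgE calibration and 0.683 for FENO, bracketing the published AUCs
of 0.72 and 0.70; the acceptance suite confirms the empirical AUCs at
$10^5$ per group land within ±0.02 / ±0.03 of the published values.

**What a green test does and does not establish.** The generator matches
group-wise marginals and rates. It does not reproduce within-participant
correlation structure, measurement error, the discreteness of small-sample
data, or any selection effects in athlete referral. Tests that pass on
synthetic cohorts validate the *pipeline's arithmetic and contracts*, not
the clinical performance of the score in new populations.

### A deliberate red: the Youden calibration criterion

The acceptance suite includes one criterion that the stated world cannot
meet, kept failing on purpose. Under the quartile-calibrated log-normals,
the IgE threshold maximizing $J(c) = \Phi\!\big(\tfrac{\mu_1 - \ln
c}{\sigma_1}\big) - \Phi\!\big(\tfrac{\mu_0 - \ln c}{\sigma_0}\big)$ sits
near $\ln c \approx 3.99$ (≈ 54 IU/mL), with operating point
(sens ≈ 0.57, spec ≈ 0.79). The published optimum — cutoff 30 IU/mL with
77%/65% — has $J = 0.42$, *above* the model's maximum of ≈ 0.35: the
48-participant empirical ROC is lumpier than any smooth log-normal pair
fitted to its quartiles. At the published cutoff of 30 the model's
operating point (0.72, 0.59) is within 10 points of the published pair; the
model's own optimum is not. Moving σ or the seed until the test passed
would be calibration-to-the-answer, so the criterion stays red with this
explanation.

## Numerical and design choices

* Quartiles: linear interpolation between order statistics (type 7), the
  common software default; configurable in `summarize_group()`. The source
  convention is unstated, and its printed IQRs are treated as inputs, not
  recomputation targets.
* Rendering: percentages one decimal half-up ("36.4%"), prevalence integer
  half-up ("46%"), likelihood ratios one decimal — centralized so printed
  formats are testable in one place.
* Fisher float ties: relative tolerance 1e-7 when comparing table
  probabilities, absorbing rounding in the hypergeometric tail sums.
* Mann–Whitney exact bound: full enumeration up to $mn \le 100$; beyond
  that the tie-corrected normal approximation (which agrees with the exact
  p within 0.02 at $n = 10 + 10$ in the cross-check).
* IRLS: tol 1e-8 on the score norm, max 50 iterations, step-halving floor
  $2^{-20}$ — conventional safeguards; the source is silent.
* CLI configs are JSON (the deployment environment has no YAML parser);
  all CLI tables are CSV plus a plain-text rendering, and every `run`
  writes a manifest (config, seed, versions, md5 of the serialized config)
  from which the run regenerates bit-identically.

## Known limitations

* The generator's independence default almost certainly understates the
  real correlation among Th2 markers; composite-score distributions under
  `copula_rho = 0` will be slightly more dispersed than reality.
* Published odds ratios (2.71 per score increment, and the covariate ORs)
  are used only as generating effect sizes for recovery tests — the Wald CI
  covers the generating OR at the nominal rate — never as point targets,
  since they depend on the unavailable individual-level data.
* No multiplicity adjustment, paired designs, >2 groups, partial AUC, or
  penalized (Firth) regression; separation is detected and reported, not
  repaired.
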