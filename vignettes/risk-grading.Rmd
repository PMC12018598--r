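---
title: "Methods: histological risk grading for inguinal lymph node metastasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histological risk grading for inguinal lymph node metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penrisk)
```

## The grading model

Penile squamous cell carcinoma metastasises first to the inguinal
nodes, and nodal status drives both treatment and survival. Because
imaging cannot detect micrometastases, risk grading of the primary
tumour decides which clinically node-negative patients undergo invasive
nodal staging. The established European Association of Urology (EAU)
stratification uses pT stage and WHO grade; WHO grading of these
tumours is subjective, with poor inter-pathologist agreement.

The grading implemented here replaces grade with four more objective
histological features of the primary tumour, following the
Brandwein-Gensler tradition of multivariable histologic risk models in
squamous cell carcinoma. Each feature contributes points:

* worst pattern of invasion (WPOI): +1 for type 4 only (dissociated
  islands of ≤ 15 cells at the invasion front); types 1–3 score 0;
* lymphocytic host response (LHR): 0 / +1 / +2 for type 1 (dense
  peritumoral infiltrate with lymphoid nodules in every low-power
  field), type 2 (nodules in some fields), type 3 (little or none);
* lymphovascular invasion (LVI): +1 when present;
* perineural invasion (PNI): +1 when present.

The total score $s \in \{0,\dots,5\}$ maps deterministically to the
risk group: low ($s = 0$), intermediate ($s \in \{1,2\}$), high
($s \ge 3$). `risk_score()` and `risk_group_from_score()` implement
exactly this and nothing else — the proposed system never consults
stage or grade, and the EAU classifier (`eau_risk_group()`: pTa and
pT1 G1 low, pT1 G2 intermediate, everything beyond high) never
consults the four features. `subclassify_pt1()` carries the TNM pT1a/b
split (G1–G2 without LVI/PNI vs G3 or either invasion). pTis is
rejected: the grading targets invasive carcinoma, and no rule for
in-situ disease exists. pT4 is accepted (EAU high) although the
development cohort contained none.

## The development-cohort fixture

The per-patient data behind the published evaluation (306 patients,
102 with nodal metastasis at diagnosis) is not public. All headline
statistics are, however, exactly recomputable from the published
aggregates, and `reference_counts()` encodes that reconstruction:
LNM-positive counts per group are `round(rate × group size)`, giving
2/35/65 of 111/110/85 (proposed) and 0/10/92 of 31/55/220 (EAU), each
cross-checked to sum to the cohort's 102 metastases. The source tables
disagree about two proposed group sizes (106/89 in one table vs 110/85
in the stratification count); the fixture follows the counts that
reproduce the published odds ratios and diagnostic metrics to every
printed decimal, and records the discrepancy here rather than
resolving it.

`expand_counts()` materialises a pseudo-cohort realising both
contingency tables at once. Within each outcome stratum, patients are
allocated to (proposed group, EAU group) cells by a deterministic
northwest-corner transport plan — any plan consistent with both
margins is admissible since the true joint cross-classification was
never published — and receive a fixed canonical feature profile for
their score and the minimal staging (pT1 G1 / pT1 G2 / pT2) for their
EAU group. Consequences worth knowing: re-tabulating the pseudo-cohort
reproduces both published tables exactly, but the between-system kappa
(0.149 on this allocation) and the pT-stage distribution are artefacts
of the allocation, not reproductions; the published kappa (0.16) and
the stage-adjusted odds ratios require the unpublished joint data and
are deliberately out of the reproduction report.

## Evaluation statistics and their conventions

**Dichotomisation.** Diagnostic metrics compare the low risk group
(test-negative) against intermediate and high pooled (test-positive),
the clinically meaningful cut: surveillance vs surgery.

**Confidence intervals for proportions.** The published intervals
follow a nonstandard convention: a Wald interval whose variance
denominator is the full cohort size $n = 306$ for every metric,
$p \pm z\sqrt{p(1-p)/n}$. We verified this against every printed
interval to all decimals (e.g. specificity 53.43, 47.84–59.02; PPV
51.28, 45.68–56.88). `diagnostic_metrics()` therefore offers three
conventions — `cohort_n` (reproduction), `wald` (each metric's own
denominator), `wilson` — computes all three in `evaluate_cohort()`,
and labels every output with the convention used, so the nonstandard
interval is never propagated silently. Intervals are clipped to
[0, 1]; a zero-denominator metric is `NA` with a note, never 0.

**z quantile.** Fixed internally at 1.959964 rather than 1.96; the
reproduced values match the published ones at either precision after
rounding to two decimals.

**Rounding.** Reproduction reports round half-up to two decimals,
matching the published presentation (plain `round()` would turn
177.125 into 177.12, not the printed 177.13). The published AUCs were
evidently rounded in two stages — the EAU AUC of the reconstructed
counts is 0.6447, which prints as 0.65 only via 0.645, and its
published interval (0.58–0.71) indeed centres on 0.645 —
so `reproduction_report()` applies half-up rounding at three then two
decimals to AUC rows, and documents that here.

**Odds ratios.** Closed form $ad/bc$ with the Wald log-scale interval.
A zero metastasis cell in a group (the EAU low risk group) yields OR 0
or ∞ with an unbounded interval, reported with a note, matching how
the published comparison reports "0.00 (0.00–infinity)"; an optional
Haldane–Anscombe +0.5 correction is available but off by default. The
regression route (`fit_logistic()`) is an ordinary maximum-likelihood
logistic fit (IRLS; relative deviance change < 1e-10 or 50
iterations; deterministic start) with reference-coded groups (low
risk, pT1 reference). For the one-factor saturated model it agrees
with the closed form to ≤ 1e-6 relative, which the tests assert
property-style. Separation is detected from boundary fitted
probabilities and runaway standard errors and reported on the affected
terms instead of being passed off as an ordinary fit.

**Ordinal AUC.** With a 3-level test, the ROC has three interior
points and the area equals the tie-corrected Mann–Whitney statistic
$\mathrm{AUC} = (\#\text{concordant} + \tfrac12\#\text{ties})/(n_+ n_-)$,
computed directly on the contingency counts: 17846.5/20808 = 0.8577
(proposed) and 13415/20808 = 0.6447 (EAU). The interval uses the
Hanley–McNeil approximation; the published account is internally
inconsistent about its AUC interval (0.81–0.89 in one place, 0.82–0.9
in another) and never states a method, so the interval is documented
as ours and is not part of the reproduction report.

**Association tests.** Pearson chi-square without continuity
correction on the 3×2 table, with automatic fallback to Fisher's exact
test whenever any expected cell drops below 5 (threshold
configurable); empty groups are dropped with a warning, or rejected in
strict mode. The fallback is validated in the tests against exhaustive
hypergeometric enumeration.

**Kappa.** Unweighted Cohen's kappa, with the degenerate case (both
labelings constant and identical, $p_e = 1$) flagged as undefined.

## The synthetic-cohort generator

`simulate_cohort()` exists so the entire pipeline is testable without
any external data. Its defaults are the development cohort's published
margins: WPOI type frequencies (2.6 / 17.3 / 44.1 / 36.0%), LHR
(57.5 / 30.0 / 12.5%), LVI 36.6%, PNI 27.8%, pT stage (35.6 / 41.2 /
23.2% over pT1–pT3), age normal with mean 67.8, sd 10.6, truncated
above 18 years. The WHO grade distribution was never published; it
defaults to uniform over G1–G3, an explicitly arbitrary choice.
Metastasis follows the dose-response the grading is predicated on:
$P(\text{LNM} \mid s) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 s)$.
Randomness is confined to one seeded generator per call (the caller's
RNG state is untouched), and the seed is mandatory.

**What the generator does not emulate.** Features are drawn
independently: only marginal frequencies were published, so any
correlation structure would be invented. The real features are clearly
correlated — independence implies P(score = 0) = 0.169 where the real
cohort has 111/306 = 0.363 — so simulated group sizes and any statistic
sensitive to the joint feature distribution will differ from the real
cohort. Passing tests on synthetic data demonstrate the pipeline's
internal correctness under the generator's own model, not fidelity to
real pathology data.

**Calibration.** `calibrate_lnm_model()` chooses $(\beta_0, \beta_1)$
by unweighted least squares so that the expected within-group
metastasis rates — averaging $P(\text{LNM} \mid s)$ over the exact
score distribution implied by the marginals (`score_distribution()`,
a 48-cell enumeration) — approximate target rates, via a coarse grid
($\beta_0 \in [-10, 2]$ by 0.5, $\beta_1 \in [0, 6]$ by 0.25) refined
by Nelder-Mead (relative tolerance 1e-12). With the default targets
(1.8 / 31.8 / 76.5%) the two-parameter model cannot match all three
rates under the independence-implied score distribution: a grid scan
shows the smallest achievable maximum absolute deviation is 0.0297,
and the least-squares optimum leaves the low risk group about 0.04
high (the other two within 0.02). The function therefore returns the
`achieved` rates alongside the coefficients, and that vector — not the
targets — is the contract simulations are held to: at n = 20,000 the
simulated group rates match the achieved rates well within 0.03
(tested), while the low-group deviation from the *target* is a
structural property of the independence simplification, not a sampling
artefact. The package keeps the published targets as defaults rather
than quietly substituting reachable ones.

## Numerical and design choices

* Problem sizes in the tests: fixture statistics are exact at n = 306;
  parameter-recovery simulations use n = 5,000; marginal- and
  rate-recovery checks n = 20,000; null-association replication 40
  seeds at n = 400. These sizes make every Monte-Carlo tolerance an
  explicit multiple of the binomial standard error.
* Ties in the ordinal AUC carry weight one half; this equals the
  trapezoidal area of the empirical ROC, and is asserted against both
  a pairwise enumeration oracle and an independent ROC library.
* Missing scored features exclude a record from grading with a warning
  (hard error in strict mode); no imputation, since the source
  describes none.
* Input encodings for binary features (`0/1`, `present/absent`,
  `yes/no`, `true/false`, case-insensitive) are normalised at the
  boundary; internally everything is logical.
* Cohort files use one canonical dialect: comma-separated, UTF-8,
  header required, `NA` or empty for missing.
* File-level wrappers and the command-line front end log package
  version, seed and conventions to stderr; results go only to files.
  Exit codes: 0 success, 2 schema/validation, 3 statistical
  degeneracy, 1 otherwise.

## Known limitations

* The generator's feature independence (above) — the main gap between
  synthetic and real cohorts.
* Stage-adjusted and pT1-restricted odds ratios are implemented
  (`fit_logistic()` with covariates) but cannot be validated against
  the published values, which depend on unpublished joint data; they
  are validated by parameter recovery on synthetic cohorts instead.
* The cohort-n interval convention reproduces the published intervals
  but understates the variance of metrics whose denominator is a
  subgroup; use `wald` or `wilson` for new analyses.
* Prevalence-dependent metrics (PPV, NPV) transfer poorly to
  populations with different metastasis prevalence; the development
  cohort's 33% is high because it is enriched with surgically staged
  patients.
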