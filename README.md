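# penrisk

Histological risk grading for predicting inguinal lymph node metastasis
(LNM) in penile squamous cell carcinoma, with the complete statistical
toolkit needed to evaluate such a grading against the European
Association of Urology (EAU) stage-and-grade comparator.

## Who this is for

Uropathologists and biostatisticians working on risk stratification of
penile cancer. The clinical problem: most patients present without
palpable inguinal nodes, yet up to a quarter harbour occult
micrometastases, and the surgery that rules metastasis out (sentinel
node biopsy or lymphadenectomy) carries substantial morbidity. Risk
grading decides who is surveilled and who is operated on. The EAU
scheme rests on pT stage and WHO grade — and WHO grading of penile
tumours is notoriously irreproducible between pathologists.

## The grading system

Four objective features of the primary tumour are scored and summed:

| Feature | Levels | Points |
|---|---|---|
| Worst pattern of invasion (WPOI) | type 1–3 / type 4 (islands ≤ 15 cells) | 0 / +1 |
| Lymphocytic host response (LHR) | type 1 / 2 / 3 (strong → absent) | 0 / +1 / +2 |
| Lymphovascular invasion (LVI) | absent / present | 0 / +1 |
| Perineural invasion (PNI) | absent / present | 0 / +1 |

Total score s ∈ {0,…,5} maps to the risk group: **low** (s = 0),
**intermediate** (s = 1–2), **high** (s ≥ 3). The comparator EAU
stratification is pTa/pT1G1 → low, pT1G2 → intermediate, pT1G3 or
≥ pT2 → high.

Evaluation statistics follow standard definitions: sensitivity,
specificity, PPV and NPV after dichotomising low vs
intermediate∪high; odds ratios OR = ad/bc with Wald intervals
exp(ln OR ± z·SE), SE = √(1/a+1/b+1/c+1/d); the ordinal ROC AUC via the
tie-corrected Mann–Whitney statistic
AUC = (#concordant + ½·#ties)/(n₊·n₋); Cohen's κ = (p₀ − pₑ)/(1 − pₑ);
Pearson chi-square association tests with Fisher's exact fallback.

## Worked example

```r
library(penrisk)

# the development cohort's published aggregate counts (n = 306),
# expanded to a per-patient pseudo-cohort
cohort <- expand_counts(reference_counts(), seed = 1)
ev <- evaluate_cohort(cohort, system = "both")
ev
```

```
Risk grading evaluation: 306 patients with outcome

== proposed grading ==
  sensitivity   98.04% (96.49-99.59)
  specificity   53.43% (47.84-59.02)
  ppv           51.28% (45.68-56.88)
  npv           98.20% (96.71-99.69)
  auc            0.86  (0.81-0.91)
  OR intermediate vs low: 25.43 (5.94-108.97)
  OR high vs low: 177.13 (40.09-782.51)
  association: pearson_chi_square p = 5.44e-27

== eau grading ==
  sensitivity  100.00% (100.00-100.00)
  specificity   15.20% (11.17-19.22)
  ppv           37.09% (31.68-42.50)
  npv          100.00% (100.00-100.00)
  auc            0.64  (0.58-0.71)
  OR intermediate vs low: Inf (0.00-Inf) [zero cell: interval unbounded]
  OR high vs low: Inf (0.00-Inf) [zero cell: interval unbounded]
  association: pearson_chi_square p = 7.12e-07

Cohen's kappa between systems: 0.149

Diagnostic-metric CI convention shown: cohort_n
```

Reading this: the proposed grading trades a sliver of sensitivity
(98.0% vs 100%) for three and a half times the specificity (53.4% vs
15.2%) — 111 rather than 31 patients fall in the low risk group, where
surgery can be avoided, at the cost of two missed metastases. The
intervals shown use the cohort-n Wald convention (variance denominator
= full cohort size); `tidy(ev)` returns everything as a tibble, and
`autoplot(ev)` draws both three-point ROC curves. The EAU odds ratios
are unbounded because its low risk group contains no metastases (a
structural zero cell, reported as such). The AUC intervals are
Hanley-McNeil; the agreement between the two gradings on this
pseudo-cohort is slight (the exact value depends on the joint
allocation of patients to the two systems, which was never published).

Synthetic cohorts with the same marginal structure and a calibrated
logistic dose-response between score and metastasis:

```r
cohort <- simulate_cohort(sim_config(n_patients = 5000, seed = 42))
glance(evaluate_cohort(cohort, system = "proposed"))
```

File-level wrappers (`grade_file()`, `evaluate_file()`,
`simulate_file()`) and a command-line front end (`inst/cli/penrisk`)
cover scripted use.

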