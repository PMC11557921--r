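---
title: "Early risk stratification after aneurysmal subarachnoid hemorrhage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early risk stratification after aneurysmal subarachnoid hemorrhage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodsebi)
```

## The clinical problem

Aneurysmal subarachnoid hemorrhage (aSAH) injures the brain directly —
the cascade of the first ~72 hours is called early brain injury (EBI) —
but it also derails extracerebral organ function.  Standard aSAH grading
(WFNS, Fisher) looks only at the nervous system.  This package implements
an ICU-style alternative: the Logistic Organ Dysfunction System (LODS), a
six-organ-system severity score computed from routine first-24-hour
physiology, used as an early surrogate marker for the severity of EBI and
as a prognostic tool for 3-month functional outcome.

Three things are computed per patient:

1. **LODS** (0–22): worst first-24-hour values of GCS, heart rate,
   systolic blood pressure, urea, creatinine, urine output, PaO2/FiO2
   under ventilation/CPAP, leucocytes, platelets, bilirubin and
   prothrombin time are mapped to per-system points (neurologic,
   cardiovascular and renal 0/1/3/5; pulmonary and hematologic 0/1/3;
   hepatic 0/1) and summed across systems.  A GCS-free total (0–17)
   isolates the extracerebral component.
2. **EBI grade** (1–5): one point for persistent loss of consciousness,
   one for global cerebral edema, plus 1–3 points from the total
   intracranial blood burden — the Hijdra cisternal score (ten
   cisterns/fissures graded 0–3, sum 0–30) + the Le Roux intraventricular
   score (four ventricles graded 0–4, sum 0–16) + hematoma points from
   the ABC/2 ellipsoid volume (A·B·C/2 in mL: 0 none, 1 under 10 mL, 2
   for 10–30 mL, 3 above 30 mL).  The burden (maximum 49) maps to 1/2/3
   points at 0–19 / 20–29 / 30–49.  Grade ≥ 3 is *severe* EBI.
3. **Charlson comorbidity index** with the classical 1/2/3/6 weights, as
   a confounding covariate (age stays a separate covariate, so the
   age-adjusted variant is deliberately not used).

The analysis stage asks how well LODS discriminates severe from mild EBI
and unfavorable (mRS > 2) from favorable outcome: ROC/AUC, a cutoff, 2×2
diagnostic metrics, odds ratios, simple logistic fits per endpoint, and a
multivariate linear model of mRS on age, treatment modality, LODS, EBI
grade and comorbidity.

## Scoring conventions that the table leaves open

The printed organ-dysfunction point table needs a handful of conventions,
fixed here once:

* Interval boundaries printed as `a–b.9` are half-open on the next
  threshold: urea `[10, 20)` scores 3 and `>= 20` scores 5; SBP
  `[90, 240)` scores 0; and so on.  This matches the printed decimals and
  leaves no gaps.
* A system's score is the **maximum** severity triggered by any of its
  variables; the total is the **sum across systems**.  Within-system
  summation would exceed the documented per-system maxima.
* Platelets below 50 ×10⁹/L score 1 point and prothrombin time more than
  3 s above control scores 1 point (the original scoring system's
  definition; the typeset table misaligns these rows).
* Scoring uses the *worst* value of the first 24 h, hence min/max
  extremes per variable.
* A missing variable is treated as physiologically normal (0 points) but
  is recorded in `lods_missing` — the standard ICU-score convention for
  retrospective tables.  A patient with *every* variable missing is an
  error.  A ventilated patient with no PaO2/FiO2 is an error rather than
  a silent 0.
* PaO2/FiO2 accepts mmHg (threshold 150) or kPa (threshold 19.9) with an
  explicit unit tag; there is no silent conversion.

```{r}
compute_lods(list(gcs_min = 7, urea_max = 25,
                  ventilated_or_cpap = TRUE, pao2_fio2 = 100))
```

EBI-side conventions: the cisternal (Hijdra) component is 0–30 and the
ventricular compartment is covered by Le Roux only — the printed burden
maximum 49 = 30 + 16 + 3 is only consistent with that reading.  A scan
with no hematoma contributes 0 points (points are assigned only on
hematoma volume); volumes exactly at 10 or 30 mL fall in the 2-point
band.  A blood-free scan still grades 1 (the grade range is 1–5, the
burden category "low" contributing its 1 point).

## The analysis machinery

* **AUC** is the rank (Mann–Whitney) statistic with ties counted 0.5 —
  identical to the trapezoidal area under the empirical ROC curve.  Its
  confidence interval is the Hanley–McNeil normal approximation (recorded
  in the report metadata, so a bootstrap or DeLong variant can be swapped
  in later without changing the report shape).
* **Cutoff**: the test is *positive when score > cutoff* (strict), so a
  cutoff of 7 separates LODS 1–7 from LODS > 7.  When not supplied, the
  cutoff maximizes Youden's J; ties are resolved toward the lower
  threshold, and the comparison is done on exact integer counts so
  floating-point noise cannot break a tie.
* **Odds ratios** use the cross-product with the Woolf logit interval;
  any zero cell triggers the Haldane–Anscombe +0.5 correction, which is
  flagged in the output rather than silently applied.  A table with an
  empty margin is reported as undefined, not as a number.
* **Logistic fits** are maximum likelihood via iteratively reweighted
  least squares (`stats::glm`); complete separation is detected before
  fitting and raised as an error naming the covariate, because the MLE
  does not exist there.  The multivariate model on mRS is ordinary least
  squares with t-based intervals — mRS is treated as the ordinal-linear
  endpoint its regression table implies, while the per-endpoint fits are
  logistic; both surfaces are exposed.
* **Median confidence intervals** are distribution-free order-statistic
  (binomial) intervals: the smallest symmetric pair of order statistics
  with coverage at or above the nominal level.  No published CI method
  for medians was identifiable, so a method-free choice was made and
  recorded in the output metadata; nothing downstream depends on the
  bounds.
* p-values below 1e-4 print as `<0.0001`, matching clinical reporting.
* An endpoint with a single class in a cohort is reported as *not
  estimable* with a reason, and the pipeline continues.

## The synthetic cohort generator

Patient-level data for the motivating cohort are not available, so the
package ships a seeded generator whose defaults emulate that cohort's
published margins: 38% severe EBI, 27% unfavorable outcome, 6.8%
in-hospital mortality, age 55.9 ± 13.6 years (truncated to 18–100), 64%
female, 53% clipping, and a LODS marginal taken from the published
frequency column (scores 1–16; renormalized, and documented as
approximate because the source is internally inconsistent about the LODS
median and range).

One latent severity trait `z ~ N(0,1)` per patient drives the joint
structure — a single-factor model rather than a copula, because it makes
the target discrimination solvable before simulation:

* The **LODS total** is assigned by inverse CDF of the configured
  marginal at `pnorm(z)` (comonotone with severity), which guarantees the
  marginal exactly.  The total is then *realized* as a deterministic
  witness set of raw physiology values that `compute_lods()` maps back to
  exactly that total, so the scorer itself stays in the loop and
  round-trips are testable for every total 0–22.
* **Severe EBI** is Bernoulli with `P(severe | z) = plogis(a + b·z)`.
  The intercept `a` and slope `b` are solved numerically (quadrature over
  a z-grid plus root finding) so that the marginal prevalence equals the
  configured value and the *tie-aware* AUC of the discrete LODS total
  against severe EBI equals the configured target (0.78 by default) in
  expectation.  An unreachable target — e.g. a degenerate LODS marginal —
  is an explicit "infeasible calibration" error.  A target of 0.5 is the
  independence limit (`b = 0`).
* The **EBI grade** is drawn conditional on the severe flag from the
  published within-class shape (grades 1–2 as 118:82; 3–5 as 66:45:13),
  then decomposed uniformly over the valid (loss-of-consciousness, edema,
  burden-points) lattice, the burden total drawn uniformly inside its
  category band and split into Hijdra/Le Roux/hematoma components that
  the EBI scorer reproduces exactly.  Hematoma points are rare (85% of
  patients have none), reflecting that most aSAH has no parenchymal clot.
* **mRS** comes from an ordinal-threshold model on `c·z + e`,
  `e ~ N(0,1)`, with the mRS > 2 and death thresholds anchored at the
  configured unfavorable and mortality fractions and within-band splits
  following the published mRS column.  The latent slope `c` defaults
  to 1; it tunes how tightly outcome couples to severity and is *not*
  separately calibrated to an outcome AUC.
* Comorbidity flags are independent draws at realistic prevalences
  (severity-graded conditions drawn as exclusive categories), independent
  of `z`.

What the generator does **not** emulate: vasospasm and delayed cerebral
ischemia, treatment effects on outcome, correlated physiology within a
patient beyond the single factor, measurement error in imaging grades,
or the real joint distribution of LODS and EBI (unknown; the latent-trait
dependence is a modeling stand-in).  Passing recovery tests on these
cohorts therefore validates the *pipeline arithmetic and calibration
machinery*, not the clinical effect sizes.

```{r}
cfg <- sim_config(n = 2000)
cohort <- generate_cohort(cfg, seed = 42)
out <- run_pipeline(cohort)
out$report
```

## Problem sizes and test design

The test suite checks the scorers against a brute-force transcription of
the point table on 10,000 random observations; AUC against pair counting
on 1,000 small instances; marginal calibration on one 20,000-patient
cohort (within three binomial standard errors); discrimination recovery
on one 5,000-patient cohort (±0.03); and 95% CI coverage of the logistic
and OLS estimators over 500 replicates of n = 1,000 (accepted within
0.925–0.975, about ±2.5 binomial standard errors of the nominal level).
These sizes make the whole suite run in a couple of minutes on a single
core while keeping every tolerance interpretable as sampling noise of
the check itself.

## Known limitations

* The LODS mortality-probability logistic transform of the original
  system is out of scope, as are APACHE II / SAPS II.
* Imaging grades are expert-read inputs; nothing is computed from pixels.
* The multivariate model treats mRS linearly; a proportional-odds model
  would be the natural extension.
* Cohort-level effect sizes (AUC 0.78, OR ~6, sensitivity/specificity at
  the cutoff) can only be reproduced distributionally via the generator,
  not from data, since no patient-level data are distributable.
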