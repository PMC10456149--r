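---
title: "Estimating clinician ARDS recognition: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating clinician ARDS recognition: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ardsrecog)
```

## The estimation problem

Clinician *documentation* of ARDS (a flag on a case report form) is
observable; clinician *recognition* is a latent state. The two differ
because documentation is noisy and one-sided: a clinician who documents
ARDS has recognised it, but many clinicians who recognise ARDS never
document it. `ardsrecog` estimates recognition from ventilator behaviour,
resting on two assumptions:

1. tidal volume delivery in ventilated hypoxemic patients is shaped by
   measurable clinical characteristics, and
2. clinicians who recognise ARDS deliver lower standardized tidal volumes
   than they otherwise would.

Under these assumptions the ARDS cohort is a mixture of recognized and
unrecognized patients, and the delivered lowest standardized tidal volume
V̂T = VT/PBW (mL/kg predicted body weight) is a proxy for the latent state.

## Feature derivation

* **PBW** uses the ARDSNet convention: males `50 + 0.91 (h − 152.4)`,
  females `45.5 + 0.91 (h − 152.4)` kg, heights restricted to the plausible
  adult range 120–220 cm.
* **V̂T (lowest)** is the minimum over study days of daily VT / PBW; a
  patient with no recorded tidal volume on any day is excluded (with
  per-reason exclusion counts, alongside missing height or gender).
* **Height z-score** standardizes height against the pooled analyzable
  cohort (ARDS + control combined) with the sample (n−1) standard
  deviation. Pooling rather than per-gender standardization is a deliberate
  choice: gender is already absorbed by PBW, and both cohorts must share
  one X axis for the density models to be comparable. The reference
  population is configurable in principle; pooled is the only implemented
  option and is flagged as an assumption.
* **Severity** uses the Berlin bands on the *lowest* PaO2/FiO2 (mild
  200 < PF ≤ 300, moderate 100 < PF ≤ 200, severe PF ≤ 100 mm Hg), the
  bound ends closed exactly as printed in the severity table.
  `cohort_config(severity_basis = "entry")` switches to the study-entry
  value.
* **Subgroups.** Documented ⇔ ARDS selected on *both* the study-entry and
  study-end forms (primary rule) or on the study-end form alone
  (sensitivity rule). Documented patients of either cohort pool into
  `pooled_documented`; the rest split into `ards_non_documented` and
  `control_non_documented`. The assignment provably partitions the cohort.
* **VAC restriction** (second sensitivity analysis) keeps patients on the
  assist control/volume control mode on a *strict* majority (> 50%) of
  days with a recorded mode; ties and patients with no mode data are
  excluded and counted. Strictness is a deliberate tie-break: "majority"
  is read literally.

## The regression screen

Candidate predictors of lowest V̂T (height z-score, PF at entry/end/lowest,
documentation flags, plateau pressure, chest-imaging quadrant counts, SOFA,
admission weight, age, region code, ventilator modality) are screened one
at a time by OLS with the predictor standardized to mean 0, sd 1 and the
outcome left in mL/kg PBW, so a coefficient is "mL/kg per 1 sd of the
factor". Confidence intervals use the normal approximation β ± 1.96 se.
Each regression is complete-case and reports its n.

Significance uses α = 0.01 with Bonferroni correction. The family size is
*counted, not assumed*: by default each screen corrects for its own number
of evaluable tests, and the pipeline corrects both subgroup screens for
their combined count. (The original analysis family of 111 tests is a
property of that analysis, not a constant of the method.)

Joint use of factors is limited by two rules: a pair whose data
availability differs by more than 10% of the cohort is non-evaluable (the
regressions would be fit on materially different subpopulations), and
remaining pairs are tested for covariance by pairwise standardized OLS at
0.01/10; a covariate pair never enters one model together. Candidate
multivariable models are all admissible non-empty subsets of the
significant factors, plus a documentation × severity-factor interaction
variant when both parents are present — the one interaction with a clinical
reading (recognition should change the *slope* of V̂T in severity). The
best model minimizes BIC; when AIC and BIC disagree, BIC (the more
parsimonious criterion) wins and the disagreement is recorded.

**Factor X** for the recognition model is the factor significant in *both*
the pooled documented and control non-documented screens with the largest
coefficient magnitude; "largest in both" is operationalized as maximizing
the smaller of the two |β| values, with ties broken toward greater data
availability. "Highest standardized beta" is read as highest absolute
value — the screen's signs differ across factors, and magnitude is what
measures influence. On cohorts with the structure this package targets the
winner is the height z-score.

## The kernel-density naive Bayes model

Each subgroup's (X, V̂T) distribution is a product-Gaussian kernel density
with per-dimension bandwidths. Numerical choices, all configurable:

* **Bandwidth**: Scott's rule for d = 2, `h_j = sd_j · n^(−1/6)`, per
  subgroup and dimension (Silverman's rule and fixed bandwidths are
  options). The source analysis names no kernel or bandwidth; Scott is the
  standard default for smooth unimodal-ish densities at these n.
* **Grid**: X ∈ [−3, 3] (z units) × V̂T ∈ [2, 14] mL/kg PBW at 201 × 201,
  covering the plotted range of the original analysis with margin.
* **Priors**: 0.5/0.5 — equal a priori probability of either subgroup, in
  the absence of a better-supported prior. The posterior is monotone in the
  prior, so the classification's sensitivity to this choice is one-sided
  and testable.
* **Density floor**: ε = 1e−12. A point where both class densities fall
  below ε is outside either support; its posterior is reported as 0.5, it
  is flagged `out_of_support`, and the conservative tie rule applies.
* **Boundary extraction**: per X column, the V̂T where the posterior
  crosses 0.5, by sign change and linear interpolation. Multiple crossings
  are a KDE ripple artifact; the crossing nearest the midpoint of the two
  subgroup V̂T means is kept, because the underlying separation is a single
  monotone line. Columns with no crossing are undefined; no crossing
  anywhere is an error (degenerate overlap).
* **Tie rule**: posterior exactly 0.5 — including on-boundary points —
  classifies as *unrecognized*. Only strictly-below-boundary patients are
  recognized; the conservative direction under-counts rather than
  over-counts recognition.
* **Bootstrap bands**: the control non-documented subgroup (the smaller,
  noisier one) is resampled with replacement at its own size for 100
  iterations; the documented model stays fixed; per-column 2.5th/97.5th
  percentiles form the band. Resample size and the fixed documented model
  are assumptions — the source states only that the control subgroup was
  bootstrapped 100 times. Zero-variance resamples are redrawn (counted,
  capped). All randomness flows through one explicit seed recorded in the
  output.

Recognition rates per severity are
`100 · (n_documented + n_classified_recognized) / n_ards`; documented
patients are recognized by definition, so the estimated recognition rate
can never fall below the documentation rate — an invariant the tests
enforce on arbitrary inputs.

## What the synthetic cohort emulates

`generate_cohort()` encodes the clinician heuristic the analysis infers: a
*default absolute tidal volume* for most ventilated patients with
*adjustment at the extremes of height*. Unrecognized ARDS patients and
controls draw an absolute volume ~N(530, 40) mL; its implied V̂T is pulled
toward plateaus at 8 (short) and 6 (tall) mL/kg PBW, retaining 30% of the
excess (`plateau_shrink`) plus 0.25 mL/kg jitter — the adjustment is
partial, as real behaviour would be. Recognized patients are targeted on a
lung-protective V̂T ~N(5.8, 0.6) with a mild height slope (−0.3 per z),
because documented subgroups also show a height effect. Latent recognition
is Bernoulli with logit `1.25 − 0.005 · PF`, so recognition rises with
hypoxemia severity; documentation occurs in 45% of recognized ARDS
patients (plus a 5% rate in controls), making documentation a noisy
one-sided observation of recognition. Severity-correlated plateau
pressure, chest-imaging and SOFA values, multi-day tidal volume and
ventilator-mode sequences, and realistic missingness complete the records.

Cohort sizes default to 2705 ARDS and 1261 controls. The distributional
defaults (heights by gender, volume spreads, noise scales) are *stylized
inventions*, chosen once at design time so that the generated cohort
expresses the qualitative structure the tool expects: a strongly negative
height-z coefficient in the control screen, height unrelated to
documentation, a ~2 mL/kg separation between recognized and unrecognized
V̂T, and an equal-posterior boundary that plateaus near 8 mL/kg for
z < −1 and 6 mL/kg for z > 1 with a linear descent between. The
calibration was done analytically (two-Gaussian crossing algebra) and
confirmed on pilot runs at three seeds before the test suite was written.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: site-level clustering and practice variation,
informative missingness, measurement error in height and documentation,
temporal trends within an admission, and the real (unknown) magnitudes of
the screen coefficients. Tests on this cohort validate the *machinery*
(feature derivation, screen protocol, density classifier, reporting), not
clinical effect sizes; the package deliberately makes no attempt to
reproduce the original cohort's coefficients.

## Problem sizes and determinism

The test suite runs on scaled-down cohorts: a few hundred to 2000 patients
for pipeline and recovery checks, 2000 points per class for the
analytic-boundary oracle, 1000 replicates at n = 150 for the type-I error
check, and the full 3966-patient default cohort for the boundary-geometry
check — sizes at which every check completes in seconds while the
quantities under test are stable. Identical seeds give byte-identical
cohorts, reports, and bootstrap bands; the staged CLI writes a manifest
with file checksums so reruns can be verified.

## Known limitations

* Recognition is latent; even the generator's "ground truth" is a modelling
  construct. Accuracy numbers quantify recovery of the generator's labels,
  not clinical truth.
* The KDE boundary is unreliable outside the data support (|z| ≳ 2.5 at
  default sizes); columns there are reported as undefined rather than
  extrapolated.
* Equal priors are an assumption, not an estimate; users with better
  prevalence information can set `prior` per model.
* The classifier is intentionally the two-density naive Bayes rule;
  alternative classifiers (random forests, boosting) are out of scope by
  design.
* No imputation: all regressions are complete-case with reported n, and
  patients missing height, gender, or all tidal volumes are excluded, not
  filled in.
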