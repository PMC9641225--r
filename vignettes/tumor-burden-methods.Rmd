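---
title: "Single-slice tumor burden and survival biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-slice tumor burden and survival biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`tumorburden` quantifies metastatic tumor burden from single-slice CT lesion
annotations and relates burden dynamics to survival under immunotherapy. The
setting it targets is a cohort of patients with mismatch-repair-deficient
(MMRD/MSI) metastatic tumors treated with anti-PD-(L)1 checkpoint blockade:
every lesion in the body is circumscribed freehand on the axial slice where
it is largest, at two examinations (baseline, before the first injection,
and the first radiological evaluation roughly two months later), and the
question is which cheap, early parameters — imaging or blood-based —
stratify overall and progression-free survival.

This vignette documents the models, the tunable parameters, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the package's known limitations.

## From a 2D contour to an approximate 3D volume

A lesion annotation is a closed polygon in physical millimetres. Three shape
features are computed analytically from the polygon:

**Area.** The enclosed surface $A$ is the absolute value of the *signed* sum
of triangle areas fanned from an interior origin $O$,
$$A = \left|\sum_i \tfrac{1}{2}\, \vec{Oa_i} \times \vec{Ob_i}\right|,$$
where $a_i, b_i$ are consecutive perimeter vertices. We place $O$ at the
polygon centroid and keep the per-triangle signs, which makes the sum equal
to the true enclosed area for *any* simple polygon — including the
non-convex shapes freehand annotation produces — and independent of the
choice of $O$ (it reduces to the shoelace formula). Summing absolute
per-triangle areas instead would systematically overestimate non-convex
ROIs, which is why the signed convention is used.

**Principal axes.** Let $\lambda_{major} \ge \lambda_{minor}$ be the
eigenvalues of the covariance matrix of the uniform distribution over the
polygon's interior. The axis lengths are
$$d_{major} = 4\sqrt{\lambda_{major}}, \qquad
  d_{minor} = 4\sqrt{\lambda_{minor}}.$$
For an ellipse with semi-axes $a \ge b$ the interior covariance eigenvalues
are $a^2/4$ and $b^2/4$, so this convention returns exactly the full
diameters $(2a, 2b)$ — the natural analogue of a caliper diameter
measurement. The covariance is computed from the exact Green's-theorem
moment integrals of the polygon, not from a rasterized mask: the result is
resolution-independent, and the test suite verifies it agrees with a
pixel-counting oracle as the pixel spacing shrinks.

**Volume.** The approximate 3D volume of a lesion annotated on its largest
axial slice is
$$V = \tfrac{2}{3}\, A \, d_{minor}.$$
The factor is exact for ellipsoids of revolution: a sphere of radius $r$
annotated at its equator ($A = \pi r^2$, $d_{minor} = 2r$) gives
$\tfrac{4}{3}\pi r^3$, and a prolate ellipsoid gives
$\tfrac{4}{3}\pi a b^2$. For real lesions it is a deliberate single-slice
approximation — no claim of slice-stack volumetry is made.

Degenerate contours (fewer than three distinct vertices, or collinear ones)
yield zero features rather than errors, and zero-area lesions are removed
with a warning before aggregation: hand-drawn input occasionally collapses,
and a zero-size "lesion" should not inflate lesion or organ counts.

### Lesion inclusion rules

Two rules mirror standard radiological practice for what counts as a
measurable lesion:

* lymph nodes count only when their **minor axis exceeds 10 mm** (the
  RECIST short-axis convention for pathological nodes);
* pulmonary nodules count only when they **exceed 3 mm**, applied here to
  the major axis, since the micronodule convention refers to the largest
  visible diameter.

Both thresholds are strict (a lesion exactly at the threshold is dropped),
following the "more than" phrasing of the conventions. Whether the 3 mm
rule should read on an image-measured diameter or the computed major axis
is genuinely ambiguous; the major axis is the closest computable analogue
and is what `filter_lesions()` uses.

## The five patient-level parameters

At each timepoint the retained lesions and the blood draw reduce to five
parameters per patient:

| parameter | definition | unit | default cutoff |
|---|---|---|---|
| `volume` | sum of per-lesion $V$ | cm³ | 90 |
| `recist_sum` | RECIST 1.1 sum of target-lesion diameters | mm | 55 |
| `nlr` | neutrophils / lymphocytes | — | 5 |
| `n_lesions` | retained lesion count | — | 10 |
| `n_organs` | distinct organ labels among retained lesions | — | 3 |

The RECIST sum is consumed as input (measured by a separate reader), not
re-derived from the annotations — except inside the synthetic generator,
which needs a stand-in selector. A 90 cm³ total volume corresponds to a
single sphere of diameter $2(3V/4\pi)^{1/3} \approx 5.6$ cm
(`equivalent_sphere_diameter(90)`).

**Variation.** Each parameter's dynamic is
$(x_{E1} - x_{BL})/x_{BL} \times 100$, binarized to *increase*
($>0\%$) versus *decrease* ($<0\%$). An exactly zero variation — common for
the integer-valued counts — is pooled with *decrease*: only "an increase"
is treated as the risk signal, so "no increase" is the conservative
assignment. Every zero is counted and warned about, never silently
classified. A zero baseline leaves the variation undefined; the patient is
excluded from that parameter's variation analysis with an explicit `NA`
marker.

**Baseline binarization.** Classes are *high* strictly above the cutoff and
*low* otherwise. The default cutoffs are integer-rounded cohort medians
(`median_integer_cutoff()`: mean-of-middle-two median, rounded half away
from zero) except the NLR, whose cutoff of 5 is the conventional prognostic
threshold from the immunotherapy literature. The RECIST cutoff is stored as
55 mm: all RECIST arithmetic in the package is in millimetres, where the
nearest-integer rule is self-consistent ("5.5 cm" is not an integer in
centimetres). `analysis_config(cutoff_mode = "median")` recomputes all
cutoffs but the NLR from the cohort at hand; the fixed mode is the default
so that reports from different cohorts are comparable.

**Concordance score.** For a pair of parameters (by default volume × NLR
and RECIST × NLR) the joint movement collapses to three categories:
`mutual_increase`, `mutual_decrease`, `discordant`. The score is symmetric
in its two parameters, and the working hypothesis it encodes is that
patients whose tumor burden *and* systemic inflammation both fall are the
long survivors.

## Survival analysis

The survival machinery is implemented in the package — product-limit
estimator, Mantel–Cox log-rank, Cox partial likelihood — so that every
routine can be validated against hand-computable fixtures; the `survival`
package serves as an independent cross-check in the test suite only.

* **Kaplan–Meier**: product-limit over distinct event times; subjects
  censored at an event time stay in the risk set for that time. The 95%
  band uses the Greenwood variance on the log-survival scale,
  $\widehat{\mathrm{Var}}[\log\hat S] = \sum d_j / (n_j(n_j-d_j))$,
  exponentiated and clipped to $[0,1]$.
* **Log-rank**: the $k$-group Mantel–Cox statistic with hypergeometric
  variances, $(k-1)$ degrees of freedom, singular covariance blocks handled
  by a generalized inverse. Pairwise comparisons between concordance
  categories report **unadjusted** p-values — each pair stands on its own —
  with an optional Bonferroni switch that is off by default.
* **Cox**: Newton–Raphson on the partial likelihood with **Efron** handling
  of tied event times (the modern default; ties arise whenever follow-up is
  recorded in rounded months). Convergence is declared at a relative
  log-likelihood change below $10^{-9}$ within 25 iterations, with step
  halving; non-convergence is flagged, not hidden. Zero-variance covariates
  and monotone-likelihood (separated) designs raise named errors — at
  $n \approx 61$ with five binary covariates these are real possibilities,
  and the pipeline records them as notes in the report rather than
  aborting. The score test of the null at $\beta = 0$ equals the log-rank
  chi-square for a single binary covariate without ties, which the suite
  checks to $10^{-6}$.
* **Independence screen**: Spearman rank correlation (average ranks on
  ties) between every pair of candidate variables; pairs at or above
  $|\rho| = 0.8$ are flagged as non-independent. The multivariate Cox
  models default to binarized covariates (the low/high classes and the
  increase/decrease directions), with a continuous option, because
  hazard-ratio magnitudes around 3 per category are only interpretable for
  categorical covariates.

## The synthetic cohort generator

No patient-level data accompany the analysis, so `generate_cohort()`
produces cohorts with the statistical structure the pipeline assumes, plus
the latent ground truth needed for recovery tests. The defaults describe a
cohort of **61 patients**: tumor types at the frequencies of the emulated
study (colorectal 26/61, endometrial 13/61, gastric 7/61, ...), lesion
counts per patient negative-binomial with mean 35 and size 0.5 — giving
roughly 2100 baseline lesions cohort-wide together with a strongly skewed
per-patient distribution (median near 10–12) — and log-normal lesion radii
(`meanlog = log(7.5)`, `sdlog = 0.6`) chosen so the median baseline total
volume lands near the 90 cm³ cutoff. Contours are star-convex polygons with
mean-preserving radial noise standing in for freehand annotation.

Each patient is latently a **responder** (51%) or **progressor**: lesion
volumes rescale between timepoints by a per-patient log-normal multiplier
(medians 0.55 and 1.8 respectively) with per-lesion scatter
(`lesion_growth_sdlog = 0.5`) emulating mixed responses; progressors can
also sprout new lesions (Poisson, mean 2). NLR drifts multiplicatively
(medians 0.75 down for responders, 1.4 up for progressors). RECIST targets
are the up-to-5 largest lesions by major axis, at most 2 per organ, chosen
at baseline and re-measured at evaluation with log-normal reader noise
(`sdlog = 0.1`).

Survival is an exponential proportional-hazards model: the linear predictor
applies the planted log hazard ratios — defaults $\log 3.2$ for high
baseline volume, $\log 2.9$ for an NLR increase, $\log 2.0$ for a volume
increase — to the binarized covariates *derived from the generated data
itself*, so the planted effects flow through the same filtering and
aggregation path the pipeline analyses. Censoring is independent
exponential, with rates set so that roughly half of OS records and ~45% of
PFS records are censored and the median PFS sits near 3 months, matching
the scale of the emulated study. PFS events are generated directly from the
hazard model, **not** derived from RECIST thresholds: progression calls are
reader-defined in the real setting, and deriving them from the generated
diameters would couple outcome noise to covariate noise in a way the real
data does not exhibit.

The exponential baseline hazard is the simplest choice consistent with
proportional hazards; nothing downstream uses the baseline hazard's shape.

### What the generator does *not* emulate

* No CT intensities, texture, or reader segmentation variability beyond the
  radial noise; no image rendering.
* Volume and RECIST variations remain strongly rank-correlated
  ($\rho \approx 0.9$) in synthetic cohorts, because the RECIST targets
  *are* the largest lesions that dominate the volume. Real cohorts show
  much weaker correlation between the two dynamics (heterogeneous
  per-lesion response, reader-chosen targets); the independence screen
  flagging this pair on synthetic data is a faithful description of the
  synthetic data, not of the clinic.
* Organ-specific growth kinetics, pseudo-progression, and any link between
  tumor type and outcome are absent.

Consequently, a passing test suite demonstrates that the *machinery* is
correct and well-calibrated (its type-I error, its recovery of planted
hazard ratios, its determinism), not that any biological claim transfers to
real patients.

## Numerical and design choices, in one place

* Signed triangle fan about the centroid for area; exact interior-moment
  covariance for the axes (both resolution-independent).
* All geometry in mm; volumes convert to cm³ (÷1000) only at patient
  aggregation.
* Strict inequalities throughout: `high` is `> cutoff`, retained lymph
  nodes are `> 10 mm`, retained lung nodules `> 3 mm`.
* Exact-zero variation pools with `decrease`, warned.
* Median cutoffs round half away from zero to the nearest integer.
* Efron ties, Greenwood-on-log CI, unadjusted pairwise log-rank p-values;
  all declared defaults rather than inferences, since tie handling and CI
  conventions are rarely reported in the applied literature.
* Validation problem sizes: 1000 replicates for log-rank calibration, 500
  for Cox recovery at $n = 61$, 100 seeded cohorts for the concordance
  separation property, 50 random ROIs against the 0.1 mm rasterization
  oracle — sizes chosen to make Monte-Carlo noise small relative to the
  acceptance bands while keeping the suite fast on one core.

## Known limitations

* The $\tfrac{2}{3} A d_{minor}$ volume is exact only for ellipsoids of
  revolution about the in-plane major axis; elongated or lobulated lesions
  are approximated, and the package makes no attempt to bound that error on
  real anatomy.
* The pipeline analyses a two-timepoint snapshot; no time-varying
  covariates, stratified Cox, or restricted-mean survival.
* Plotting is limited to exporting Kaplan–Meier step coordinates
  (`km_step_coordinates()`); figures are the caller's job.
* The generator's organ-sampling weights and lesion-size distributions are
  order-of-magnitude modelling choices exposed in `cohort_config()`, not
  estimates from any dataset.
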