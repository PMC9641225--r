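# tumorburden

Quantify metastatic tumor burden from single-slice CT lesion annotations
and relate burden dynamics to survival under immunotherapy.

## The problem

Patients with mismatch-repair-deficient (MMRD/MSI) metastatic tumors are
treated with anti-PD-(L)1 checkpoint blockade regardless of tumor origin,
yet response is highly heterogeneous. Cheap biomarkers that read out early
— from the baseline CT, the first evaluation CT about two months in, and
routine blood counts — would let clinicians stratify patients long before
conventional response criteria settle. `tumorburden` implements such an
analysis for radiologists and biostatisticians: every lesion in the body is
circumscribed freehand on the axial slice where it is largest, and the
package turns those contours plus blood counts into patient-level burden
biomarkers and survival stratifications.

## The model

Per lesion, from the 2D contour (a polygon in mm):

- area `A = |Σ ½ Oaᵢ × Obᵢ|` — a signed triangle fan about the centroid,
  equal to the true enclosed area for any simple polygon;
- axis lengths `d = 4√λ`, with `λ` the eigenvalues of the exact interior
  covariance of the polygon (an ellipse with semi-axes `a ≥ b` gives
  exactly `(2a, 2b)`);
- approximate 3D volume `V = ⅔ · A · d_minor`, exact for ellipsoids of
  revolution (`A = πr²`, `d_minor = 2r` recovers `4⁄3 πr³`).

Lymph nodes below a 10 mm minor axis and lung nodules at or below 3 mm are
excluded. Per patient and timepoint, five parameters result: total volume
(cm³), RECIST 1.1 sum of target diameters (mm), neutrophil-to-lymphocyte
ratio (NLR), lesion count, organ count. Each is analysed at baseline
(binarized low/high at cutoffs 90 cm³ / 55 mm / 5 / 10 / 3) and as its
percent variation `(E1 − BL)/BL × 100`, binarized to increase (>0%) vs
decrease. A two-parameter *concordance score* (mutual increase / mutual
decrease / discordant) combines volume×NLR or RECIST×NLR dynamics.

Survival analysis — Kaplan–Meier with Greenwood log-scale bands, Mantel–Cox
log-rank (pairwise, unadjusted), Cox proportional hazards with Efron ties,
Spearman independence screening at |ρ| ≥ 0.8 — is implemented in-package
and cross-checked against the `survival` package in the test suite.

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the
study structure (61 patients, ~2100 baseline lesions, two timepoints,
roughly half of OS records censored) with planted hazard ratios, so the
entire pipeline is testable without patient data. See the methods vignette
(`vignettes/tumor-burden-methods.Rmd`) for model details and limitations.

## Worked example

```r
library(tumorburden)

dir <- file.path(tempdir(), "cohort")
cohort <- generate_cohort(cohort_config(), seed = 42, out_dir = dir)
report <- run_pipeline(file.path(dir, "annotations.jsonl"),
                       file.path(dir, "blood_recist.csv"),
                       file.path(dir, "outcomes.csv"),
                       analysis_config(), out_dir = file.path(dir, "results"))
print(report)
```

```
Tumor-burden survival analysis report
=====================================
Patients analyzed: 61 | rejected: 0
Lesions retained: 4220 (dropped by rules: lymph_node 191, lung 3 )
Events: OS 31 | PFS 41
Cutoffs (fixed): volume=90, recist_sum=55, nlr=5, n_lesions=10, n_organs=3

-- baseline univariate log-rank p-values --
  volume       groups 31/30 | OS p=9.304e-05 PFS p=0.002329
  recist_sum   groups 14/47 | OS p=0.2755 PFS p=0.00706
  nlr          groups 44/17 | OS p=0.1619 PFS p=0.9287
  n_lesions    groups 24/37 | OS p=0.0264 PFS p=0.006141
  n_organs     groups 16/45 | OS p=0.2258 PFS p=0.0342
-- variation univariate log-rank p-values --
  volume       groups 27/33 | OS p=0.09517 PFS p=0.05771
  recist_sum   groups 30/30 | OS p=0.2583 PFS p=0.02316
  nlr          groups 28/33 | OS p=0.0009881 PFS p=7.998e-05
  n_lesions    groups 33/27 | OS p=0.3789 PFS p=0.0347
  n_organs     groups 50/10 | OS p=0.2836 PFS p=0.5007

-- concordance analyses --
  volume_x_nlr: sizes mutual_decrease=19, discordant=16, mutual_increase=25
    OS pairwise p: mutual_decrease vs discordant 0.0858; mutual_decrease vs mutual_increase 0.00933; discordant vs mutual_increase 0.212
    PFS pairwise p: mutual_decrease vs discordant 0.573; mutual_decrease vs mutual_increase 0.00203; discordant vs mutual_increase 0.0133
  ...
```

Reading it: in this seeded synthetic cohort the high-baseline-volume group
(31 vs 30 patients at the 90 cm³ cutoff) separates strongly on overall
survival (log-rank p = 9.3e-05), an increasing NLR is the strongest
dynamic marker (OS p = 0.00099), and patients with a mutual decrease of
volume and NLR outlive the mutual-increase group (pairwise p = 0.0093) —
the planted effects the generator put in, recovered by the analysis. The
run also writes `biomarker_table.csv` (one row per patient: all parameters,
variations, classes and concordance categories), `report.json`
(machine-readable, byte-stable across identical runs), `report.txt` and
`rejects.csv` into the output directory.

Single lesions work just as directly:

```r
f <- shape_features(polygon2d(cbind(10 * cos(seq(0, 2*pi, len = 257)[-257]),
                                    10 * sin(seq(0, 2*pi, len = 257)[-257]))))
f$volume / 1000          # 4.188 cm^3: a 10 mm-radius sphere
equivalent_sphere_diameter(90)   # 5.56 cm sphere for the 90 cm^3 cutoff
```

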