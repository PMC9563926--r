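---
title: "Validating exhaled-breath OSA markers with breathflow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating exhaled-breath OSA markers with breathflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathflow)
```

## The problem

Obstructive sleep apnea (OSA) is diagnosed by in-laboratory sleep studies
that are slow, costly and burdensome. Real-time analysis of exhaled breath
by secondary electrospray ionization high-resolution mass spectrometry
(SESI-HRMS) offers a non-invasive alternative: a subject exhales directly
into the instrument, which records full positive-mode scans (m/z 50–500,
0.5 s accumulation) over six consecutive exhalations. Prior work proposed a
targeted panel of 78 breath features associated with OSA. `breathflow`
implements the validation workflow for such a panel: from raw scan streams
to a subject-by-feature intensity matrix, targeted marker detection,
nonparametric between-group testing, and cross-validated classification of
untreated versus CPAP-treated OSA.

## Preprocessing model

The chain applied to each subject's mzXML scan stream is:

1. **Mass recalibration.** All sessions are mapped onto one reference
   breath spectrum by a two-parameter linear model
   $m/z_\text{corr} = a \cdot m/z + b$, least-squares fitted on calibrant
   ions. The default calibrants are the protonated water clusters
   (37.0284, 55.0390, 73.0495 Da), which are always present in breath.
   Time-of-flight drifts are locally linear over 50–500 Da; with only a
   handful of calibrants, higher polynomial orders are not identifiable,
   so they are deliberately not offered. Accepted fits must satisfy
   $a \in [0.999, 1.001]$ and $|b| \le 0.05$ Da; post-fit calibrant
   residuals are reported and should stay below the downstream matching
   tolerance (0.005 Da). The reference defaults to the most intense scan
   of the first session (alphabetical file order); it is configurable, and
   any reference choice only shifts the common frame, not relative
   positions.

2. **Exhalation gating.** Only scans acquired during exhalation carry
   breath signal. A scan counts as a breath scan when its maximum
   intensity within 55.039 ± 0.005 Da — the protonated water trimer
   [(H2O)3+H]+ — exceeds 10% of the session-wide maximum of that window.
   "Presence" of the gate ion is not an absolute threshold because
   absolute intensities vary strongly between subjects; a fractional gate
   is scale-free and reduces to a plain threshold for clean data. The
   fraction (default 0.1) and window are configurable. Raising the
   fraction can only remove scans (a tested monotonicity property).

3. **Interpolation and averaging.** Scans are linearly interpolated onto a
   uniform grid (default 0.001 Da — less than half the FWHM of a peak at
   resolving power 30,000 anywhere in range) and the selected breath scans
   are averaged arithmetically per grid point. We average the gridded
   traces first and pick peaks once on the average; the alternative
   (pick per scan, then average matched peaks) is available via
   `per_scan = TRUE` in `average_breath_scans()`. Averaging first uses all
   scans' statistics at every grid point and is the numerically gentler
   default for noisy single scans.

4. **Peak picking.** Local maxima strictly greater than both neighbours
   (plateaus resolved to their midpoint) with apex height ≥ 5 counts/s,
   the pipeline's height filter. The centroid is the intensity-weighted
   mean m/z over the contiguous region above half the apex — a standard
   centroiding rule that is robust to grid phase and mild asymmetry.

5. **Cross-subject alignment.** Features from all subjects are pooled and
   single-linkage clustered along m/z, cutting links larger than the same
   0.005 Da tolerance used for marker matching. Each cluster becomes a
   matrix column with an intensity-weighted representative m/z. A subject
   without a feature in a cluster gets intensity 0: absent signal is a
   measured zero under total-ion-current semantics, not a missing value,
   so no imputation is performed.

6. **Normalization cascade.** Strictly ordered:
   raw → TIC-normalized (each row divided by its total ion current; rows
   then sum to 1) → median-scaled (all rows multiplied by the median TIC
   of included subjects, restoring an interpretable scale) → auto-scaled
   (per-feature z-score). Auto-scaling uses the population (n) standard
   deviation by default (`sd_type = "sample"` switches to n−1); the
   choice only rescales columns and cannot change any rank-based result.
   Zero-variance columns are dropped with a warning. Because z-scores
   destroy ratios, the TIC-normalized values are carried alongside the
   final matrix for fold-change computation.

## Marker panel and mass audit

Targeted detection matches each panel m/z to the nearest matrix column
within 0.005 Da (nearest wins when several columns fall inside the
window; the paper-style tolerance is configurable). The panel's elemental
compositions are interpreted as **cation formulas** (protonated species,
charge +1): computing their monoisotopic masses — sum of
most-abundant-isotope masses minus one electron mass — reproduces the
printed panel m/z values to better than 0.001 Da for all nine attributed
markers, which would not hold under a neutral-formula reading.
`audit_panel_masses()` performs exactly this consistency check.

The bundled 78-feature panel deserves a caveat: only the nine significant
markers are published with full attribution. The remaining 69 entries in
`osa_panel()` are synthetic placeholders (the file is named
`osa_panel_synthetic.csv` for that reason) so the full targeted workflow
can be exercised; 42 of the 78 are flagged `detectable` and are the
features the cohort generator emits, mirroring the published detection
count.

## Group statistics

Breath intensities are right-skewed across subjects, so group differences
are tested with the Mann–Whitney U test; the Shapiro–Wilk statistic is
reported per marker and group as the normality gate that justifies the
choice, but never switches the test silently. U is computed from midrank
sums and reported as min(U1, U2); p-values are exact (equivalent to full
permutation enumeration) for combined n ≤ 12 without ties, otherwise the
normal approximation with tie and continuity corrections. Because
auto-scaling is a positive affine map per feature, testing on auto-scaled
or TIC-normalized values gives identical p-values — an asserted property,
not an assumption.

Fold change is the ratio of group medians on the TIC-normalized scale,
and the reported direction ("increased" in untreated OSA) is defined by
that ratio. No multiple-testing correction is applied by default — the
workflow's significance rule is unadjusted p < 0.05 — but
Benjamini–Hochberg is available via `p_adjust = "BH"`.

Two stratification rules select the analysis cohort. Stratification 1
keeps all untreated subjects and treated subjects with ≥ 5 h/night
averaged CPAP usage (the boundary is closed: "minimal 5 h/night").
Stratification 2 additionally requires disease severity: AHI > 30, or
AHI > 10 and ESS > 10, with strict inequalities as printed; treated
subjects use their pre-treatment (diagnosis) AHI, untreated subjects the
AHI measured at the visit. ODI-based variants of both rules — the earlier
study's criteria — are implemented as flagged legacy options
(`strat1_odi`, `strat2_odi`).

## Classification

`crossvalidate()` runs stratified 10-fold cross-validation of a linear
support vector machine (unit cost; kernel and cost configurable — no
hyperparameter values were reported for the original model, so the
simplest member of the family is the default). The AUC is averaged over
folds; the confusion matrix is pooled over folds at the classifier's
default decision threshold (margin sign, no threshold tuning). The ROC
AUC is computed as the normalized Mann–Whitney statistic of the scores,
with ties contributing ½ — and equals U/(n1·n2) by construction, a
property the tests assert against the group-statistics module.

One deliberate difference from a global-preprocessing workflow: since
auto-scaling moments are cohort statistics, computing them on the full
cohort before cross-validation leaks test-fold information into training.
The default here recomputes per-feature scaling inside each training fold
(`scale = "fold"`); `scale = "global"` reproduces the simpler
whole-cohort scaling for comparison. For balanced designs,
`balanced_subsample()` reduces the majority class to the minority size,
uniformly at random and reproducibly from the seed.

## The synthetic cohort generator

No raw clinical data are distributable, so the generator is a first-class
module providing ground-truthed inputs for every stage:

* **Scan streams.** Each session alternates ambient blocks (4 scans) and
  exhalation blocks (8 scans) for six exhalations at 0.5 s per scan. The
  water-cluster series appears only during exhalation, the gate trimer
  with a trapezoidal ramp (half height on the block's edge scans);
  breath features are Gaussian peaks in m/z with width set by resolving
  power 30,000, constant in height across an exhalation, plus additive
  truncated-Gaussian noise (default SD 2 cps). Within an exhalation the
  real intensity dynamics of SESI are unpublished; the trapezoid/plateau
  is an explicit modeling choice isolated behind the generator interface.
  Spectra are emitted as sparse profile points concentrated around peaks
  with a 1-Da baseline comb; real profile data are dense everywhere, but
  the pipeline only consumes peak-local structure.
* **Mass drift.** A per-subject linear axis distortion with offset drawn
  from ±0.003 Da (and a ppm-level slope term), within the ±0.01 Da range
  the recalibration model must correct.
* **Marker effects.** Per-subject feature intensities are log-normal:
  feature abundance log-means are uniform on log(20)–log(400) cps and the
  between-subject log SD is 0.5. A planted effect shifts the untreated
  group's log intensity by `effect × sigma_log`. The default effect for
  the nine significant markers is 0.73 SD units, chosen so that the
  median fold change is exp(0.73 × 0.5) ≈ 1.44, the fold change reported
  for 2-butylfuran; recovery studies use explicitly stronger settings.
  Note that TIC normalization slightly attenuates planted effects (the
  markers themselves inflate the untreated TIC) — a closure property of
  compositional normalization that the power simulations inherit on
  purpose.
* **Metadata.** AHI/ODI/ESS/CPAP are drawn from log-normal or clipped
  normal approximations matched to the cohort's published medians and
  IQRs (untreated AHI at visit median 28; treated 1.3 at visit but 35.5
  at diagnosis; ESS medians 5–7.5; CPAP usage centred at 5.8 ± 1.6
  h/night so roughly two thirds of treated subjects meet the 5 h/night
  bar). These are shape references for exercising the stratification
  rules, not clinical simulations.

What passing tests on generated data do **not** show: robustness to
chemical background drift, isotope interference, non-Gaussian line
shapes, within-exhalation dynamics, or correlated marker biology — none
of which the generator models.

## Numerical choices and degenerate inputs

* Grid spacing 0.001 Da default; the large simulation studies use 0.005 Da
  and small cohorts (2–6 subjects, m/z 50–210) to keep runtimes in seconds
  — the statistical layers are exercised at the published cohort sizes
  (43 vs 29; 15 vs 15 balanced) through the matrix-level generator, with
  1000-seed null calibration and 200-seed recovery studies.
* Gate edge: a scan is selected when it strictly exceeds the fractional
  threshold; a session with no qualifying scan is a failed measurement
  and raises an error rather than returning an empty set.
* Peak plateaus (ties in gridded intensity) resolve to the plateau
  midpoint; ties in ranks use midranks everywhere.
* Zero TIC aborts normalization naming the subject; zero-variance
  features are dropped with a warning at auto-scaling.
* Fold assignment shuffles within class and deals round-robin, so class
  balance per fold is within one subject; every reported run embeds its
  seed, config hash and package version.

## Known limitations

* The 69 unattributed panel entries are synthetic stand-ins; real
  validation requires the original panel values.
* The classifier family is fixed to SVMs; the original model-selection
  sweep over many algorithm families is out of scope.
* Correlation of marker intensities with disease severity (AHI/ODI) is
  not modeled or tested, and chemical identification of markers is out of
  scope.
* mzXML is the only supported on-disk format (the workflow's conversion
  target); mzML and vendor formats are not read.
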