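---
title: "Quantifying the peri-enhancing zone: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the peri-enhancing zone: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pezmap)
```

## The scientific problem

Glioblastoma recurs almost universally, and most local relapses arise in
the *peri-enhancing zone* (PEZ): the few millimetres of tissue immediately
surrounding the contrast-enhancing tumor core, where infiltrating tumor
cells, edema and matrix remodelling mix. `pezmap` implements a 3D,
region-of-interest-based analysis of this zone on co-registered
quantitative MRI: the apparent diffusion coefficient (ADC, in units of
10^-6^ mm^2^/s, from diffusion-weighted imaging) and a semi-quantitative
relative cerebral blood volume (rCBV, unitless, from dynamic
susceptibility contrast perfusion). The question the pipeline addresses:
do baseline ADC and rCBV differ between PEZ tissue that later develops
recurrent enhancement and PEZ tissue that stays stable?

The analysis takes as *inputs* the segmentation products a neuro-oncology
workflow produces anyway — the enhancing core (including its necrotic
interior), the FLAIR-hyperintense region, a brain mask, and the follow-up
recurrence region mapped back into baseline space — all on a 1 mm
isotropic grid. Skull stripping, tumor segmentation and registration are
deliberately out of scope: masks are consumed, not produced.

## The per-case chain

1. **rCBV reconstruction.** DSC signal is converted voxel-wise to a
   contrast-agent concentration curve, `C(t) = -(1/TE) * ln(S(t)/S0)`,
   with `S0` the mean pre-bolus baseline signal. Per transverse slice, an
   arterial input function (AIF) is estimated from candidate vascular
   voxels — those whose peak concentration reaches the 98th percentile of
   in-mask peaks, with a minimum of ten voxels enforced — as the
   per-time-point median curve, smoothed with a Gaussian of one time
   point. Voxel-wise rCBV is the trapezoidal integral of `C(t)` divided by
   that of the slice AIF.
2. **Rim construction.** The PEZ is the set of brain voxels at Euclidean
   distance 0 < d <= 5 voxels from the core, computed with an exact
   separable distance transform. At 1 mm isotropic resolution, voxel units
   and millimetres coincide.
3. **Fluid exclusion.** Rim voxels at or above a per-case ADC threshold
   (ventricles, sulci; free water sits near 3000 x 10^-6^ mm^2^/s) are
   removed before any statistics.
4. **Partition.** The cleaned rim is split 2x2 by FLAIR membership and
   recurrence overlap into `t1pos_flairpos`, `t1neg_flairpos`,
   `t1pos_flairneg`, `t1neg_flairneg` — recurrence-prone versus stable
   tissue inside and outside the FLAIR-hyperintense region. Any voxel-wise
   overlap with the recurrence mask counts as recurrence-prone; the four
   compartments are disjoint and tile the rim exactly.
5. **ROI statistics.** Per compartment and modality: mean, SD, and two
   trimmed means — `mean_high` drops the lowest 20% of voxels,
   `mean_low` the highest 20%.

At the cohort level, per-case maps are normalized onto a cohort-mean
reference range, compartment means are compared with paired two-sided
Wilcoxon signed-rank tests, ADC–rCBV association is measured with Pearson
correlation, and discrimination between recurrence-prone and stable
compartment means is summarized by ROC AUC with a Youden-index operating
threshold.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| rim width | 5 | voxels (= mm) | the invasion front; wider rims dilute the signal with normal tissue |
| fluid ADC threshold | per-case, auto | 10^-6^ mm^2^/s | CSF contaminates means; per-case histograms vary |
| trim fraction | 0.20 | — | robustness check against tail-driven differences |
| AIF peak percentile | 98 | — | isolates arterial voxels from tissue |
| AIF minimum candidates | 10 | voxels | median of fewer curves is unstable |
| AIF smoothing sigma | 1 | time point | suppresses sampling noise without distorting the bolus |
| baseline window | first 5 | time points | pre-bolus samples for `S0` (bolus arrives ~18 s with 1.8 s sampling) |
| normalization anchors | 1st / 99th | in-brain percentiles | robust ends of the cumulative histogram |

Every one of these is surfaced in `pipeline_config()`; nothing is hidden
in the implementation.

## Design choices where the design was genuinely open

**Rim metric.** The rim is defined by the exact Euclidean distance
transform rather than Chebyshev (box-kernel) dilation: a surface offset of
the 3D core contour is isotropic, and Chebyshev dilation over-thickens
diagonals by up to sqrt(3). With the whole core as the distance source, a
non-convex core cannot re-enter its own rim.

**Paired test as primary.** Each case contributes both the
recurrence-prone and the stable compartment, so the design is
within-patient; the signed-rank test is the default and an unpaired
rank-sum mode is available (`test_mode = "rank_sum"`).

**Fluid threshold automation.** Expert per-case histogram inspection is
emulated by `suggest_fluid_threshold()`: the deepest valley of the
smoothed in-rim ADC density between the parenchymal mode and any
fluid-like mode (>= 2000 x 10^-6^ mm^2^/s), falling back to 2000 for
unimodal histograms. A fixed override is available.

**Negative concentrations are kept.** Noise can push `C(t)` below zero;
the integral is taken over the curve as defined, without clamping
(`clamp_negative` exists but is off), so the reconstruction reproduces the
stated formulas literally.

**AIF-less slices.** Slices with fewer in-mask voxels than the candidate
minimum (thin apex slices) borrow the nearest valid slice's AIF rather
than being dropped, which would bias rim coverage; borrowing is logged.

**Cohort normalization of statistics, not maps.** `analyze_cohort()`
applies each case's normalization affine to the ROI statistics rather than
re-traversing the maps: an increasing affine map commutes exactly with
means, quantile-trimmed means, and (up to its slope) SDs, so the result is
identical to normalizing the maps first and far cheaper for 4D cohorts.
`normalize_map()` performs the map-level operation where a normalized
volume itself is wanted.

**Trimming convention.** Percentiles use linear interpolation of order
statistics; values tied with the cut are excluded together with the
trimmed tail, making the trimmed means deterministic. For a constant ROI
both trimmed means equal the mean.

## The synthetic cohort: what it emulates, and what it does not

Because the underlying patient data are not public, validation runs on a
phantom generator (`phantom_spec()`, `generate_case()`,
`generate_cohort()`) that reproduces the *structure* of the study data:

* an ellipsoidal brain with a subarachnoid CSF shell (~15% of the
  intracranial volume) and two ventricles, one abutting the rim — so fluid
  exclusion and histogram normalization face realistic conditions;
* a spherical enhancing core with necrotic interior, a one-sided
  FLAIR halo, and a recurrence lobe contiguous with the core whose polar
  angle is *solved* per case so that one third of the rim's recurrence
  tissue falls outside FLAIR (the share reported for real cohorts); the
  azimuth and all radii are randomized across cases;
* tissue-class ADC and CBV values taken from the reference group means
  (FLAIR+ recurrence-prone/stable ADC 1192/1291, CBV 0.33/0.29; FLAIR-
  987/971 and 0.36/0.35), with i.i.d. Gaussian voxel noise (SD 150) on
  ADC;
* a 4D DSC series synthesized through the same signal model the
  reconstruction inverts: `S(t) = S0 * exp(-TE * C(t))` with
  `C(t) = 25 * CBV_class * bolus(t)` and a gamma-variate bolus (arrival
  18 s, time-to-peak 9 s, shape 3; TE 29 ms, 60 points at 1.8 s). Vertical
  arterial structures (CBV 1) occupy ~3% of each slice crossing the rim,
  so the 98th-percentile AIF selection genuinely recovers arterial curves.
  Signal noise (SD 10 on S0 = 1000) is added within the brain — the
  analysis never reads background voxels;
* between-subject variability: per-case class means are drawn around the
  group means with the reference between-subject SDs, through a shared
  subject offset that induces within-patient correlation between
  compartment means (0.5 for ADC, 0.1 for rCBV — chosen once so that the
  implied paired-difference spreads match the reference p-values at
  n = 46), and an ADC–CBV coupling of -0.6 that reproduces the observed
  negative diffusion–perfusion correlation.

Deliberately *not* modelled: real anatomy (no template brain, no cortical
folding), spatially correlated noise (the within-ROI texture of real
tumors is unknown to us; i.i.d. noise makes trimmed means behave slightly
better than they would on textured data), susceptibility artifacts,
motion, leakage effects in DSC, and registration error. Passing tests on
phantoms therefore demonstrate correctness of the *computational chain*
and statistical calibration under the stated model — not clinical validity
on patient data.

## Numerical notes

* The distance transform is the exact separable lower-envelope algorithm
  (compiled); tests compare it voxel-exactly with an O(N·|core|)
  brute-force oracle.
* Quantiles everywhere are the linear-interpolation convention
  (`stats::quantile` type 7); trimmed means at small ROI sizes depend on
  this and it is therefore stated.
* Gaussian AIF smoothing uses reflection at the curve ends; for a bolus
  that has returned to baseline the smoothed curve integrates to the same
  value, which is why an AIF-identical voxel has rCBV exactly 1.
* Signed-rank p-values are exact for n <= 25 without ties or zero
  differences, and use the normal approximation with continuity
  correction otherwise; all-zero differences yield a flagged degenerate
  result rather than a p-value.
* ROC ties count one half (midrank formulation); Youden ties are broken
  toward higher specificity.
* Empty ROIs (e.g. an empty recurrence mask) propagate as flagged
  undefined statistics, never as zeros, and drop out of the paired
  comparisons as incomplete cases.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use 96^3 phantom grids for the
full-pipeline cohort (46 cases, the reference cohort size), 48^3
diffusion-only grids for the 200-replicate type-I calibration, and 32^3
or smaller grids for oracle comparisons; the full 256x256x220 acquisition
matrix is supported (`phantom_spec(grid_shape = c(256, 256, 220))`,
`--full-grid` in the CLI) and all geometry defaults scale with the grid.

## Known limitations

* The recurrence lobe is a single sphere: multifocal or distant recurrence
  is out of scope, as is any recurrence not contiguous with the core.
* The near (5–10 mm) and far (10–15 mm) zones around the core are not
  modelled; the rim width is configurable but the zonal scheme is not.
* rCBV is the semi-quantitative integral ratio: no deconvolution, no
  leakage correction, no absolute quantification. Units are arbitrary and
  only within-cohort comparisons are meaningful.
* ADC maps are treated as already quantitative; their cohort normalization
  is optional (`normalize_adc`) and on by default for symmetry with rCBV.
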