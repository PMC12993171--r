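# pezmap

Quantitative 3D analysis of the **peri-enhancing zone** (PEZ) in brain
tumor MRI: the thin rim of tissue immediately surrounding the
contrast-enhancing glioblastoma core, where most local recurrences arise.
`pezmap` is aimed at quantitative-imaging researchers who have
co-registered, 1 mm isotropic volumes per case — an ADC map, a 4D DSC
perfusion series, and segmentation masks (enhancing core incl. necrosis,
FLAIR hyperintensity, brain, and follow-up recurrence mapped to baseline)
— and want reproducible compartment statistics and cohort inference.

## What it computes

* **rCBV** — semi-quantitative relative cerebral blood volume from DSC:
  voxel-wise concentration `C(t) = -(1/TE) ln(S(t)/S0)`, a slice-wise
  arterial input function AIF(t) (median over voxels whose peak reaches
  the 98th percentile of in-slice peaks, minimum 10 voxels, Gaussian
  smoothing σ = 1 time point), and
  `rCBV = ∫₀ᵀ C(t) dt / ∫₀ᵀ AIF(t) dt` by the trapezoidal rule.
* **PEZ construction** — the rim `{v ∈ brain : 0 < d_E(v, core) ≤ 5}` by
  exact Euclidean distance transform, minus fluid voxels above a per-case
  ADC threshold (ventricles/sulci, suggested automatically from the rim's
  ADC histogram).
* **Partition** — the rim split 2×2 into recurrence-prone vs stable
  (T1+/T1−) × FLAIR-hyperintense vs FLAIR-normal (FLAIR+/FLAIR−)
  compartments.
* **ROI statistics** — per compartment and modality: mean, SD, and
  20th-percentile trimmed means (`mean_high`, `mean_low`).
* **Cohort inference** — histogram normalization to a cohort reference
  range, paired Wilcoxon signed-rank comparisons of T1+ vs T1− (per FLAIR
  region), percent differences, Pearson ADC–rCBV correlation, and ROC/
  Youden analysis of per-case compartment means.
* **Synthetic cohorts** — a phantom generator with known ground truth
  (tissue-class labels, class means, true CBV ratios) for end-to-end
  validation, including a DSC series synthesized through the same signal
  model the reconstruction inverts.

## Worked example

A noise-free phantom case recovers the tissue-class parameters exactly
through the full per-case chain (rCBV reconstruction → rim → fluid
exclusion → partition → statistics):

```r
library(pezmap)
sp <- phantom_spec(grid_shape = c(48, 48, 48), adc_noise_sd = 0,
                   signal_noise_sd = 0, between_subject_scale = 0)
pc  <- generate_case(sp, seed = 1)
res <- analyze_case(pc, pipeline_config(fluid_threshold = 2000))
res$stats[, c("roi_label", "modality", "n_voxels", "mean")]
#>        roi_label modality n_voxels    mean
#> 1 t1pos_flairpos      adc      163 1192.00
#> 2 t1neg_flairpos      adc     2405 1291.00
#> 3 t1pos_flairneg      adc       81  987.00
#> 4 t1neg_flairneg      adc     1543  971.00
#> 5 t1pos_flairpos     rcbv      163    0.33
#> 6 t1neg_flairpos     rcbv     2405    0.29
#> 7 t1pos_flairneg     rcbv       81    0.36
#> 8 t1neg_flairneg     rcbv     1543    0.35
```

The ADC means (in 10⁻⁶ mm²/s) and rCBV values per compartment equal the
generator's class parameters: recurrence-prone FLAIR+ tissue is the
low-ADC (1192 vs 1291), high-rCBV (0.33 vs 0.29) compartment.

A full cohort with between-subject variability and noise
(`analyze_phantom_cohort(46, phantom_spec(), seed = 7)`, 96³ grids, a few
minutes) yields the group-level pattern:

```
   region modality  pct_difference  p_value
 flairpos      adc          -7.4    6.7e-05
 flairpos     rcbv         +14.0    5.0e-03
 flairneg      adc          +2.2    0.18
 flairneg     rcbv          +0.9    0.78
AUC (per-case FLAIR+ means): ADC 0.70, rCBV 0.68
```

— ADC down and rCBV up in recurrence-prone FLAIR+ tissue with paired
significance, null contrasts in FLAIR-normal tissue, and about one third
of rim recurrence outside the FLAIR halo.

A command-line wrapper ships in `inst/scripts/pezmap`
(`simulate | rcbv | pez | analyze-case | analyze-cohort`).

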