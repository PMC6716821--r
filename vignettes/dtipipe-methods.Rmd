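---
title: "dtipipe: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dtipipe: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the numerical methods behind each pipeline stage and
the design decisions that are not obvious from the API. Code chunks are
shown but not evaluated at build time; all of them run as written against
the installed package (the heavier ones take minutes).

## 1. Synthetic cohort with tensor ground truth

`phantom_spec()` describes a digital mouse-brain phantom on an isotropic
diffusivity background: two cortical boxes (left/right, mediolateral fibre
direction), a transcallosal "callosum" cylinder (radius 0.4 mm) connecting
them, and a vertical "cst" cylinder (radius 0.2 mm) as the spared control
structure, each carrying a characteristic anisotropic tensor.
`simulate_subject()` renders the phantom into a diffusion-weighted stack
using the exact mono-exponential signal model `S = S0 * exp(-b gᵀ D g)`
over a 30-direction, 5-b0, b = 1000 s/mm² scheme, then adds Rician noise;
per-subject anatomical variability is a small random rigid jitter (±1 voxel,
±3°) of the phantom within the field of view.

**Structure sizes and sampling adequacy.** The default native grid is
24 × 24 × 10 voxels of 102 × 102 × 250 µm, i.e. an in-plane field of view
of ~2.45 mm over a 2.5 mm slab. Every structure spans at least three native
voxels along each axis — in particular at least three of the coarse 250 µm
slices — so partial-volume boundary rendering stays a minor fraction of
each structure's volume under the ±1-voxel jitter, and after 200 µm FWHM
smoothing on the 50 µm template grid each structure retains a core of
voxels above the FA ≥ 0.2 threshold. The default lesion
(`default_lesion()`) multiplies the two radial eigenvalues by 1.25 inside
the cortex and callosum structures of mutant follow-up scans, lowering FA
there while sparing the "cst" cylinder; the affected region spans thousands
of 50 µm template voxels, well above the 256-voxel cluster floor, which is
what makes cluster-level recovery with Dice ≈ 0.9 possible at n = 9 per
group.

**Partial-volume rendering (`pv_samples`).** Each native voxel's generating
tensor is the average of the phantom tensor over `pv_samples^3` sub-voxel
midpoints (default 3³ = 27), mimicking how an MR voxel integrates the
underlying tissue. Averaging is done on the *tensor*, so the voxel signal
remains exactly mono-exponential in the averaged tensor and noise-free
tensor recovery is still exact to machine precision. The alternative —
evaluating the phantom only at the voxel centre — makes edge voxels flip
discretely between "inside" and "outside" as the subject jitter changes,
producing bimodal cross-subject distributions at structure boundaries.
Voxelwise t-tests are not calibrated on bimodal data at small n, and chance
perfect group splits then produce spurious p ≈ 1e−6 voxels that survive any
FDR procedure. Sub-voxel integration restores continuous, unimodal edge
distributions and with them the nominal type-I behaviour verified in the
null-cohort tests.

## 2. Tensor fit and scalar metrics

`fit_tensor()` solves the log-linearised Stejskal–Tanner system
`log(S/S0) = -b gᵀ D g` per voxel by ordinary (optionally signal-weighted)
least squares; `compute_metrics()` derives FA, MD, AD and RD from the
closed-form eigenvalues of the symmetric 3 × 3 tensor (`eig3_values()`).
With zero noise the fit recovers the generating field to < 1e−8 relative
error on a 64³ grid in well under a minute.

## 3. Template construction and normalization

`process_cohort()` runs quality control, tensor fitting, resampling of the
native maps onto an isotropic template grid, and iterative template
construction:

* **Template grid: 48 × 48 × 50 at 50 µm.** The in-plane extent matches the
  native 24 × 102 µm ≈ 2.45 mm field of view, and 50 slices cover the
  native 10 × 250 µm = 2.5 mm slab. Using the *native slab thickness* to
  set the slice count (rather than a cube) keeps the template isotropic
  without extrapolating beyond acquired data.
* **Registration** is landmark-based affine (`landmark_affine()`, exact
  least-squares Procrustes on the simulated landmark sets) followed by a
  light nonlinear refinement; `build_templates()` alternates
  register-to-mean / re-average symmetrically and stops when the minimum
  subject-to-template FA correlation exceeds `template_corr_stop = 0.7` or
  after `max_iter = 10`.
* **QC threshold 0.65.** `quality_check()` scores each diffusion-weighted
  volume by its voxelwise correlation with the median of its angularly
  nearest gradient directions (model-free: neighbouring directions see
  nearly the same tissue contrast, so a clean volume correlates highly with
  their median, while a motion- or dropout-corrupted volume, as produced by
  `corrupt_with_motion()`, does not). Clean simulated volumes score well
  above 0.8 and corrupted ones well below 0.5; the threshold 0.65 sits
  between those populations. A volume is flagged below 0.65, and a scan
  fails if more than `qc_max_bad_fraction = 10%` of its volumes are
  flagged, in which case `select_best_scan()` can fall back to a repeat
  acquisition.

## 4. Whole brain-based spatial statistics (WBSS)

`run_wbss()` evaluates one of four contrasts on smoothed template-space FA
maps: (a) genotype at baseline, (b) genotype at follow-up, (c) paired
within-group change, and (d) genotype difference in the per-day change map.
The statistical chain is: voxelwise two-sample (or paired) t-test within
the template FA ≥ 0.2 mask → Benjamini–Hochberg FDR at q = 0.05 →
26-connected component labelling → minimum cluster size 256 voxels
(256 × 50 µm³ voxels = 0.032 mm³, roughly one smoothing kernel volume, so a
surviving cluster cannot be a single-kernel noise blob).

`fdr_correct()` and `label_components()` are verified against brute-force
oracles — an all-thresholds BH scan and a stack-based flood fill — on
hundreds of random fields, and the full chain is verified on null cohorts
(no lesion, n = 5 per group), where at most one of 20 cohorts may show any
surviving cluster. The acceptance script runs the full 20 cohorts (~9 s
each); the test suite runs 8 with the same at-most-one bound to keep its
runtime within budget.

**Masked-truth Dice.** Recovery of a known lesion is scored as Dice overlap
between the surviving-cluster labels and the ground-truth lesion mask
*intersected with the analysis mask* (template FA ≥ 0.2). Lesion voxels
outside the analysis mask are untestable by construction, so including them
in the denominator would penalise the statistics for a masking decision
made upstream.

## 5. Longitudinal per-day change maps

`delta_map(m1, m2, t1, t2)` computes `(m2 − m1) / Δdays`. Two exact
identities are tested rather than tolerated: identical maps give an
identically zero rate map, and scaling the interval by k scales the map by
exactly 1/k. Contrast (d) above runs the group comparison on these rate
maps, which removes between-animal differences in scan interval.

## 6. Tractography and TFAS

`track_streamlines()` is deterministic streamline integration (fixed
25 µm steps, trilinearly interpolated principal eigenvector with per-step
sign alignment to the incoming direction, 45° angular threshold, FA ≥ 0.2
stopping, bidirectional from each seed, minimum track length 0.5 mm).
Geometry is validated analytically: on a uniform +x field the streamline
deviates from the seed line by less than one voxel, and on a circular
tangent field a quarter-arc's length matches (π/2)·R within 5 %.

`tfas()` computes each animal's mean FA over the tract occupancy mask
(voxels visited by at least one streamline of the selected bundle, within
the FA mask) and runs a two-sample genotype t-test per timepoint.

**Interpretation of the two-sample TFAS.** The tract is traced once, on the
all-scan average tensor field, and the same mask is applied to every
animal; the test therefore asks "does mean FA *within this common tract
region* differ between genotypes?", not "does each animal's individually
traced tract differ?". Animals with no supra-threshold voxel in the mask
carry NA and drop out of that cell. Because the spared-tract comparison is
a true null, its p-value is uniformly distributed — about 5 % of simulation
seeds will show p < 0.05 on the spared tract at some timepoint purely by
sampling; the per-timepoint baseline p-value should be inspected before
attributing a follow-up effect to pathology.

## 7. Two-way ANOVA from cell summaries

`anova_two_way()` accepts either raw per-animal values or `cell_summary()`
rows (group, level, n, mean, dispersion). From summaries it reconstructs
Type III sums of squares via the effect contrasts on cell means with a
pooled within-cell error term — algebraically identical to `car::Anova(lm(
..., contrasts = contr.sum), type = 3)` on raw data, which the test suite
cross-checks on unbalanced designs. Tukey honest significant differences
use the studentised range on the pooled error.

**Dispersion is interpreted as a standard deviation.** Published bar-graph
tables sometimes report SEM instead; `cell_summary()` takes `sem =` as an
alternative and converts exactly (`sd = sem * sqrt(n)`). With the packaged
neuron-density summaries (n = 3/3/3/4) the reconstruction reproduces the
printed F values — interaction 14.75, genotype 7.90, age 46.90 on 1 and 9
degrees of freedom — within 5 %, confirming the dispersions are SDs.

## Reproducibility

Every output CSV written by the CLI begins with a comment line carrying
`config_hash()` of the active `pipeline_config()`, and reruns with
identical inputs are byte-identical. The headline validation quantities can
be regenerated for any seed with:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
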