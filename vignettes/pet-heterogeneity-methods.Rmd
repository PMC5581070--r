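---
title: "Quantifying FDG-PET tumor heterogeneity and its association with EGFR/KRAS status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying FDG-PET tumor heterogeneity and its association with EGFR/KRAS status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pethet)
```

## The problem

Activating mutations in *EGFR* and *KRAS* define treatment-relevant molecular
subgroups of non-small-cell lung cancer, but mutation testing requires
tissue. FDG-PET is acquired routinely at staging, and both global uptake
(SUVmax, metabolic tumor volume, total lesion glycolysis) and *intratumoral
heterogeneity* of uptake plausibly carry molecular information. `pethet`
implements the full quantification-and-association chain: delineate the
metabolic tumor volume from an SUV image, extract uptake and heterogeneity
metrics, and test their association with mutation status across a cohort,
alongside clinical covariates (age, gender, smoking, stage).

Because no patient images or per-patient records are available, every stage
is exercised on synthetic data with known ground truth: 3-D SUV phantoms
with analytic lesion metrics, and simulated cohorts with a known
covariate–mutation–metric structure.

## Per-lesion metrics

Over the voxels of a volume of interest (VOI) with SUVs $v_1,\dots,v_n$ and
voxel volume $w$ (ml):

* $\mathrm{SUV}_{max} = \max_i v_i$, $\mathrm{SUV}_{mean} = \bar v$,
  $\mathrm{SD} = \sqrt{\tfrac1n\sum_i (v_i-\bar v)^2}$;
* $\mathrm{MTV} = n\,w$ (ml) and $\mathrm{TLG} = \mathrm{MTV}\cdot
  \mathrm{SUV}_{mean}$ — the identity is exact by construction;
* metabolic tumor diameter: the longest 3-D distance between VOI voxel
  centres (mm);
* $1/\mathrm{COV} = \mathrm{SUV}_{mean}/\mathrm{SD}$, a homogeneity score;
* AUC-CSH: the area under the cumulative SUV-volume histogram — the curve of
  the VOI volume fraction with SUV strictly above $t\cdot\mathrm{SUV}_{max}$
  as $t$ sweeps $[0,1]$. Uniform uptake gives 1; heterogeneity pulls it
  down.

Two conventions needed fixing where the source description is ambiguous or
internally inconsistent:

* **1/COV scale.** The methods phrasing of the original report suggests a
  percentage ($\times 100$), but the magnitudes it tabulates (roughly 1.5 to
  18) are only consistent with the bare ratio $\mathrm{SUV}_{mean}/
  \mathrm{SD}$. The bare ratio is implemented.
* **SD denominator.** Population ($n$) by default; the $n-1$ alternative is
  a switch (`sd_denominator`) and the choice is recorded in the metric
  provenance. For VOIs of hundreds of voxels the difference is far below
  reported precision.

In the continuous-threshold limit the AUC-CSH of any non-negative uptake
profile equals $\mathrm{SUV}_{mean}/\mathrm{SUV}_{max}$ (integrate
$\int_0^1 \Pr(V > t\,V_{max})\,dt$). This identity gives the generator its
closed-form ground truth; the binned curve (default 1000 uniform thresholds,
trapezoidal rule) converges to it with error below $1/n_{thresholds}$, i.e.
well under the two decimals at which the score is reported. The strict
inequality ("above" the threshold) has a measure-zero effect on the
integral; it matters only at the exact threshold values of a discrete lesion.

**Eligibility.** Heterogeneity scores computed over a handful of voxels are
noise. Lesions with a metabolic diameter under 10 mm have SD (as a
heterogeneity index), 1/COV and AUC-CSH set to `NA`
(`apply_eligibility`); exactly 10 mm is eligible. The size *strata* used by
the association screen ("> 1 cm", "> 2 cm", "> 3 cm") are strict
exclusive thresholds, except that the 1 cm stratum coincides with the
inclusive eligibility set — mirroring the convention of the original
analysis, where the 10 mm rule is stated inclusively but the strata are
labelled with ">".

## Delineation

The original measurements used a commercial gradient-based edge tool with
manual adjustment. The algorithm is proprietary, so `petedge_segment` is a
*declared emulation* of the published class of gradient methods, and its
provenance tag says so:

1. locate the local SUV maximum within 20 mm of the seed;
2. cast rays from the peak in the 26 lattice directions, resampling the SUV
   profile at 1 mm by trilinear interpolation;
3. per ray, place the edge at the maximum spatial-gradient magnitude
   (central differences, parabolic sub-sample refinement);
4. interpolate the edge radius between rays (inverse-squared-angle
   weighting) and keep the 26-connected component containing the peak.

On noiseless high-contrast spheres this recovers the ground-truth mask at
Dice ≥ 0.95 with every boundary voxel within one voxel of the analytic
surface. On lesions with a strong *internal* step (two-compartment,
necrotic core) the strongest gradient can sit at the inner interface, and
the emulation then delineates the inner compartment — the expected behaviour
of any gradient method and the reason a fixed-fraction threshold segmenter
(`threshold_segment`, default 42% of local SUVmax) is provided as a
sensitivity check. Both methods are invariant to positive rescaling of the
volume, and both refuse a seed placed in background ("no lesion at seed":
no voxel above the local median + 3 robust SDs within 20 mm). There is no
interactive adjustment step; a user-supplied mask (`read_mask`) is the
override path.

The longest diameter is computed in 3-D by default (the original report does
not state whether measurements were in-plane); `mode = "axial"` restricts
pairs to a common axial plane. Only boundary voxels are searched — the
maximum cannot occur at an interior voxel — and the result equals the
exhaustive all-pairs maximum (tested exactly on small masks). Background and
blood-pool uptake are measured with the conventional 10 mm circular ROI on a
transaxial plane (`circular_roi`).

## The phantom generator

`generate_phantom` emulates what the metrics need from a thorax PET volume
and nothing more: six axis-aligned rectangular lung fields at the normal
SUVmean levels (0.4–0.6 by field), a central blood-pool column at 1.7,
additive Gaussian noise clipped at zero (SUV cannot be negative; the source
gives no noise model), and lesions voxelized by centre-sampling (a voxel
belongs to the lesion iff its centre is inside the analytic shape — simple,
unambiguous, and matched to the voxel-counting oracle). The default noise SD
(0.1 SUV) sits at the lower end of the between-patient field SDs, read as an
upper bound on within-image noise.

Each lesion carries analytic ground truth from the closed-form moments of
its uptake model; e.g. a two-compartment lesion with volume fraction $f$ at
peak and the rest at $s\cdot$peak has
$\mathrm{SUV}_{mean} = (f + (1-f)s)\,\mathrm{peak}$,
$\mathrm{SD} = \sqrt{f(1-f)}\,(1-s)\,\mathrm{peak}$ and
$\mathrm{AUC} = s + (1-s)f$.

What the phantom deliberately does **not** model: scanner physics
(reconstruction point-spread, attenuation, scatter), respiratory motion,
anatomical lobe shapes. Passing tests therefore demonstrate correctness of
the measurement chain on idealized volumes, not robustness to
reconstruction artefacts; partial-volume blur in real PET would shrink
gradients and bias small-lesion metrics in ways these phantoms cannot show.

## The cohort generator

`generate_cohort` draws a synthetic surgical cohort whose defaults are the
study conditions of the 131-patient reference cohort: 86/131 male; smoking
current/former/never 22/77/32 with gender-specific composition; age
~ N(67, 10) truncated to 24–86; pack-years zero for never-smokers and
Gamma(mean 30) otherwise; the published stage distribution; EGFR and KRAS
missing in 4/131 and 5/131. Mutation status follows a logistic model whose
default intercept and never-smoker coefficient are derived from the
published cross counts (EGFR+ odds 18:13 in never-smokers vs 14:82 in
ever-smokers; KRAS+ 3:27 vs 28:68), giving marginal prevalences near
25%.

Lesion-metric distributions (diameter lognormal around 33 ± 27 mm; SUVmax
lognormal; 1/COV Gamma; AUC-CSH a noisy monotone transform of 1/COV mapped
into its observed 0.28–0.86 range; TLG and SD derived exactly from the
definitional identities) are keyed on **smoking status** by default rather
than on mutation class: ever-smokers draw higher-uptake, more heterogeneous
lesions. This single confounder structure reproduces, at once, the marginal
metric differences by EGFR class *and* the signature multivariate pattern —
metrics significant univariately but not conditionally on smoking — which is
the central finding the association battery must be able to exhibit. A
`metric_link = "mutation"` mode retains the direct per-class assignment, and
`metric_link = "none"` plus an intercept-only mutation model yields the null
cohorts used for type-I-error calibration. About 9–10% of simulated
diameters fall below 10 mm, matching the 14/131 heterogeneity-ineligible
rate. All of these calibrations were fixed once from the published summary
tables; they are conditions of the simulation, not tuning knobs.

## The statistical battery

* **Mann-Whitney** (`mannwhitney`): exact two-sided p by enumeration when
  the smaller group has ≤ 8 observations and the data are tie-free,
  otherwise the normal approximation with tie and continuity correction.
  The exact mode is verified against an independent brute-force enumeration
  oracle; across all attainable U values at 8 vs 8 the two modes differ by
  < 0.01 on average (worst case ~0.04 in the far tails).
* **Categorical association** (`categorical_assoc`): Pearson chi-square
  *without* continuity correction by default — the convention that
  reproduces the published gender–EGFR p (0.0464, printed 0.047) from the
  published counts; Fisher's exact test by flag. (The printed KRAS–smoking
  p of 0.018 is not reproducible from the printed counts by either test —
  uncorrected chi-square gives 0.033, Fisher 0.044 — so it is not used as an
  anchor.)
* **Univariate screen** (`univariate_scan`): the original "univariate
  analysis" for continuous indices is unnamed and its p-values differ from
  the tabulated Mann-Whitney ones, so both are computed and reported side by
  side — Mann-Whitney (`p_mw`) and the univariate logistic score (Rao) test
  (`p_score`, the primary `p` for continuous rows). Staging is screened as
  IA/IB vs higher (the early-stage split the cohort description
  emphasizes); smoking as never vs current+former. Complete cases per row,
  group sizes always reported, no multiplicity correction (matching the
  reproduced analysis); a Benjamini–Hochberg column is appended and labelled
  supplementary.
* **Multivariate model** (`multivariate_logistic`): maximum-likelihood
  logistic fit with Wald p-values; default predictors gender, smoking,
  SUVmax, 1/COV. Separation is detected (divergent coefficients with
  blown-up SEs, or the 0/1 fitted-probability warning) and flagged with
  p-values suppressed rather than reported from a divergent fit. A
  fewer-than-10-cases-per-predictor fit warns.

Significance is two-sided at 0.05 throughout.

## Numerical and degenerate-input choices

* Connectivity is 26 everywhere (recorded in mask provenance); the 3-D
  connected-component labelling is a vectorised flood fill written for this
  package (no installed R package labels 3-D components).
* A perfectly homogeneous lesion has SD = 0: 1/COV is `NA` with a warning,
  never `Inf`.
* A VOI with SUVmax = 0 has no CSH ("no uptake" error).
* A single-voxel mask has diameter 0 and is flagged sub-resolution.
* Mask/volume alignment (shape and spacing) is checked before any metric.
* All simulation entry points take one integer seed and are bit-reproducible
  for a fixed seed.

## Problem sizes used by the test-suite

The suite's simulations were sized to give stable checks at interactive
runtimes: type-I error of the scan from 1000 null cohorts of n = 300;
Wald-CI coverage from 200 cohorts of n = 1000; the confounding pattern from
30 cohorts of n = 500; phantom oracles at 1 mm voxels (spheres of 20–30 mm).
Larger sizes change none of the conclusions, only the Monte-Carlo width of
the bands.

## Limitations

* The gradient delineation is an emulation; agreement with any specific
  commercial tool on real images is untested and untestable here.
* Phantoms omit scanner physics; absolute metric accuracy on real
  reconstructions (especially partial-volume effects below ~2 voxels of
  lesion diameter) is out of scope.
* The cohort simulator reproduces published *marginal* and two-way
  structure; real three-way joint structure is unknown and arbitrary in the
  reconstruction helper (`cohort_from_counts`).
* Prognosis/survival endpoints are not modelled — the reference analysis
  had none available.
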