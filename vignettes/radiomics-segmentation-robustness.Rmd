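---
title: "Methods: segmentation robustness of radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation robustness of radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrobust)
```

## The question the package addresses

Radiomic analyses mine quantitative descriptors — intensity histograms,
3D shape measures, gray-level texture statistics — from segmented tumor
volumes. Every descriptor therefore inherits the variability of the
segmentation it was computed on. Manual slice-by-slice contouring is the
clinical default but is slow and shows substantial inter-observer
variability; semi-automatic competitive region growing (GrowCut) needs only
rough foreground/background strokes and is far more repeatable. The package
implements the full comparison as a simulation study: it synthesizes tumors
with known ground truth, simulates both kinds of observers, extracts a
56-feature radiomic panel from every segmentation, and quantifies feature
reproducibility with intraclass correlation coefficients (ICC),
reproducibility classes, Wilcoxon rank-sum comparisons and Z-normalized
feature ranges.

Because the observers are simulated, absolute ICC levels are properties of
the chosen observer models, not of any patient cohort; what the simulation
is designed to establish is the *structure* of the comparison — that when
manual boundary variability exceeds stroke-level variability, the
semi-automatic pipeline yields systematically more reproducible features.

## The synthetic cohort

`phantom_spec()` describes one CT-like tumor:

* a star-shaped lesion: a sphere of radius `lesion_radius` (default 10 mm)
  modulated by `spiculation_count` von Mises–Fisher surface bumps of height
  up to `spiculation_amplitude` (mm) — spiculated margins are a hallmark of
  malignant lung lesions, and they are exactly the fine-scale shape detail
  manual contouring smooths away;
* intensities: tumor core 40 HU against a lung-like background of −800 HU,
  a partial-volume edge ramp (`edge_blur`, Gaussian sigma 0.8 mm),
  spatially correlated intratumoral texture (Gaussian correlation length
  `texture_correlation_length`, amplitude `texture_sd` = 50 HU) and white
  acquisition noise (`noise_sd` = 20 HU). The correlated texture is what
  makes the co-occurrence and run-length features non-trivial and gives
  them between-tumor variance, without which no ICC is estimable.

The default grid is 40×40×22 voxels at 1×1×2 mm — a realistic thoracic CT
anisotropy, sized so that the largest drawn lesion keeps a ≥ 2-voxel
margin. `study_config()` draws per-tumor parameters (radius 7–12 mm,
0–8 spiculations, amplitude 0.5–2 mm, correlation length 2–5 mm) and fixes
the canonical design: 20 tumors, 5 manual observers, 3 semi-automatic
observers × 2 runs = 11 segmentations per tumor. Everything is a pure
function of `master_seed`.

What the generator does *not* emulate: PET guidance, pleural or vascular
attachment, respiratory motion, dose/reconstruction-dependent noise
texture, and reader fatigue. Passing tests therefore show that the
statistical machinery behaves correctly under controlled variance
orderings; they do not certify absolute reproducibility levels on real CT.

## Observer models

**Manual** (`observer_model("manual")`): the truth surface is displaced
radially by a smooth random field. The field is white noise smoothed to
FWHM `smoothing_fwhm` (default 4 mm), sampled on the sphere of
volume-equivalent radius so the displacement is constant along rays,
scaled to `boundary_jitter_sd` (default 1.5 mm), and added to the signed
Euclidean distance of the truth together with the observer's
`systematic_bias` (drawn once per observer, sd 0.5 mm — physicians contour
systematically tighter or looser). Morphological closing-then-opening with
radius FWHM/2 then removes fine detail, mirroring the smoothing-out of
subtle spiculations in hand-drawn contours; the largest connected
component is kept.

**Semi-automatic** (`observer_model("semiauto")`): foreground strokes are
random short walks inside the truth eroded by 20 % of the equivalent
radius; background strokes are placed in a surrounding shell, stratified
over azimuth so their convex hull encloses the lesion. GrowCut then runs to
convergence and isolated foreground islands are removed. Run-to-run
variability comes only from stroke randomization; each observer carries a
small idiosyncratic stroke-margin factor (±15 %).

With these defaults manual inter-observer mask variance exceeds
semi-automatic variance by construction — the qualitative regime the study
design assumes. No published Dice statistics exist for the original
observers, so the jitter scale was fixed once at values giving
inter-observer Dice ≈ 0.85–0.92 for manual and ≥ 0.95 for semi-automatic
masks, consistent with reported lung GTV delineation variability.

## GrowCut

Every voxel holds a label and a strength θ ∈ [0, 1]; seeds start at θ = 1.
A labeled neighbor *q* conquers voxel *p* when
g(|C_p − C_q|)·θ_q > θ_p, with g(x) = 1 − x/max‖ΔC‖ and the intensity
scale fixed over the region of interest before iterating. Updates are
synchronous, so a run is deterministic given its seeds; strengths are
non-decreasing and bounded, and convergence is declared when a sweep
changes no label. The ROI is the discrete convex hull of the seeds
(exact 64-bit integer half-space tests, with rank-0/1/2 degenerate seed
sets handled exactly) dilated by a configurable margin — the hull margin
is not documented for the original interactive tool, so it is exposed as
`margin_voxels` (default 2). The automaton neighborhood is 26-connected,
matching the texture connectivity; seeds can never be overrun (g ≤ 1), and
voxels outside the ROI never change.

## The 56-feature panel

*First order (15)*: energy, entropy, interquartile range, kurtosis,
maximum, mean absolute deviation, mean, median, minimum, range, RMS,
skewness, SD, uniformity, variance. Moments are population (biased) by
default (`unbiased = TRUE` switches), kurtosis is non-excess, and
entropy/uniformity are computed on the same fixed-bin-width discretization
as the texture matrices (25 HU default) so one discretization pass governs
all histogram-based features. The canonical first-order list has 14
members; this panel's 15th, the interquartile range, is the package's own
choice of a standard robust spread descriptor.

*Shape (8)*: volume, surface area, surface-to-volume ratio,
compactness 1 and 2, spherical disproportion, sphericity, maximum 3D
diameter. Surface area uses a marching-tetrahedra mesh at iso-level 0.5 on
the mask indicator smoothed with sigma = 1 voxel: meshing the raw binary
field overestimates a digitized sphere's area by ≈ 25 % (staircase
artifact) and breaks the sphere limits (sphericity → 1); with sigma = 1
the error is 0.3–4 % over radii 8–20 voxels. The calibration target is
the closed-form sphere, i.e. an estimator-accuracy choice, and voxel-face
counting remains available (`area_mode = "voxel"`).

*Texture (33)*: 22 co-occurrence (Haralick-type) and 11 run-length
(Galloway-type) features. Matrices are built per direction over the 13
symmetric 3D directions (unique up to negation; union with negations is
the 26-neighborhood) at distance 1, co-occurrences counted symmetrically,
runs broken at the mask boundary; features are computed per direction and
averaged arithmetically (not pooled into one matrix). Entropies are in
bits. Two definitional choices the ambiguity of the classic literature
forces: homogeneity 1 uses 1 + |i−j| and homogeneity 2 uses 1 + (i−j)²
denominators, and sum variance is centered on the sum average (the classic
centering on sum entropy is widely regarded as a misprint). Undefined
values (e.g. correlation at zero marginal variance) are explicit `NA`s,
never zeros, and direction averaging skips undefined directions.

## Reproducibility statistics

For each feature a subjects × raters matrix (tumors × observers) feeds one
of two ANOVA estimators:

* inter-observer sets (5 manual; each 3-observer semi-auto run set):
  two-way mixed, absolute agreement, single rater —
  ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE));
* intra-observer run pairs: one-way —
  ICC = (MSR − MSW) / (MSR + (k−1)·MSW).

Raw estimates can be negative; they are preserved but clamped to [0, 1]
for classification into high (ICC ≥ 0.8), medium (0.8 > ICC ≥ 0.5) and low
(ICC < 0.5) reproducibility, with closed lower bounds at both thresholds.
Tumors with undefined feature values are dropped row-wise with a logged
count, not imputed. Group comparisons use the two-sample rank-sum test
(exact for combined n ≤ 20 without ties; normal approximation with tie
correction otherwise; all-tied inputs give p = 1) even though per-feature
ICCs are pairable — the unpaired comparison is the more conservative and
is the one the study design prescribes.

For the range analysis each (tumor, feature) cell's 11 observer values are
Z-scored together; per group the min, max and range of the Z-scores are
averaged over tumors and the two groups compared across the 56 features.
A pooled-across-tumors normalization mode exists
(`znormalize_and_range(..., mode = "pooled")`) because the per-tumor
reading, while the more natural one, is not the only possible one; the
report records which mode produced its numbers. Cells with zero spread get
Z = 0 and are counted in `n_zero_sd`.

## Numerical choices

* Sub-seeds for tumors/observers/runs come from an integer mixing chain,
  keeping every stage independently reproducible below 2³¹.
* The partial-volume ramp snaps values within 1e−9 of 0/1, so noise-free
  homogeneous phantoms have a bit-exact core.
* Largest-component ties break to the component whose smallest linear
  voxel index is lowest; GrowCut attack ties break to the first neighbor
  in a fixed scan order — both deterministic.
* Distance transforms are exact Euclidean (lower-envelope algorithm) with
  anisotropic spacing; metric morphology (erosion/dilation/smoothing by mm
  radii) is built on them.
* Empty matrices, empty masks, single-voxel masks and all-tied rank-sum
  inputs all take explicit flagged paths rather than producing silent
  zeros.

## Problem sizes in the test-suite

The suite exercises the full default design: oracle equivalence on fifty
random 6×6×6 volumes (naive triple-loop co-occurrence/run-length oracles,
1e−10 tolerance) and one hundred random ratings matrices (explicit
sum-of-squares ANOVA); variance-component recovery at n = 200 subjects
× 100 replicates; and twenty full 20-tumor end-to-end replicates for the
qualitative ordering (semi-auto ICC above manual, significantly smaller
normalized range). These sizes were chosen as the smallest at which each
property is sharply testable.

## Known limitations

* Observer realism is bounded by the two-parameter displacement model; real
  contouring errors are structured (slice-wise, anatomy-driven).
* The GrowCut attack rule is the standard cellular-automaton form; the
  original interactive tool adds manual post-editing that is out of scope.
* Absolute ICC levels depend on the generator's variance settings and
  should not be read as predictions for patient data.
* NRRD support covers the raw little-endian single-file flavor the package
  writes (plus common integer types on read); gzip-encoded NRRD is not
  parsed — use NIfTI for compressed interchange.
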