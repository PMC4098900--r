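# radrobust

Segmentation robustness of radiomic features, as a reproducible simulation
study in R.

Radiomic features — first-order intensity statistics, 3D shape descriptors,
gray-level co-occurrence (GLCM) and run-length (GLRLM) texture features —
are computed over a segmented tumor volume, so their reliability is capped
by the reliability of the segmentation. `radrobust` implements the full
comparison between manual contouring and semi-automatic GrowCut
segmentation as a tested pipeline:

1. **Phantoms** — synthetic CT-like lung tumors (spiculated star-shaped
   lesions, correlated intratumoral texture, partial-volume edges, noise)
   with known ground truth;
2. **Observers** — simulated manual delineations (smooth random radial
   boundary displacement + per-observer systematic bias + morphological
   smoothing) and semi-automatic segmentations (GrowCut cellular automaton
   seeded by randomized foreground/background strokes);
3. **Features** — a 56-feature panel: 15 first-order, 8 shape, 33 texture
   features computed over the 13 symmetric 3D directions at distance 1 and
   averaged;
4. **Reproducibility** — per-feature intraclass correlation coefficients
   from ANOVA mean squares, two estimators:

   * inter-observer (two-way mixed model, absolute agreement, single
     rater): `ICC = (MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`
   * intra-observer (one-way model): `ICC = (MSR − MSW) / (MSR + (k−1)MSW)`

   plus reproducibility classes (high ICC ≥ 0.8, medium 0.8 > ICC ≥ 0.5,
   low ICC < 0.5), Wilcoxon rank-sum group comparisons, and Z-score
   normalized feature-range analysis across the 11 segmentations of each
   tumor (5 manual + 3 observers × 2 GrowCut runs).

The design mirrors a classic multi-observer CT study: 20 tumors, 5 manual
observers, 3 semi-automatic observers segmenting twice.

## Worked example

```r
library(radrobust)
report <- run_study(study_config(master_seed = 1))
report
#> <radrobust_report>
#>   56 features x 20 tumors, 11 segmentations/tumor
#>   inter-observer ICC: manual 0.40+/-0.31, semi-auto 0.85+/-0.25 (p = 1.18e-11)
#>   intra-observer ICC (semi-auto): 0.84+/-0.26
#>   features with higher semi-auto ICC: 47/56
#>   normalized range p = 3.79e-14 (lower 0.265, upper 5.14e-12)
```

Reading: averaged over the 56 features, semi-automatic segmentations give a
mean inter-observer ICC of 0.85 versus 0.40 for simulated manual contours
(rank-sum p ≈ 1e−11), 47 of 56 features are individually more reproducible
under GrowCut, and the Z-normalized spread of feature values across
observers is significantly narrower (range p ≈ 4e−14). The absolute ICC
levels are properties of the simulated observer models; the ordering is
the finding. `summary(report)` adds per-family (intensity/shape/texture)
breakdowns; `plot(report, which = "boxplot")` shows the ICC distributions
per observer set.

Lower-level entry points: `generate_phantom()`, `simulate_manual_mask()`,
`simulate_semiauto_mask()`, `growcut()`, `extract_features()`,
`icc_twoway_mixed_absolute()` / `icc_oneway()`, `analyze_features()`.
Volumes and masks round-trip through NRRD or NIfTI-1
(`read_volume()`/`write_mask()`/...), and a command-line front end lives at
`inst/cli/radrobust.R` (`simulate | segment | extract | compare |
run-study`).

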