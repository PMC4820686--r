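# kidneyseg

Coarse-to-fine kidney segmentation for abdominal CT slice sequences in R.

Kidney delineation is a prerequisite for surgical planning and ablation
guidance, but it is tedious to do by hand and hard to automate because
kidney parenchyma has nearly the same CT intensity as adjacent organs
(liver, spleen). `kidneyseg` implements a two-stage pipeline that needs
exactly **one** manual input — a rectangle drawn around the kidney on the
slice with its largest cross-section — and segments the rest of the
sequence automatically:

1. **Rough stage (SKFCM).** Each slice is median-filtered, cropped, and
   clustered with spatially constrained kernel fuzzy c-means. The
   objective is

   J_m = Σᵢ Σₖ u_{ik}^m (1 − K(x_k, v_i)) + α Σᵢ Σₖ u_{ik}^m (1 − K(x̄_k, v_i)),

   where K is a Gaussian kernel, x̄_k is the mean of pixel k's 8
   neighbors, and memberships/centroids are updated by alternating
   iterations until the centroids stop moving. The modal cluster,
   reduced to its largest connected region, hole-filled and smoothed,
   is the candidate kidney; its minimum bounding rectangle extended by
   10 px crops the adjacent slice, so the crop propagates through the
   stack in both directions.

2. **Refinement stage (automatically seeded GrowCut).** Slices whose
   rough mask changes abruptly relative to their neighbor (or loses
   solidity) are re-segmented by a GrowCut cellular automaton. Each
   cell carries (label l_p, strength θ_p, intensity C_p); a neighbor q
   conquers p when g(|C_p − C_q|)·θ_q > θ_p with g(d) = 1 − d. The
   seed labels are generated automatically from the contour of the
   adjacent, already-accepted slice: foreground seeds T₁ px inside the
   contour, background seeds T₂ px outside, placed vertically where
   the contour is locally horizontal (altitude difference d_y < T_h)
   and horizontally otherwise. No user interaction is consumed.

The package also provides the standard evaluation metrics (accuracy,
Jaccard overlap, sensitivity, specificity from TP/FP/FN/TN), readers and
writers for NIfTI volumes and PNG/TIFF stacks, and a deterministic
synthetic phantom generator with ground truth, so the whole pipeline is
testable without patient data.

## Worked example

Segment the default 20-slice synthetic phantom from its suggested
starting box and evaluate against ground truth:

```r
library(kidneyseg)

ph <- generate_phantom(phantom_spec(rng_seed = 1))
print(ph$start_bbox)
#> <bbox rows 29..99, cols 27..125>

run <- run_pipeline(ph$volume, ph$start_index, ph$start_bbox)
print(run)
#> <pipeline_run: 20 slices, 6 flagged, 6 refined, 2 failed>

ord <- order(as.integer(names(run$masks)))
ev  <- evaluate_masks(unname(run$masks[ord]), ph$truth)
print(vapply(ev$pooled, round, numeric(1), digits = 4))
#>    accuracy     overlap sensitivity specificity
#>      0.9867      0.9280      0.9435      0.9963
```

The report says 6 of 20 slices were flagged by the refinement criterion
(2 of them because the rough candidate was degenerate) and re-segmented
with automatically seeded GrowCut — on real CT the authors of this class
of method find roughly half of slices need refinement. The pooled
metrics compare every final mask against the phantom's noiseless truth:
94.4% of kidney pixels are recovered (sensitivity) while 99.6% of
non-kidney pixels are rejected (specificity).

A command-line front end is installed with the package
(`system.file("scripts", "kidneyseg", package = "kidneyseg")`) with
subcommands `phantom`, `rough`, `run`, `growcut`, and `evaluate`.

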