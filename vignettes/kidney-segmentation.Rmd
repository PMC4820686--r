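---
title: "Coarse-to-fine kidney segmentation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine kidney segmentation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyseg)
```

# The problem

Kidney parenchyma in abdominal CT has an attenuation very close to that
of neighboring organs, so purely intensity-based segmentation of a
single slice is unreliable, while fully manual contouring of a
200–300-slice series is prohibitively slow. This package exploits the
spatial continuity of thin-slice CT: the kidney cross-section changes
little between adjacent slices, so one manual rectangle on the slice
with the largest cross-section can be propagated through the whole
stack, and a slice that segments poorly can borrow seed information from
its already-segmented neighbor.

# Stage 1: rough segmentation with SKFCM

## Model

Spatially constrained kernel fuzzy c-means clusters the pixel
intensities $x_k \in [0,1]$ of the cropped slice into $c$ fuzzy classes
by minimizing

$$J_m=\sum_{i=1}^{c}\sum_{k=1}^{N} u_{ik}^m\,\bigl(1-K(x_k,v_i)\bigr)
 \;+\;\alpha\sum_{i=1}^{c}\sum_{k=1}^{N} u_{ik}^m\,\bigl(1-K(\bar x_k,v_i)\bigr),$$

where $K(x,v)=\exp(-(x-v)^2/2\sigma^2)$ is a Gaussian kernel,
$\bar x_k$ is the mean of the 8 neighbors of pixel $k$ (center
excluded, reflect-padded at borders), $u_{ik}$ are memberships summing
to 1 over clusters, and $v_i$ are intensity centroids. The kernel
distance $1-K$ saturates for far-away values, which damps the influence
of outliers; the $\alpha$-weighted term ties each pixel to its
neighborhood mean, which suppresses isolated noise labels. Memberships
and centroids are updated in alternation (the membership update
normalizes $d_{ik}^{-1/(m-1)}$ over clusters; the centroid update is the
kernel-weighted mean with the previous iterate inside the kernel) until
$\lVert V_{new}-V_{old}\rVert_\infty < \varepsilon$.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `c` | 4 | number of intensity classes. In a tight kidney crop the natural populations are background, boundary/partial-volume pixels, neighbor organ, and kidney. |
| `m` | 2.0 | fuzziness exponent; the standard FCM choice. |
| `alpha` | 1.0 | spatial-penalty weight; equal weight to the neighborhood term, the usual convention for this family of algorithms. |
| `sigma` | 0.2 | kernel bandwidth in normalized-intensity units, of the order of inter-tissue contrast after the volume-wide rescale to $[0,1]$. |
| `eps` | 1e-4 | infinity-norm centroid-change tolerance. |

Initialization is deterministic: centroids start at the
$(i-0.5)/c$ intensity quantiles of the crop. After convergence the
centroids are sorted ascending and hard labels are the argmax
membership (ties to the lowest index), so cluster indices are
reproducible run to run. Degenerate pixels whose kernel distance to a
centroid is exactly zero receive full membership on the singular
cluster(s), split equally on ties — the closed-form update divides by
zero there.

## The six per-slice steps and their failure mode

Median filter (3×3, reflect-padded) → crop → SKFCM → modal cluster →
largest connected region → hole filling (vessels rejected by clustering
leave holes) → morphological opening+closing with a disk of radius 2.
The mask's minimum bounding rectangle, extended by `margin` (default
10 px) and clamped to the image, crops the adjacent slice; propagation
runs independently up-stack and down-stack from the seed slice, since
the largest cross-section lies mid-kidney.

Two situations are declared *failure* for a slice rather than producing
a mask: an empty candidate after smoothing, and a fragmented modal
cluster — when the largest connected region holds less than
`min_component_frac` (default 0.75) of the modal cluster's pixels. A
kidney cross-section is one coherent region; a modal cluster that is a
scatter of noise fragments means the crop contains no organ (this is
what terminates propagation when the kidney ends). On a failed slice
the previous crop box is reused once; after two consecutive failures
propagation stops in that direction.

The modal-cluster rule assumes the kidney is the most numerous tissue
class inside the crop. This holds for tight manual rectangles on real
CT (a kidney roughly fills half of its 10-px-extended bounding box at
sub-millimeter pixel spacing) but can fail for loose crops, where the
background class wins — the refinement criterion catches such slices.

# Stage 2: refinement with automatically seeded GrowCut

## The cellular automaton

Each pixel is a cell with state $(l_p, \theta_p, C_p)$: label in
$\{-1, 0, +1\}$, strength in $[0,1]$, and feature = intensity. Seeded
cells start at strength 1, everything else unlabeled at strength 0.
All cells update synchronously: among the neighbors $q$ (Moore
8-neighborhood by default) whose attack force
$g(\lVert C_p-C_q\rVert)\cdot\theta_q$ with $g(d)=1-d$ strictly exceeds
$\theta_p$, the strongest conquers $p$, copying its label and setting
$\theta_p$ to the force. Force ties are broken by a fixed row-major
neighbor scan order, which together with the synchronous update makes
the automaton fully deterministic. Strengths are monotone
non-decreasing and bounded, so the automaton terminates; iteration
stops when no cell changes. The normalizing constant in $g$ is 1
because intensities are pre-normalized to $[0,1]$ volume-wide.

## Automatic seeding from the adjacent slice

The contour of the template mask (the adjacent slice's accepted
segmentation) is traced clockwise by Moore boundary tracing. At each
traced point (subsampled by `step`, default 1) the *altitude
difference* $d_y$ — the absolute row change between the points `step`
positions ahead and behind on the chain — decides the placement axis:
$d_y < T_h$ means the contour is locally horizontal and seeds are
placed vertically, otherwise horizontally. The foreground seed goes
$T_1$ px on the interior side (resolved by testing which candidate lies
inside the template, robust to concave contours), the background seed
$T_2$ px on the exterior side; candidates out of bounds or on the wrong
side are discarded.

$T_h=1$, $T_1=T_2=3$ by default: the offsets must exceed the contour
drift between adjacent 0.5–1 mm slices (a pixel or two) yet stay inside
thin kidney sections. The automaton runs on the cropped window, not the
full slice, mirroring the crop propagation and bounding runtime.

## Which slices are refined, and with which template

A slice needs refinement when its rough mask area changes by more than
10% relative to its toward-seed neighbor, or when its solidity
(area over convex-hull area, computed exactly on lattice points via
Pick's theorem) drops below 0.85. The criterion itself is a design
choice — the upstream literature states only that about half of slices
need no refinement — and both thresholds are configurable.

Templates chain outward from the seed slice: a flagged slice is refined
against the final (refined or rough) mask of its adjacent toward-seed
neighbor. An earlier design used the nearest *unflagged* slice as
template, but for runs of consecutive flagged slices near the kidney
poles that template is several slices away; seeds generated from a
too-distant contour straddle the true boundary and the error compounds.
Chaining keeps the template both adjacent and already accepted, which
is exactly the condition the seeding relies on. Refined masks are
canonicalized (largest component, holes filled) before use, since a
stray pixel would break contour tracing. Finally every mask receives a
morphological closing (disk radius 1) — closing is extensive, so thin
kidney poles are not eroded.

# The synthetic phantom

Patient data cannot ship with the package, so all tests run on a
deterministic phantom emulating the conditions the pipeline assumes: a
bright convex "kidney" ellipse (intensity 0.62) abutting a larger
similar-intensity neighbor structure (0.58, the liver/spleen confound)
over a dark background (0.25), with additive Gaussian noise
(sd 0.03), a low-frequency multiplicative gain field, and ground-truth
masks. Across 20 slices the kidney's semi-axes vary smoothly with a
mid-stack maximum and its center drifts at most one pixel per slice.

Geometry choices that matter and why:

* **Kidney size** (semi-axes 26×40 px on a 128×128 slice): the kidney
  fills roughly half of its 10-px-extended bounding rectangle, the
  proportion a tightly boxed kidney occupies in sub-millimeter CT.
  Because the crop margin is a fixed pixel count, a phantom kidney much
  smaller than this would make the crop unrealistically loose and break
  the modal-cluster assumption for reasons that have nothing to do with
  real data.
* **Cross-section profile**: a 20-slice stack at sub-millimeter slice
  spacing spans a small fraction of a kidney, so adjacent true masks
  overlap at Jaccard ≈ 0.93–0.98. The automatic seeding budget
  ($T_1=T_2=3$) is calibrated to exactly this continuity; a phantom
  whose kidney shrank 20% per slice would violate the physical premise
  the method rests on.
* **Neighbor contrast 0.04**: close enough that the confound is real
  (noise sd comparable to the contrast), separable enough that the task
  is well posed.
* **Gain field amplitude 0.01** (cap 0.05): small relative to the 0.04
  tissue contrast. Intensity clustering presumes roughly stationary
  class means; stronger bias fields would require bias-field
  correction, which is outside this pipeline's scope.
* **Noise sd 0.03**: chosen so the rough stage fails on occasional
  slices — on the order of a quarter to a half of the stack, matching
  experience on real CT — so the refinement path is genuinely
  exercised. The high-noise variant (sd 0.08) used in testing makes
  rough failure the norm and shows the refinement's improvement
  directly.

What the phantom does *not* emulate: anatomical shape variation,
Hounsfield calibration, ribs/fat/vessels, partial-volume effects beyond
what median filtering induces, and streak or beam-hardening artifacts.
Passing tests therefore demonstrate the algorithmic contracts and the
pipeline's behavior under controlled confounds, not clinical
performance.

# Numerical conventions

* Intensities are normalized to $[0,1]$ once, volume-wide, at load (a
  constant volume maps to zeros), so centroids and feature distances
  are comparable across slices. DICOM rescale slope/intercept handling
  is out of scope (no DICOM reader; convert to NIfTI first).
* Bounding boxes are 1-based inclusive `(row_lo, col_lo, row_hi,
  col_hi)` — native R slicing; rows increase downward.
* Median filter and neighborhood means use symmetric (edge-repeating)
  reflection, so no artificial extremes enter at borders.
* Component ties (equal areas) go to the component whose top-left-most
  pixel is smallest in (row, col) order; modal-cluster ties go to the
  brighter centroid; attacker-force ties to the first neighbor in scan
  order. All three rules exist purely for determinism: two identical
  runs are bit-identical.
* An empty cluster during the centroid update (possible after singular
  membership assignments) is re-seeded from the pixel with the lowest
  maximum membership and logged as a warning.

# Problem sizes used in the test suite

The suite runs the full pipeline on 20-slice 128×128 phantoms, the
automaton-vs-reference equivalence on fifty 8×8 instances to
convergence, centroid recovery on ten 100×100 four-blob images, and
seeding validity on one hundred random star-shaped templates. These
sizes keep the complete suite in the low minutes on a single CPU while
leaving every scientific claim exercised end to end.

# Known limitations

* The initial rectangle and starting slice are manual by design; no
  kidney detector is included.
* The modal-cluster heuristic can lock onto the background in loose
  crops or when the crop's class mixture makes the 4-cluster split
  ambiguous (the quantile initialization then places two centroids in
  one tissue). Such slices are flagged and repaired by refinement, but
  a stack whose *seed* slice roughly segments badly will propagate a
  bad box.
* GrowCut's boundary placement degrades when the template contour is
  more than about $T_1$ px from the true boundary, so long runs of
  consecutive bad rough slices accumulate template drift.
* 2-D only: slices are processed independently along the stack; no 3-D
  regularization is applied.
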