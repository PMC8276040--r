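---
title: "Methods: segmentation, morphometry and phenotype classification of microglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, morphometry and phenotype classification of microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microgliamorph)
```

## The problem

Microglia, the resident immune cells of the central nervous system,
change shape as they change functional state: surveilling cells are
small-bodied and highly ramified; activation retracts and thickens the
processes and swells the soma; rod-like cells elongate along an axis;
fully amoeboid cells are round and process-free. In chromogen-stained
brightfield sections (dark cells on a light background, ~0.122 µm per
pixel) these four morphologies can be told apart by eye, and
quantitatively by morphometric parameters — but parameter-based
classification depends on which parameters one picks.

`microgliamorph` implements the full computational chain:

1. **segmentation** of a tissue image into uniquely labeled single
   cells, each split into soma and processes with a skeleton;
2. **morphometry** — 18 per-cell parameters (areas, perimeters, convex
   hull descriptors, solidity/convexity/circularity, skeleton
   statistics, process count, and Sholl-analysis statistics) plus
   per-image segmented-area percentage and cell density;
3. **cnn classification** of each cell into the four phenotypes with a
   VGG-style convolutional network trained on tri-level cell masks;
4. **nearest-centroid (NC) comparison** — classify the same cells by
   distance to per-class median centroids in any subset of 17
   parameters and quantify the *degree of conformity* between the two
   classifications, with an exact symmetry test on the cross-tabulation
   and exhaustive subset sweeps (131,054 subsets of sizes 2–17);
5. a **synthetic-data generator** providing ground-truthed cells and
   tissue tiles so that all of the above is testable without any image
   downloads.

## Segmentation model

The pipeline assumes dark stained cells on a light background. Stages
and their tunable constants (`segmentation_config()`):

| stage | operation | default | why |
|---|---|---|---|
| contrast | CLAHE, clip limit 2, 8×8 tiles | — | local stain/illumination variation |
| polarity | invert | — | cells become bright |
| soma channel | white top-hat, disc radius 40 px | see below | remove smooth background, keep somata |
|  | Gaussian blur σ = 5 px | — | suppress thin processes |
|  | Otsu global threshold | — | bimodal soma/background |
|  | size filter, ≥ 1,500 px | published constant | drop artifacts and process clumps |
|  | closing, radius 7.5 px | published constant | reconstruct soma outlines |
| process channel | adaptive mean threshold, radius 5 px, offset 0.15 | see below | catch all stained structure |
|  | Hessian ridge filter σ = 5, then adaptive threshold | published constant | amplify thin processes |
| repair | endpoint bridging ≤ 50 px, line width 3 px | published constant | reattach cut processes |
| cleanup | delete orphans and border-touching cells | published rule | only complete cells are measured |
| separation | parallel flood fill from soma regions | published rule | split touching cells |

Two defaults deviate from the constants a naive reading would suggest,
because implementation proved them wrong:

* **Top-hat radius 40, not ~25.** A white top-hat passes only
  structures whose minor width is smaller than the structuring
  element; with radius 25 the largest (amoeboid) somata survive the
  opening and are *subtracted away*. The radius must exceed the
  largest expected soma minor semiaxis (~38 px at the default scale).
* **Adaptive offset 0.15, not 0.** With a strictly-above-local-mean
  rule at offset 0, half of all background pixels binarize to
  foreground — above the ~0.40 site-percolation threshold of
  8-connectivity — so the background forms one giant component that
  touches the border and deletes every cell. Measured on default
  synthetic tiles, CLAHE amplifies background noise (sd 0.032 → 0.080)
  while genuine process pixels exceed their local disc mean by
  0.17–0.35; background margins stay below 0.18 at the 99th
  percentile. The default 0.15 sits in that gap. The offset is in
  post-CLAHE intensity units and is configurable.

Orphan components smaller than `bridge_min_orphan_px` (30 px) are not
bridged: they are noise speckle, not detached processes, and bridging
them would both corrupt cell outlines near somata and cost O(n) work.
Ties in the flood fill go to the lower label id; soma centroids are
rounded means of soma pixel coordinates; all connectivity is
8-connectivity.

## Morphometry

* **Perimeter.** Marching-squares boundary polygons (sub-pixel
  vertices) are smoothed with two corner-average passes before
  measuring length. Plain marching squares inflates a rasterized
  disc's perimeter by ~6% (circularity 0.89); after smoothing a
  radius-50 disc measures circularity 0.990 while a 101-px square
  measures 0.798 against the continuous-limit π/4 ≈ 0.785. The
  documented rasterization tolerance is ε = 0.05 for features ≳ 30 px.
* **Convex hull** is computed over the (smoothed) boundary vertices;
  solidity = pixel-count area / hull area is clamped at 1 because
  rasterization can push the pixel count a fraction of a pixel past
  the polygonal hull for convex shapes.
* **Skeleton.** Cell skeletons are the morphological thinning of the
  process mask (Zhang–Suen with a 2×2-block cleanup); the soma is not
  skeletonized, so an amoeboid cell has skeleton length exactly 0.
  Length sums inter-pixel steps (1 axial, √2 diagonal); endpoints have
  exactly one 8-neighbour, branch points three or more.
* **Process count** = components of the cell mask minus the
  3-px-dilated soma (published rule); stubs shorter than the collar
  vanish and do not count.
* **Sholl analysis.** Rings of 1-px width spaced `step_um` (default
  2 µm — the source does not state a step) starting one step beyond
  the soma-equivalent radius √(soma area/π). A crossing is one
  8-connected component of skeleton ∩ ring, so process thickness
  cannot inflate counts. Derived statistics: dendritic maximum (peak
  crossings), critical radius (smallest radius attaining the peak),
  branching index (sum of positive ring-to-ring increments weighted by
  ring radius, with a zero baseline before the first ring), and the
  Schoenen ramification index SRI = peak crossings / number of primary
  processes. SRI is undefined (`NA`, never 0) for cells without
  processes, which is why it is excluded from all nearest-centroid
  analyses (17 usable parameters).

## The classifier

The full-scale preset follows the VGG-16 layout: 13 convolutional 3×3
layers in blocks of 2-2-3-3-3, five 2×2 max-pooling layers, two
fully connected layers and a four-node softmax, with ReLU activations
each followed by batch normalization, trained with Adam (learning rate
0.001, batch 64) and dropout 0.5 on the fully connected layers, on
128×128 inputs. Inputs are tri-level cell masks (soma 1, processes
0.5, background 0) by default; a grayscale-crop mode exists because the
training-set representation is ambiguous in the source material.

The **reduced preset** exists so the pipeline can be trained end-to-end
on one CPU in minutes. It keeps the topology family — 3×3
convolutions, five pooling stages with doubling widths, two fully
connected layers, four-node softmax — but thins the widths by 1/8
(8-16-32-64-64) *and* shortens each block to a single convolution
(5 convolutional layers, ~460k parameters, <1% of the full preset).
A 13-layer 1/8-width network in double-precision BLAS costs
~100 s/epoch at this batch size and would not meet the package's own
15-minute benchmark budget over up to 30 epochs; the 5-layer variant
converges on the synthetic classes in 2–4 epochs at ~25–40 s each.
Training stops early once validation accuracy reaches 0.99 (the
benchmark protocol allows "at most" 30 epochs); disable by setting
`early_stop_val_acc` above 1.

Data handling follows the published protocol: stratified 70/15/15
train/validation/test split (floor per class for validation and test,
remainder to training), the eight dihedral transforms (rotations by
multiples of 90° and reflections) as augmentation of the *training*
partition only, and optional 3-fold cross-validation with folds formed
at source-cell level *before* augmentation so augmented variants of one
cell never straddle a fold boundary (a `leaky_order` flag reproduces
the literal augment-then-fold order for comparison).

## Nearest-centroid comparison

Class centroids are componentwise medians (midpoint rule for even
counts) of the selected parameters over the training cells of each
class. Cells are assigned the class of the nearest centroid in
Euclidean distance; ties go to the fixed class order (amoeboid,
activated, rod-like, ramified). Raw-unit distances are the default (the
literal reading of the source); a z-score mode is provided because raw
distances in high-dimensional subsets are dominated by large-range
parameters such as areas. The degree of conformity of CNN and NC labels
is the trace over the total of their 4×4 cross-tabulation. Matrix
asymmetry is tested with the exact symmetry test for paired contingency
tables: per off-diagonal pair, a two-sided exact binomial test of
n_ij in n_ij + n_ji trials at p = ½ (closed form 2·P(X ≤ min), capped
at 1), FDR-adjusted across the six pairs; the global p is the minimum
adjusted pairwise p. Subset sweeps enumerate all C(17, k) subsets for
k = 2…17 — 131,054 in total, which resolves the source's internal
wording conflict ("three up to 17") in favour of the printed count.

## The synthetic generator: what it emulates, what it does not

`generate_cell()` draws the soma as a filled ellipse parameterized by
equivalent radius (area = π r²) and elongation, and grows processes as
biased random walks from the soma boundary (step 1.5 px, AR(1) heading
noise, per-step branching probability, disc-brush thickness). Default
per-phenotype ranges (px at 0.122 µm/px):

| phenotype | r_eq | elongation | processes | length | thickness |
|---|---|---|---|---|---|
| amoeboid | 31–38 | 1–1.2 | 0 | — | — |
| activated | 27.5–31 | 1–1.3 | 2–4 | 15–35 | 3–5 |
| rod-like | 24.5–27.5 | 2.5–4 | 2–3 (axis-aligned) | 40–70 | 2–3 |
| ramified | 22–24.5 | 1–1.2 | 4–7 (branching) | 60–120 | 2–3 |

These ranges were chosen once: every soma exceeds the 1,500-px
detection threshold at the published pixel size, soma areas are
ordered amoeboid > activated > rod-like > ramified with rod-like
distinguished from activated mainly by elongation, and skeleton lengths
separate the classes strongly enough that a nearest-centroid classifier
on (soma area, skeleton length) exceeds 90% accuracy — the property
that makes the fixtures usable for classifier benchmarks. Tiles render
cells dark on a light background (soma darker than processes, matching
chromogen polarity), with additive Gaussian noise (default sd 0.03) and
a low-frequency background modulation (default amplitude 0.04) that
gives CLAHE something real to do. The source material never
characterizes its scanners' intensity statistics; the noise levels are
free parameters of the fixture, not claims about real data.

What the generator does **not** emulate: overlapping and out-of-focus
cells, vascular and monocyte confounders, stain gradients at tissue
boundaries, or 3D structure collapsed into extended-focus images. A
green test on synthetic tiles therefore establishes that the
implementation is faithful to the stated procedure and behaves
correctly on data matching its assumptions — not that the pipeline's
accuracy transfers to any particular real tissue set. Benchmark
accuracies on the synthetic classes (typically ~100%) compare against
the published 95.56% only as a lower bound on an easier, controlled
fixture.

## Numerical choices and degenerate inputs

* Flat (zero-range) CLAHE tiles map identically, so constant images
  pass through preprocessing as their constant complement.
* An image with no detectable somata yields an empty mask and zero
  cells — a valid result, not an error; a *label* without a soma pixel
  is a hard error (pipeline contract violation).
* Otsu thresholding uses 256 bins over the observed range; the
  adaptive and disc-morphology neighbourhoods restrict to the image
  domain at borders.
* Fractional structuring-element radii (7.5) use the exact disc
  {offsets with ‖·‖ ≤ r}.
* Flood-fill ties: lower label id; bridging ties: lowest (row, col).
* Undefined SRI propagates as `NA` and is excluded from feature
  tables; constant parameter columns yield `NA` Spearman correlations,
  reported as missing.
* All randomness flows through explicit seeds; generator and training
  runs are bit-reproducible for a given seed on a given BLAS.

## Known limitations

* Physical units assume square pixels and a single focal plane; the
  source's extended-focus acquisition is out of scope.
* The reduced network is a desk-scale surrogate: its accuracy on real
  Iba1 images is untested here because no image data are deposited.
* The flood-fill front splits touching cells at equal geodesic
  distance, which under-segments strongly interdigitated processes.
* Group statistics are descriptive only; the inferential battery of
  the original study (density-equality, Kruskal–Wallis, Mann–Whitney,
  Bonferroni) is intentionally not reimplemented.
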