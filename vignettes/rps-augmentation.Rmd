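---
title: "Random Pixel Swap: a histogram-preserving augmentation for CT images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random Pixel Swap: a histogram-preserving augmentation for CT images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpswap)
```

## The transform and its invariants

Random Pixel Swap (RPS) augments a 2D image by exchanging the contents of two
congruent, disjoint rectangular patches inside the same image. Formally the
output is a pixel permutation `X' = T(X)`, which gives RPS two exact
invariants that the comparator augmentations lack:

* **histogram preservation** — the count `n(i)` of pixels at every intensity
  level `i` is unchanged, so the relative frequencies `p(i) = n(i)/N` are
  unchanged;
* **global-intensity conservation** — `Ig = sum_i i * n(i)` is unchanged.

Cutout overwrites a square with a constant, Random Erasing with noise —
both destroy intensity counts. MixUp and CutMix import pixels (and blend
labels) from a second patient's scan. RPS keeps every original pixel and
never touches the label, which is the property that matters in diagnostic
imaging, where erased or foreign tissue can silently change the semantics of
a training sample.

For intuition: a chest CT slice still shows the same lungs, the same nodule
and the same intensity distribution after RPS; a patch of one lung region
simply trades places with the homologous patch of the complementary region.

## Swap geometry

Four configurations define the source region `A1` and target region `A2`,
always congruent, disjoint, and related by a pure translation (the half-image
extent). With `h = floor(H/2)`, `w = floor(W/2)`:

| config | `A1` | offset to `A2` |
|---|---|---|
| `h` (vertical) | top half | `(+h, 0)` |
| `w` (horizontal) | left half | `(0, +w)` |
| `u` (upper-right diagonal) | lower-left quadrant | `(-h, +w)` |
| `d` (upper-left diagonal) | lower-right quadrant | `(-h, -w)` |

For odd `H` or `W` the middle row/column belongs to neither region and is
never swapped; this keeps the regions exactly congruent. One published
description of the mapping writes the target anchors as the source anchors
"times 2", which does not in general land inside the complementary region;
the translation above is the only reading consistent with two equal,
disjoint sub-swap regions and with the diagrams of the four configurations,
and is what this package implements.

Within `A1`, two anchor pixels `Pi`, `Pj` are drawn uniformly and their
inclusive bounding box is the sub-swap rectangle `As1` (coincident anchors
give a legal 1×1 patch, so no resampling loop is needed); `As2` is its
translate. Images must be at least 4×4 so every configuration admits a
patch of at least one pixel.

## The swap-area factor

`Sf in [0.1, 1.0]` controls how much of the sampled rectangle is actually
exchanged: `area(Sa1) = area(As1) * Sf`. (The factor is occasionally also
written as the inverse ratio `As/Sa`; this package consistently uses the
shrinking convention, `Sf <= 1`.) Implementation: each side of `As1` is
scaled by `sqrt(Sf)` about the patch center, rounded to nearest with a floor
of one pixel — this achieves an area ratio within integer-rounding slack of
`Sf` (the tests bound the deviation by `2 * perimeter/area`) while
preserving the aspect ratio, and `Sf = 1` is exactly the identity. `Sa2` is
obtained by translating `Sa1`, not by re-rounding, so congruence is exact by
construction.

Two policies are provided: `svsf(value)` uses one fixed factor; `mvsf(lo,
hi)` draws a factor uniformly from `[lo, hi]` at each call, one draw per
augmentation. A continuous uniform draw is used because MVSF is specified
only as "multiple values in a range"; the continuous distribution subsumes
any finite grid of tenths. The package defaults — `Sf = 1.0`, probability
1.0, random configuration — are the settings under which the bundled
benchmark tables were produced.

## Comparator augmentations

The comparators follow their original publications where this benchmark
leaves parameters unstated: Cutout zero-fills (fill configurable), Random
Erasing uses probability 0.5, area fraction (0.02, 0.33) and aspect ratio
(0.3, 3.3), MixUp/CutMix use `Beta(alpha, alpha)` with `alpha = 0.2`. MixUp
rounds blended integer pixels half-to-even and clamps to `[0, L-1]`. CutMix
recomputes its label weight from the *clipped* pasted rectangle
(`lambda_eff = 1 - pasted_area/(H*W)`), so "proportionally blending labels"
stays literally true when the paste overlaps a border. Flips and ±90°
rotations are pixel permutations and share RPS's invariants; the test suite
uses them as positive controls and Cutout/Random Erasing as negative
controls of histogram preservation.

## Lung-ROI segmentation

The preprocessing pipeline for chest CT slices is threshold → lung mask →
dilation → hole filling → crop:

1. **Threshold.** Otsu's method on the image histogram by default (the
   procedure is specified only as "a threshold algorithm"; a fixed threshold
   mode exists for reproducibility studies). Lungs are the *dark* phase, so
   foreground = pixels below the threshold.
2. **Border cleanup.** The air surrounding the body is equally dark and
   must be discarded: connected components of the dark phase touching the
   image border are removed, as are components below `min_component_area`
   (default 64 px).
3. **Morphology.** Dilation (default 2 iterations, 3×3 square element) then
   hole filling, so vessels and nodules inside the lung fields do not
   puncture the mask. Both operations are monotone.
4. **Crop.** One bounding box around all remaining foreground (both lungs
   cropped together), expanded by `crop_margin` (default 0).

The pipeline is deterministic. Defaults are declared package choices, not
benchmark facts: the published description names the steps but none of the
parameters.

## The phantom generator

`generate_phantom()` renders a synthetic axial chest-CT-like slice: dark
background (intensity 10), bright body ellipse (200), two dark lung ellipses
(60), and for the tumor classes a brighter nodule disk (160) inside one
lung, with Gaussian noise (sd 5 of 255) clipped to the intensity range.
The three classes mirror the normal / benign / malignant structure of public
lung-CT collections; benign versus malignant is encoded as a smooth versus
sinusoidally-perturbed nodule boundary — a deliberately simple morphological
stand-in with no claim of radiological realism. The default canvas is
512×512, the native CT slice resolution; tests render 96–256 px phantoms,
which preserve all geometric relations at lower cost.

What the phantom does *not* emulate: CT physics (beam hardening,
reconstruction kernels), soft-tissue texture, mediastinal anatomy, or the
intensity distributions of real scanners. Passing tests therefore
demonstrate the correctness of the transforms and of the segmentation logic
on idealized geometry — not clinical segmentation accuracy.

Every sample is a pure function of its `phantom_spec` (including the spec's
seed); `generate_dataset()` derives per-image seeds from one master seed, so
a dataset is reproducible byte for byte.

## Ranking and statistics

Techniques are compared by the cumulative score over models,
`C = sum_models (accuracy + AUROC)`, with rank 1 for the highest `C`.
Scores are accumulated in scaled-integer arithmetic at the tables'
two-decimal precision, so near-ties (0.01 percent-point gaps occur in the
bundled tables) are ranked exactly rather than at the mercy of binary
floating point. Ties share the smaller rank, are listed lexicographically,
and raise a warning. The base (unaugmented) row is included by default —
matching the published tables' six-way ranks — and excluded with
`include_base = FALSE`, matching the published five-technique prose
rankings.

`paired_t_test()` implements the textbook paired statistic with sample
standard deviation and `df = k - 1`; p values are two-sided (sidedness is
unstated in the source of the bundled tables). Zero-variance differences
are flagged as degenerate (`p = 1` for zero mean, `p = 0` otherwise) rather
than returning `NaN`. `compare_techniques()` pairs per-model values of
accuracy, AUROC, or their sum — which scalar was paired in the original
analysis is unstated, so the choice is exposed as a flag. One of the four
bundled grids is *not* shipped for its printed ranks: the 224-px two-CNN
chest-CT table in the source prints ranks inconsistent with its own cells,
so only the four internally consistent tables are bundled.

```{r ranking}
rank_techniques(benchmark_table("chestct_512"), include_base = FALSE)
compare_techniques(benchmark_table("iqothnccd_224"),
                   "Random Pixel Swap", "Cutout", metric = "acc")
```

## Reproducibility and numerical choices

* All stochastic operations draw from R's global RNG; `set.seed()` (or the
  CLI's `--seed`) makes any run byte-reproducible. The phantom spec carries
  its own seed so samples are addressable individually.
* Coordinates are 1-based `(row, col)` from the top-left; rectangles are an
  origin plus an inclusive extent (`patch_rect(r0, c0, h, w)`).
* Intensities are integers in `[0, L-1]`; `L = 256` by default, 16-bit PNGs
  load with `L = 65536`. Histogram equality is always asserted in integer
  mode. JPEG round trips are never used where pixel equality matters.
* Test problem sizes: the permutation/involution/area suites run 1,000
  randomized cases each at image sizes 4–64 px; segmentation recovery runs
  100 phantoms at 256×256. These sizes exercise every code path, including
  odd dimensions and 1×1 patches.

## Known limitations

* 2D only; no volumetric swaps, and inter-image swapping is deliberately
  excluded — the method's premise is that swaps stay within one patient's
  scan.
* `save_image()` writes 8-bit PNG/JPEG only; 16-bit data can be read and
  processed but not written.
* The segmentation defaults are tuned to high-contrast slices (and the
  phantoms); low-dose or heavily windowed scans may need the fixed-threshold
  mode or more dilation.
* The ranking machinery consumes printed accuracy/AUROC tables; it does not
  train models or compute AUROC from raw predictions.
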