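---
title: "Methods: segmentation-based cryo-EM particle picking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-based cryo-EM particle picking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryopick)
```

## The problem

A cryo-EM micrograph is a single low-dose exposure of protein particles
embedded in vitreous ice.  Particles appear as faint dark blobs on a noisy
background, next to confounders that are not particles at all: dark ice
patches, carbon-film edges, aggregates.  Single-particle reconstruction
needs the centers (and a size) of many thousands of true particles;
picking them by hand does not scale, and picking confounders degrades the
reconstruction.  `cryopick` implements a three-stage automated picker:

1. **Denoise** the micrograph and resize it to a square model frame.
2. **Segment** it with an attention-gated U-Net into a per-pixel particle
   probability map, and convert the map into scored per-particle mask
   proposals.
3. **Postprocess** the proposals with a size-consensus filter and emit
   per-micrograph `.star` coordinate files for downstream tools.

## Denoising chain

Micrographs have extremely low SNR, so segmentation operates on a
contrast-enhanced version of the image.  The chain applies, in order:
Gaussian smoothing (`gaussian_sigma = 1` px), standard normalization
(mean/sd, clipped at ±3 sd to bound hot pixels, mapped to 0–255; a
constant image maps to mid-gray 128), fast non-local means (strength
`h = 10` on the 8-bit scale, 7-px patches, 21-px search window), an
adaptive Wiener filter (5-px window, noise power estimated as the mean
local variance), CLAHE (8×8 tiles, clip limit 2), and finally a guided
filter (radius 8, regularizer 0.01) that uses the CLAHE result as the
*guide* and the Wiener result as the *source* — edge-preserving smoothing
whose edges come from the contrast-enhanced image.  All parameters live in
`denoiseConfig()`; none of them is prescribed by theory, and the defaults
are ordinary choices for 8-bit microscopy images.  The chain is
deterministic and pure: identical input and configuration give
bit-identical 8-bit output.

The non-local means, Wiener and guided filters are implemented here
directly (vectorised integral-image forms); Gaussian smoothing and CLAHE
use EBImage.  Resizing to the model frame is bilinear and deliberately
does **not** preserve aspect ratio: the x and y axes are scaled
independently by `o_w/1024` and `o_h/1024`, which keeps the coordinate
rescaling of the postprocessing stage exact.

## Attention-gated U-Net

`buildUNet()` constructs a standard U-Net with attention-gated skip
connections: `depth` encoder blocks (two 3×3 convolutions + ReLU, 2×2 max
pooling), a bottleneck, and `depth` decoder blocks (2× nearest-neighbour
upsampling followed by a 3×3 convolution, a gated skip concatenation, two
3×3 convolutions), closed by a 1×1 convolution and a sigmoid.  Each
attention gate computes additive attention from the skip tensor and the
coarser decoder signal (two 1×1 convolutions, sum, ReLU, 1×1 convolution,
sigmoid) and multiplies the skip tensor by the resulting map in \[0, 1\] —
letting the decoder suppress regions (ice, carbon) that look locally
particle-like but are contradicted by coarser context.  The full-scale
configuration is depth 5, base 32 channels doubling per level, 1024×1024
input; depth and width are configurable, and desk-scale tests use depth
2–3 with 4–8 base channels at 64–256 px.

Design choices made where the architecture was genuinely open:

* **Upsampling** is nearest-neighbour + 3×3 convolution rather than a
  transposed convolution: the same expressive role without checkerboard
  artifacts, and it reuses the single convolution primitive.
* **No normalization layers.**  With the small batches used here,
  He-initialised conv+ReLU stacks train stably; omitting batch-norm keeps
  the hand-derived backward pass small and exactly deterministic.
* **Output bias prior.**  `buildUNet()` exposes the initial bias of the
  final 1×1 convolution (`head_bias`, default 0).  For sparse-foreground
  segmentation, initialising it to −2 starts the sigmoid near the true
  foreground prevalence instead of at 0.5 — the standard
  prior-probability initialisation for rare-foreground problems.  In the
  short desk-scale training runs used by the tests this markedly
  accelerates probability calibration (the confidence and
  threshold-stability scores downstream depend on calibrated, not just
  well-ranked, probabilities); in single-image overfitting experiments it
  is counterproductive, which is why it is an explicit opt-in rather than
  the default.

The network, its backward pass and the Adam optimiser are implemented in
plain R: convolutions are im2col gathers followed by BLAS matrix
multiplications, and every gradient was verified against central finite
differences (see `test-unet.R`).  No deep-learning framework is involved,
which keeps training exactly reproducible from a seed: seeded weight
initialisation, seeded shuffling, no hidden parallel nondeterminism.

Training minimises a unit-weighted sum of mean pixelwise binary
cross-entropy and Dice loss
\(1 - (2\sum p t + \varepsilon)/(\sum p + \sum t + \varepsilon)\),
\(\varepsilon = 10^{-6}\): BCE calibrates individual pixels while the Dice
term directly targets overlap of the sparse foreground.  The full-scale
training recipe (batch 6, learning rate 1e-4, 200 epochs) is the package
default in `trainConfig()`.

## From probability map to scored proposals

`proposeMasks()` converts a probability map into per-particle proposals:
binarize at 0.5, fill interior holes, remove components below 16 px,
label 8-connected components, and score each component with

* `pred_iou` — a threshold-stability proxy: the mean IoU between the
  component's footprint at threshold 0.5 and its footprints at 0.4 and
  0.6.  A confidently segmented particle is stable under threshold
  perturbation (score near 1); a marginal blob is not.
* `confidence` — 100 × the mean probability inside the component.

Proposals with confidence ≤ 88 are dropped, then greedy non-maximum
suppression removes overlaps above IoU 0.7 (ties broken by confidence,
then by box position, making the survivor set reproducible).  The same
data-frame contract accommodates an external promptable mask-generator
backend (grid-prompted proposals with its own predicted-IoU and stability
scores); the built-in proposer keeps the package self-contained and
deterministic, with no checkpoint downloads.  Crop-boundary discarding,
which only arises in a multi-crop proposal regime, is a no-op for the
full-frame proposer.

## Size-consensus postprocessing

Particles of one protein share a size; spurious proposals (ice, carbon,
aggregates, fragments) usually do not match it.  `postprocessMicrograph()`
exploits this:

1. keep proposals with predicted IoU **strictly** above 0.94;
2. compute the mode of the surviving box widths (`m_w`) and heights
   (`m_h`), rounding to integer pixels first, breaking ties toward the
   smaller value;
3. convert the modal box to a consensus diameter in original-micrograph
   pixels, \(d = \sqrt{(m_w\,o_w/M)^2 + (m_h\,o_h/M)^2}\) with \(M = 1024\)
   the model frame — the diagonal of the axis-rescaled modal box;
4. set the size tolerance `th` to 10% of the consensus size and keep boxes
   with \(m_w - th/3 < w < m_w + th\) (and likewise for height) — a band
   deliberately tighter below the mode, since under-segmented fragments
   are more common than oversized boxes;
5. rescale surviving box centers to the original micrograph,
   \(x' = (x + w/2)\,o_w/M\), and emit every survivor with the shared
   diameter `d`.

One unit question is genuinely open: the tolerance is defined from the
original-frame diameter but compared against model-frame box sides.  The
package default computes `th` in the model frame
(\(th = 0.1\sqrt{m_w^2+m_h^2}\), i.e. the same formula with
\(o_w = o_h = M\)), keeping every comparison in one coordinate system; the
`literal_units` flag in `postprocessParams()` restores the mixed-frame
reading for comparison.  For square micrographs the two differ only by
the constant \(o/M\) scale factor on both sides of the inequality chain,
so the default is also the dimensionally consistent reading of the same
rule.

The composition of steps 1–5 is verified, on a thousand randomized
proposal sets, against a straight-line re-implementation kept free of any
shared code (`test-acceptance.R`).

## Evaluation

`matchParticles()` matches predictions to ground truth greedily,
nearest-first and one-to-one, accepting a pair when the center distance is
at most half the ground-truth diameter (the matching criterion is a
package decision, exposed in `matchConfig()`; it is the usual convention
in picking benchmarks).  Precision, recall and F1 follow, with explicit
conventions for empty sets (all 1 when nothing was expected and nothing
predicted).  Dice similarity is computed between rendered particle masks.
The greedy matcher is verified against an exhaustive oracle on all
instances with up to 6 particles.

The package ships three published benchmark tables of automated pickers
(per-protein picking metrics; reconstruction summaries on a labelled test
corpus and on full public image sets) as plain-text fixtures, so the
aggregation and correlation utilities can be exercised offline:
unweighted column means reproduce the published averages, and the Pearson
correlation between per-protein recall and reconstructed map resolution
reproduces the published −0.78.  The analogous published correlations for
precision, F1 and Dice do **not** reproduce from the printed per-protein
values under either Pearson or Spearman recomputation; only the recall
correlation is asserted by the tests, and the others are left unasserted
as unresolved discrepancies of the source tables.

## Synthetic data: what it does and does not show

`generateMicrograph()` draws dark particles on a lighter noisy background:
diameters from Normal(30, 2) px truncated to \[6, o_w/4\] (a tight
distribution — one protein, one size mode), 70% discs, 20% mild ellipses
(aspect 1.3), 10% short rods (aspect 1.8), rejection-sampled centers with
a minimum separation of 1.2 diameters, additive Gaussian noise scaled so
the interior contrast over background noise equals `snr` (default 2), plus
confounders excluded from the ground truth: up to one large soft-edged ice
blob and a dark carbon band along one edge.  Everything is a deterministic
function of the seed.

This emulates the *statistical contract* the pipeline relies on — shared
size mode, dark-on-light polarity, confounders larger than the particle
scale — not the physics of image formation: there is no CTF, no structured
noise, no aggregation, and the default SNR of 2 is far kinder than real
micrographs.  A passing recovery experiment therefore demonstrates that
the pipeline's machinery (denoising, segmentation, proposal scoring,
size-consensus filtering, coordinate rescaling) is internally consistent
and learnable end-to-end; it does not certify performance on real data.

## Desk-scale experiment sizes and numerical choices

The shipped tests train reduced networks: the end-to-end recovery
experiment uses 50 training and 20 held-out micrographs at 256 px, a
depth-3 U-Net with 4 base channels, batch size 1, learning rate 2e-3 and
8 epochs, repeated over three seeds with a 2-of-3 pass rule (particle F1
at least 0.8, confounder-only picks at most 10% of picks).  Batch size 1
at a moderate learning rate reaches calibrated probabilities in the
fewest wall-clock minutes here because Adam takes one step per image;
the criterion thresholds themselves are fixed independently of any run.
The module tests use 64-px images throughout.

Numerical conventions worth knowing: coordinates are 0-based with
`(x, y) = (column, row)` and boxes in XYWH form anchored at the top-left;
binarization uses strict `> 0.5`; the predicted-IoU cut is strict; mode
ties round down; NMS ties are ordered by confidence then position;
degenerate inputs (constant images, empty particle sets, empty survivor
sets) all have defined, tested behaviour rather than errors, except where
the method is genuinely undefined (mode of an empty set).

One numerical caveat: very narrow nets (4 base channels) can stall on a
uniform-output plateau in single-image overfitting experiments for a
substantial fraction of init seeds, at any learning rate tried — an
optimization-basin effect, not dead units (init activations are healthy).
Eight base channels remove the stall for every seed tested; the wider
shipped defaults are not affected.

## Known limitations

* The built-in proposer scores components of a *binarized* map; unlike a
  promptable mask generator it cannot split touching particles that merge
  into one component — the NMS stage then sees a single proposal.  At the
  default minimum separation this is rare; in dense real micrographs it
  would not be.
* Pure-R training is practical at desk scale (minutes at 256 px) but not
  at the full 1024-px, depth-5, 200-epoch configuration, which is
  expressible but assumes hardware acceleration elsewhere.
* The `.star` output carries coordinates and a single shared diameter per
  micrograph; per-particle diameters, CTF metadata and multi-frame movies
  are out of scope.
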