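---
title: "Segmenting pulmonary arteries with a dense residual U-Net: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting pulmonary arteries with a dense residual U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druseg)
```

## The problem

Contrast-enhanced pulmonary arteries occupy a tiny, highly branched fraction
of a thoracic CT volume. Segmenting them automatically is hard for three
reasons: arteries and veins share attenuation and run side by side; the
vessel tree spans four orders of scale from the main trunk to sub-segmental
branches; and the foreground/background imbalance (typically well under 5%
of voxels) destabilizes training objectives that treat all voxels equally.
`druseg` implements a complete patch-based 3D pipeline around a dense
residual U-Net (DRU-Net) addressing these pressures, and ships a synthetic
vascular phantom generator so every stage can be exercised and tested
without clinical data.

## Preprocessing

CT intensities are physical (Hounsfield units), so windowing is fixed, not
data-driven:

1. **Clip** to $[-800, 500]$ HU. This brackets aerated lung at the bottom
   and contrast-enhanced blood at the top, and makes scans from different
   scanners comparable.
2. **Normalize** with the *clip bounds* as constants:
   $x \mapsto (x + 800)/1300 \in [0, 1]$. Per-volume min–max would re-scale
   every scan differently and was deliberately rejected.
3. **Patch**: each scan is cut into 9 in-plane patches of
   $256 \times 256 \times (\text{all slices})$. Origins are drawn uniformly
   at random (seeded) over the valid offsets; if the draw leaves any
   in-plane voxel uncovered, the trailing origins are replaced by a
   deterministic $3 \times 3$ anchor grid at stride $(\text{dim} - 256)/2$.
   The published protocol asks for both "9 patches" per scan and "random
   patches with varied centers"; this scheme honours the randomness while
   guaranteeing that whole-volume prediction is well defined (every voxel is
   covered by at least one patch). Whether the original patches tiled or
   overlapped is not stated; the coverage-guaranteed random scheme is this
   package's choice.

Masks are cut at the same integer origins with no interpolation, so
image/mask pairs stay voxel-aligned and masks stay strictly binary.

## The network

The DRU-Net is a four-level encoder–decoder built from **dense residual
blocks**. Each block runs four serial units of
conv($3^3$, stride 1) → group normalization → leaky ReLU, where unit $i$
consumes the channel-concatenation of the block input and all previous unit
outputs (dense connectivity *within* the block). A parallel $1^3$
convolution transforms the block input's channels, and the two paths merge
by element-wise addition (the residual connection). Downsampling is a
*learned* transition-down (stride-2 $2^3$ convolution → GN → LReLU) rather
than max-pooling; upsampling is a stride-2 $2^3$ transposed convolution.
After each transition down every spatial dimension halves and the channel
count doubles; each decoder stage concatenates the matching encoder output
before its block. A $1^3$ convolution plus sigmoid produces per-voxel
foreground probabilities at the input resolution.

Parameters the original description leaves open, with the defaults adopted
here:

| parameter | default | rationale |
|---|---|---|
| base width | 16 (8 in desk-scale runs) | unstated; configurable for desk-scale testing |
| GN groups | 8, reduced to divide the channel count | the usual GN default |
| leaky slope | 0.01 | the usual LReLU default |
| channel schedule | first block maps 1 → base width, then doubles per level | unstated; the minimal reading |
| dense scope | within a block; across blocks only via U-Net skips | the block diagram draws four serial units per block |
| skip transform | one $1^3$ conv per block | one parallel conv is drawn per block |
| weight init | fan-in-scaled Gaussian, slope-corrected | unstated; standard |
| binarization threshold | 0.5 | unstated; standard |

Input spatial dimensions must be divisible by $2^{\text{levels}} = 16$;
`predictScan()` zero-pads other sizes for the forward pass and crops back.

All tensor algebra is implemented in compiled code inside the package
(im2col/col2im unrolling with BLAS matrix products, exact analytic
backward passes, Adam). The $3^3$ convolutions run in single precision by
default — the precision a GPU framework would train in — with a
double-precision mode used by the test suite, where the forward/backward
pair of every layer is verified against finite differences.

## The DBCE objective

Two losses are combined. The Dice loss uses the squared-denominator form
exactly as published:

$$L_{\mathrm{Dice}} = 1 - \frac{2\sum_i p_i g_i}{\sum_i p_i^2 + \sum_i g_i^2 + \epsilon},$$

which for binary $p$ collapses to $1 - \mathrm{DSC}$. The binary
cross-entropy is averaged over voxels with predictions clamped to
$[10^{-7}, 1 - 10^{-7}]$. The hybrid objective is their arithmetic mean:

$$L_{\mathrm{DBCE}} = \tfrac{1}{2}(L_{\mathrm{BCE}} + L_{\mathrm{Dice}}).$$

Numerical choices: $\epsilon = 10^{-6}$ is added to the denominator only;
when prediction and truth are *both* identically empty the Dice loss is
defined as 0 (perfect agreement on emptiness) rather than letting the
smoothing term force it to 1. The published formula for the cross-entropy
swaps its symbol definitions between equation and caption; the standard
reading (log of the prediction, weighted by the label) is implemented.

## Metrics

**DSC** is $2|P \cap G| / (|P| + |G|)$, defined as 1 when both masks are
empty and 0 when exactly one is. **HD95** extracts boundary voxels (a
foreground voxel with at least one of its six face-neighbours background;
grid-edge voxels count), scales voxel centres by the spacing to physical
mm, computes both directed nearest-neighbour distance sets, takes the 95th
percentile of each (linear interpolation between order statistics), and
returns the larger — the common medical-segmentation convention. Whether
the original pooled the two directions before taking the percentile is not
stated; per-direction-then-max was chosen and the brute-force test oracle
implements the identical rule. Only spacing is used, not the full affine: a
rigid rotation cannot change internal distances, and the metric is
undefined (an error, never a silent 0) for empty masks.

## Post-processing

Predicted patches are fused by *averaging* probabilities wherever patches
overlap (max-fusion was rejected as biased toward false positives), then
thresholded at 0.5 with a strict inequality. "Area opening and closing"
become: delete foreground components smaller than `minComponentVoxels`
(default 64) at 26-connectivity, and fill background holes smaller than the
same bound at the complementary 6-connectivity. The filter is applied in
3D per volume — per-slice filtering would be the other reading of "area" —
and is idempotent and never enlarges the foreground except inside holes.

## Training protocol

Adam (betas 0.9/0.999, no weight decay, no schedule) with learning rate
$10^{-4}$, batch size 1, 200 epochs, 10-fold cross-validation, and random
in-plane rotation augmentation (the angles were unstated; ±15° by default,
bilinear for the image, nearest-neighbour for the mask so it stays binary).
Every source of randomness — initialization, shuffling, augmentation —
derives from one integer seed, so identical seeds give identical loss
curves. The published protocol mentions both a fixed 80:10:10 split and
10-fold cross-validation; here cross-validation runs over the non-test
scans of a manifest, with the test list held out by its `split` column.

## The phantom generator

The generator emulates the *structure* of the task rather than CT physics:
a recursive bifurcating tree of capsules (radius decaying by 0.72 per
generation from a 2.5-voxel trunk) rasterized as ground truth, at
contrast-vessel attenuation (300 ± 30 HU) over aerated-lung background
(−850 ± 40 HU, straddling the clip floor on purpose so clipping is
exercised) with a soft-tissue blob (40 ± 20 HU) as a mediastinum stand-in
and 15 HU acquisition noise. Default spacing 0.7 × 0.7 × 1.0 mm sits inside
the published in-plane range with 1 mm slices. The foreground fraction
stays well under 5%, reproducing the class imbalance the DBCE loss targets,
and vessel/lung contrast survives windowing by a wide margin (≥ 0.3 on the
[0, 1] scale), so the segmentation task is learnable by construction.

What phantoms deliberately do *not* model: arteries and veins of identical
attenuation in contact, airway walls, cardiac chambers, motion and
beam-hardening artifacts, or annotation noise. Passing the phantom
benchmark therefore demonstrates that the pipeline's mechanics — windowing,
patching, network, loss, reconstruction, cleanup, metrics — are correct and
that the architecture can learn a vessel-tree segmentation; it does not
certify clinical performance.

## Problem sizes for in-repo runs

The shipped tests and the acceptance script run the full protocol at sizes
chosen for a single CPU core:

- *overfit check*: one 32 × 32 × 16 phantom patch, base width 8, full
  4-level/4-unit architecture, Adam $10^{-4}$, stopping as soon as the DBCE
  falls below 0.1 (at most 300 iterations);
- *end-to-end benchmark*: 8 training and 3 held-out phantoms of
  32 × 32 × 16 voxels, 30 epochs, base width 8, with the component-size
  floor scaled to 8 voxels in proportion to the smaller scan volume
  (the 64-voxel default is calibrated to full-size scans);
- *loss ablation*: the three objectives trained for 4 epochs each on an
  identical 4-scan split.

These sizes are the package's own desk-scale choice; the architecture,
optimizer settings, loss definitions and thresholds are exactly the ones
described above, and nothing in the generator or the evaluation is tuned
per run.

## Known limitations

- The depth axis of a scan must be padded (done internally) when not
  divisible by 16; extreme anisotropy is not resampled away, matching the
  original protocol, which never resamples.
- Training is CPU-bound R/BLAS; paper-scale runs (full-resolution scans,
  base width ≥ 16, 200 epochs) are out of desk reach, which is precisely
  why the phantom benchmark exists.
- The Dice loss alone can collapse to an empty prediction on extreme
  imbalance early in training; that instability is expected (it motivates
  the hybrid loss) and shows up in the ablation harness.
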