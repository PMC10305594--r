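# druseg — dense residual U-Net segmentation of pulmonary arteries in CT

Pulmonary arteries are hard to delineate in contrast-enhanced thoracic CT:
they share attenuation with the adjacent veins and airway walls, branch
down to sub-voxel calibre, and occupy well under 5% of the volume, so naive
voxel-wise objectives collapse toward "all background". `druseg` is an R
package for researchers in medical image analysis that implements a
complete, tested, patch-based 3D segmentation pipeline around a **dense
residual U-Net (DRU-Net)** trained with a **hybrid Dice + binary
cross-entropy (DBCE) objective**, plus a synthetic vascular phantom
generator so that every stage — and the whole pipeline end to end — runs
and is testable without any clinical data.

## The method

**Network.** A four-level 3D encoder–decoder. Each stage is a *dense
residual block*: four units of conv(3×3×3) → group normalization → leaky
ReLU, where unit *i* consumes the channel-concatenation of the block input
and all previous unit outputs; a parallel 1×1×1 convolution transforms the
block input and merges by element-wise addition. Downsampling is a learned
stride-2 2×2×2 convolution (channels double, spatial dims halve),
upsampling a stride-2 transposed convolution, with encoder features
concatenated into the decoder at each level. A 1×1×1 convolution + sigmoid
yields per-voxel foreground probabilities. All forward and backward passes
(and Adam) are implemented in compiled code inside the package and
validated against finite differences.

**Objective.** With predictions \(p_i \in [0,1]\) and labels
\(g_i \in \{0,1\}\):

$$L_{\mathrm{Dice}} = 1 - \frac{2\sum_i p_i g_i}{\sum_i p_i^2 + \sum_i g_i^2 + \epsilon},
\qquad
L_{\mathrm{BCE}} = -\tfrac{1}{N}\sum_i \big[g_i \log p_i + (1-g_i)\log(1-p_i)\big],$$

$$L_{\mathrm{DBCE}} = \tfrac{1}{2}\left(L_{\mathrm{BCE}} + L_{\mathrm{Dice}}\right).$$

**Pipeline.** NIfTI in → clip to [−800, 500] HU → normalize to [0, 1] with
the clip bounds → 9 coverage-guaranteed random patches of 256 × 256 × (all
slices) → network → probability fusion back into the scan frame (overlaps
averaged) → threshold 0.5 → small-component removal and hole filling →
NIfTI mask out. Evaluation reports the Dice similarity coefficient and the
95th-percentile Hausdorff distance in millimetres; k-fold cross-validation
and a three-loss ablation harness are included.

## Worked example

Train a small DRU-Net on synthetic vascular phantoms and evaluate on
held-out ones (about five minutes on one CPU core):

```r
library(druseg)

mkScan <- function(seed) {
  ph <- generatePhantom(phantomSpec(shape = c(32L, 32L, 16L), seed = seed))
  list(id = scanId(ph$volume), volume = ph$volume, mask = ph$mask)
}
train <- lapply(100:107, mkScan)   # 8 training phantoms
test  <- lapply(200:202, mkScan)   # 3 held-out phantoms

pre  <- preprocessConfig(patchXY = 32L, patchesPerVolume = 1L, seed = 1L)
post <- postprocessConfig(minComponentVoxels = 8L)

tr  <- druseg:::collectPatches(train, pre)
fit <- trainNetwork(tr$images, tr$masks,
                    networkConfig(baseWidth = 8L),
                    trainConfig(epochs = 30L, seed = 1L))

res <- do.call(rbind, lapply(test, function(s) {
  pred <- predictScan(fit$network, s$volume, pre, post)
  evaluateSegmentation(pred, s$mask, s$id)
}))
res
```

```
       scan_id       dsc   hd95_mm
1 phantom_0200 0.9117647 0.7000000
2 phantom_0201 0.8389262 0.7289949
3 phantom_0202 0.8308703 0.9899495
```

Each row scores one held-out phantom: `dsc` is the volumetric overlap with
the ground-truth tree (1 = perfect) and `hd95_mm` the 95th-percentile
boundary distance in millimetres — here the predicted vessel surface stays
within about one voxel (0.7 × 0.7 × 1 mm spacing) of the truth. Training
and prediction are fully seeded: the same seeds reproduce these numbers
exactly.

`generateDataset()` writes phantom cohorts (NIfTI pairs plus a JSON
manifest) to disk, `runCrossValidation()` scores a manifest with k-fold
cross-validation, and `ablateLosses()` compares the `dice`, `bce` and
`dbce` objectives on one split. A thin command-line front end over these
functions lives in `inst/cli/druseg.R` (`simulate`, `preprocess`, `train`,
`predict`, `evaluate`, `crossval`).

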