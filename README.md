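# PelvicSeg3D

3D multi-organ segmentation of female-pelvis MRI for cervical-cancer
radiotherapy planning, built around two ideas:

1. **A positional Dice loss (PDL)** that penalises spatially displaced
   false positives through per-axis bounding-box mismatch, for anatomy
   known to form one continuous volume in a predictable location.
2. **Class-conditioned masked networks (M-Net, DM-Net)** that inject a
   per-case binary class-label vector — encoding gross anatomical state
   such as "inflated bladder" or "tumour larger than the uterus" — into
   the encoder of a 3D U-Net-style backbone.

The package is aimed at researchers prototyping segmentation losses and
architectures for small, highly variable clinical datasets. Because the
clinical MRI the method targets cannot be redistributed, the package
ships a synthetic pelvic phantom generator whose organ volumes span the wide
ranges seen clinically (bladder 30–722, GTV 11–712, rectum 19–213 cm³), and every component — losses, networks,
preprocessing, augmentation, cross-validation, evaluation — runs
end-to-end on phantoms on an ordinary CPU.

## The model

Segmentation uses four channels: background, bladder, CGU (the merged
cervix + GTV + uterus, the bulk of the clinical target volume) and
rectum. With one-hot ground truth `p` and softmax prediction `q`:

```
D_loss = 1 - 2 Σ p q / (Σ p² + Σ q²)

S_x(X) = Σ_{y,z} X  (then S > 0 → 1),  similarly S_y, S_z
R_x    = count(S_x(p + q) > 0)

B_loss = (|S_x(p) - S_x(q)| + |S_y(p) - S_y(q)| + |S_z(p) - S_z(q)|)
         / (R_x + R_y + R_z)

PDL    = D_loss + B_loss
```

`B_loss` is computed per foreground structure and averaged; during
training the binarised profiles are replaced by the saturated sums
`min(Σ, 1)`, which coincide on crisp masks and admit subgradients.

Three architectures are provided: a 3D U-Net variant (stride-2
downsampling, additive skips, instance normalisation, dropout 0.2),
M-Net (adds the class-label branch: one convolution + pooling per
encoder resolution, added to the encoder features), and DM-Net (M-Net
plus a bottleneck of three dilated convolutions with equal dilation and
descending filters 4F/2F/F). Training follows Adam, learning rate 0.001,
batch size 1, with optional transfer of pretrained weights across tasks
(e.g. a 5-class male-pelvis model warm-starting the 4-class female-pelvis
model, head reinitialised).

Evaluation reports DSC, full Hausdorff distance and mean surface
distance in mm (anisotropic spacing), with mean/median ± SD aggregates
and two-sided paired Wilcoxon signed-rank comparisons between
approaches.

## Worked example

```r
library(PelvicSeg3D)

# a synthetic case with an inflated bladder and a tumour 8x the uterus
cs <- generatePhantom(phantomSpec(bladderVolume = 300, gtvVolume = 400,
                                  uterusVolume = 50, seed = 21))
cs
#> CaseRecord patient=P01 series=S1
#> ImageVolume 64x64x32 @ 6.56x6.56x6 mm, intensity [30.1, 239]
#> LabelVolume 64x64x32x4 @ 6.56x6.56x6 mm
#>   voxels: background=128134, bladder=1163, CGU=1550, rectum=225
#>   class vector: [ 0, 1, 1, 0 ]
```

The class vector `[0, 1, 1, 0]` is derived from the generated anatomy:
the bladder's maximum inscribed radius exceeds 17 mm (entry 2) and the
GTV volume exceeds 4x the uterus volume (entry 3). It is broadcast to a
constant volume and fed to the masked networks.

```r
# the positional Dice loss on a nested-cube toy case: a 4x4x4 ground
# truth cube vs a 2x4x4 prediction nested at the same corner
shape <- c(8L, 8L, 8L)
mk <- function(xr) { m <- array(0, dim = c(shape, 2L))
                     m[, , , 2][xr, 1:4, 1:4] <- 1
                     m[, , , 1] <- 1 - m[, , , 2]; m }
positionalDiceLoss(mk(1:4), mk(1:2), excludeBackground = TRUE)
#> LossValue total=0.5 (dice=0.333333, bbox=0.166667)
```

The Dice term is `1 − 2·32/(64+32) = 1/3`; the bounding-box term
mismatches only along x, `2/(4+4+4) = 1/6`.

```r
net <- buildNetwork(networkSpec("dmnet", baseFilters = 8L), seed = 1)
net
#> SegNetwork 'dmnet': 4 classes, F=8, 4 levels, 620820 params

# distances honour anisotropic voxel spacing: two voxels 3 apart along x
a <- array(FALSE, c(6, 4, 4)); a[1, 1, 1] <- TRUE
b <- array(FALSE, c(6, 4, 4)); b[4, 1, 1] <- TRUE
hausdorffDistance(a, b, c(1.64, 1.64, 3.0))
#> [1] 4.92
```

A full desk-scale experiment — 40 phantoms, patient-level 2-fold
cross-validation, DM-Net+PDL vs U-Net+Dice — is one call
(`runExperiment(seed = 1)`, ~15 min on one CPU); per-structure
aggregates come from `aggregateMetrics()` and significance tests from
`compareApproaches()`. A thin command-line wrapper with `phantom`,
`preprocess`, `augment`, `split`, `train`, `evaluate` and `compare`
subcommands is provided in `exec/pelviseg`.

See the methods vignette (`vignettes/pelvic-segmentation-methods.Rmd`)
for the model details, parameter defaults and design choices.

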