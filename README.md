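# nodulemt

Joint voxel-wise **segmentation** and benign/malignant **classification** of
pulmonary nodules on chest-CT patches, implemented end to end in R with a
C++ (Rcpp/RcppArmadillo) numerical core — no external deep-learning
framework and no external imaging data required.

Radiology workflows need both the delineation of a nodule (volumetry,
follow-up) and its characterization (malignancy risk). Both tasks read the
same evidence — size, boundary spiculation, contrast — so the package
implements a single 3-D multi-task network:

- a residual encoder (18-layer style, group-normalized) producing feature
  maps at strides 4/8/16/32;
- **GSA** (global semantic attention) gates on every skip connection:
  dual sigmoid→pool channel descriptors reweight the skip features;
- a decoder with trilinear upsampling and concat fusion, each fused map
  refined by **MSConv** — four parallel grouped convolutions
  (kernels 1³/3³/5³ + residual 3³) summed element-wise,

  Y = Conv⁽ᵍ⁾₍res₎(X) + Σ_{k∈{1,3,5}} Conv⁽ᵍ⁾ₖ(X),

  with the shared group number g = max{ g ≤ min(⌊C_in/2⌋, C_out), g | C_out };
- **DSA** (dual spatial attention: channel-avg and channel-max maps,
  convolved and sigmoid-gated) in the two deepest decoder stages;
- a classification branch tapping encoder stages 3–4 plus the first fused
  decoder feature, each through squeeze-excite channel attention (**CA**),
  pooled and mapped to 2 logits;
- the compound objective L_total = (L_CE + L_Dice) + L_cls with
  ε = 1e-5 Dice smoothing and unit task weights, optimized by SGD
  (lr 0.01, momentum 0.9, weight decay 1e-4, batch 4).

Every block is an ablation switch (`active_blocks`), the preprocessing
chain (1 mm isotropic resampling, HU clip to [−1000, 400] and [0, 1]
normalization, 64³ lesion-centered patches, four augmentations) is
implemented exactly, and evaluation reports DICE, mIoU, ACC, SEN, SPE, PRE
and F1 as mean ± sd in percent. A synthetic nodule-phantom generator
(star-shaped spiculated nodules, vessel clutter, CT noise) provides
ground-truth cohorts so the whole pipeline trains and evaluates at desk
scale. See the vignette in `vignettes/` for the full model description and
design rationale.

## Worked example

Generate a 40-case phantom cohort, train the desk-scale model on the 8:1:1
training split, and evaluate on the held-out cases:

```r
library(nodulemt)

man <- generate_cohort(40, malignant_fraction = 0.5, seed = 31,
                       out_dir = "cohort40")
man <- read_manifest("cohort40/manifest.csv")
sp  <- split_cohort(man, seed = 31)          # 32 train / 4 val / 4 test

cfg <- train_config(
  batch_size = 4, epochs = 30, seed = 5,
  network = network_config(stage_channels = c(8, 16, 32, 64),
                           patch_size = 32, seed = 5))
run   <- fit_model(sp$train, cfg)
preds <- predict_cases(run$model, sp$test, out_dir = "preds")
rep   <- evaluate_predictions(preds)
rep$table
```

Output of this exact run:

```
   metric   group n  mean_pct    sd_pct     formatted
1    dice overall 4  79.80577 16.370089 79.81 ± 16.37
2    miou overall 4  68.53630 20.985959 68.54 ± 20.99
3     sen overall 4  92.43585  5.165709  92.44 ± 5.17
4     pre overall 4  74.16210 25.678673 74.16 ± 25.68
5 cls_acc overall 4 100.00000        NA        100.00
6 cls_sen overall 4 100.00000        NA        100.00
7 cls_spe overall 4 100.00000        NA        100.00
8 cls_pre overall 4 100.00000        NA        100.00
9  cls_f1 overall 4 100.00000        NA        100.00
```

Segmentation rows are per-case mean ± sd; `dice` 79.81% means the argmax
masks overlap the ground truth at Dice ≈ 0.8 on held-out phantoms, and
`miou` is the per-case foreground IoU (consistent with Dice via
IoU = D/(2−D)). The `cls_*` rows show the classification branch separating
benign from malignant phantoms perfectly on this split — the phantom class
signal (size, spiculation, contrast) is strong by construction.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/nodulemt.R make-phantoms --n 40 --seed 31 --out-dir cohort40
Rscript inst/cli/nodulemt.R train --manifest cohort40/manifest.csv \
    --out-dir run --stage-channels 8,16,32,64 --patch-size 32 --epochs 30
Rscript inst/cli/nodulemt.R predict --checkpoint run/checkpoint.rds \
    --manifest cohort40/manifest.csv --out-dir preds
Rscript inst/cli/nodulemt.R evaluate --predictions preds \
    --manifest cohort40/manifest.csv --out metrics.csv
```

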