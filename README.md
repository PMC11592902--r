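# cytoRL

Single-cell cytology image classification under severe class imbalance,
in pure R.

Automated Pap-smear screening must find the rare, diagnostically critical
cells: abnormal classes in public collections (Herlev, SipaKMeD) can be
under 8% of the data, and an ordinary cross-entropy classifier drifts
toward the majority classes. `cytoRL` implements a hybrid classifier and a
reinforcement-learning remedy:

* **Backbone** — a compact EfficientNetV2-style CNN (Fused-MBConv and
  MBConv stages, optional squeeze/recalibration paths) producing a local
  feature map F<sub>CNN</sub>.
* **ViT encoder** — the feature map is split into non-overlapping P x P
  patches, projected with position embeddings, and run through post-norm
  multi-head self-attention blocks
  (Attention(Q,K,V) = softmax(QKᵀ/√d_k)V).
* **Supporter module** — a Conv3D over feature maps stacked from
  different backbone stages, a BiLSTM over the spatial raster, and
  attention pooling (α = softmax(e), e_t = vᵀtanh(W_h h_t + b_h),
  c = Σ α_t h_t) into a context vector fused with the CNN and
  transformer features for the final softmax head.
* **RL reweighting** — after supervised training, a deep Q-network
  observes a compressed training state and adjusts per-class loss weights
  (actions raise/lower one class weight by β = 1.2, weights kept in
  [0.25, 4] with mean 1). Rewards: +1 correct minority, −1 missed
  minority, +0.1 correct majority, 0 otherwise; targets
  Y = r + γ max<sub>a'</sub> Q(s', a'; θ⁻) with replay buffer and
  delayed target network.

Everything runs on a small reverse-mode autodiff engine over base-R
matrices (im2col convolutions, fused LSTM cells, LayerNorm, masked
softmax) — no Python or deep-learning framework is required. A seeded
synthetic cytology generator (elliptical nucleus/cytoplasm cells whose
class identity is the nuclear-cytoplasmic area ratio) makes the whole
stack testable offline.

## Worked example

```r
library(cytoRL)

# 10:1 imbalanced synthetic dataset, 300 normal / 30 abnormal cells
man <- generate_dataset(two_class_specs(300, 30), seed = 1,
                        size = c(32, 32), out_dir = "cells")
man
#> Dataset manifest: 330 images, 2 classes (root: cells)
#>   normal abnormal
#>      300       30

cfg <- default_config()
cfg$training$stage1_epochs <- 4L
cfg$training$stage2_epochs <- 12L
cfg$training$lr_stage2 <- 1e-3
fit <- cytorl(man, cfg)          # stage 1 + RL stage 2
fit
#> RL-reweighted cytology classifier
#>   classes: normal, abnormal
#>   parameters: 10245 | stages trained: 1+2
#>   test accuracy 0.9592 | macro-F1 0.8886 | G-means 0.9778
#>   final class weights: 0.250, 1.750

round(predict(fit, man[1:3, ], type = "prob"), 4)
#>      normal abnormal
#> [1,] 0.8942   0.1058
#> [2,] 0.7150   0.2850
#> [3,] 0.8657   0.1343
plot(fit)                        # training curves + weight trajectory
```

The printed test accuracy is on the held-out 15% test split; `macro-F1`
averages per-class F1 with equal class weight, and `G-means` is
√(macro recall × macro specificity) — both sensitive to minority-class
failures that raw accuracy hides. The final class weights show the agent
raised the abnormal (minority) class weight to 1.75, the ceiling of the
mean-1 feasible set at two classes.

The paired experiment behind the method's core claim — that stage-2
reweighting raises minority recall over the stage-1 baseline on 10:1
data — is packaged as:

```r
imbalance_experiment(seeds = 1:5)
#>   seed recall_stage1 recall_stage2 diff minority_weight
#> 1    1             0             1    1            1.75
#> ...
```

A thin command-line interface covers the same ground
(`inst/cli/cytorl gen-data | split | train | evaluate | compare`).

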