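---
title: "Hybrid CNN-transformer cytology classification with reinforcement-learned class reweighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Automated Pap-smear screening classifies single-cell microscopy images into
normal and (pre-)malignant categories. Two features of this task shape the
design of `cytoRL`: the diagnostic signal is morphological (dysplastic cells
carry an enlarged nucleus relative to their cytoplasm, i.e. a raised
nuclear-cytoplasmic ratio), and the clinically important classes are rare —
public collections such as the 917-image seven-class Herlev set have
minority classes below 8% of the data. A classifier trained with a plain
cross-entropy loss on such data drifts toward the majority classes; the
samples that matter most are exactly the ones it learns to ignore.

`cytoRL` implements a three-part answer:

1. a **hybrid classifier**: a compact EfficientNetV2-style convolutional
   backbone for local features, a vision-transformer (ViT) patch encoder
   over the backbone's feature map for global context, and a *supporter*
   context module (3-D convolution over stacked stage outputs, a BiLSTM
   over the spatial raster, and attention pooling into a context vector);
2. a **two-stage training protocol**: supervised training of the hybrid
   classifier, then a reinforcement-learning stage in which a deep
   Q-network (DQN) dynamically adjusts per-class loss weights;
3. a **reward structure favouring the minority**: +1 for a correctly
   classified minority sample, -1 for a missed one, +0.1 for a correct
   majority sample, 0 otherwise.

# Model components

## Backbone

The default backbone has three stages: two Fused-MBConv stages (3x3
expansion convolution + ReLU + 1x1 projection, strides 2 and 2) and one
MBConv stage (1x1 expansion, depthwise 3x3, 1x1 projection, stride 1),
with residual connections where shape permits. On a 32x32 input it
produces an 8x8x16 feature map with roughly 10k parameters. An optional
squeeze/recalibration ("supporter insertion") path can be enabled per
stage: channel means are squeezed through a bottleneck MLP and a sigmoid
gate rescales the channels. No pretrained weights exist for this
architecture; everything is trained from scratch, which is why the desk
profile is deliberately small.

## ViT encoder

The feature map is cut into non-overlapping P x P patches (default P = 2,
so N = 16 tokens on the default profile), flattened and affinely projected
to d = 16 dimensions, and given learned position embeddings. Each encoder
block applies multi-head self-attention (h = 2 heads, scaled dot-product
attention with the 1/sqrt(d_k) temperature) and a ReLU feed-forward layer.
Two deliberate departures from the modern ViT idiom are kept because they
match the architecture this package implements:

* **post-norm blocks**: `z <- LN(z + MHSA(z)); z <- LN(z + FFN(z))` —
  LayerNorm sits *after* each residual sum;
* **no class token**: the classification readout concatenates all N patch
  outputs (the auxiliary head) or mean-pools them (the fused head input).

## Supporter module

The channel-mean maps of the last S = 3 backbone stages, bilinearly
resized to the final stage's spatial size, are stacked into an H x W x S
volume whose depth axis is *feature-map provenance*, not physical depth. A
single 3x3x3 convolution kernel (zero same-padding in all axes) mixes
information across stages. The convolved volume is average-pooled 2x2
(`supporter$seq_pool`) and scanned in row-major raster order by a BiLSTM
(8 hidden units per direction); attention pooling (scores
`v' tanh(W_h h_t + b_h)`, softmax weights, weighted sum) produces the
context vector. The BiLSTM output map is also projected back to S channels
by a 1x1 convolution and added to the volume (the residual path); the
global pool of this enhanced volume re-enters the classifier. The pooling
factor keeps the recurrence at 16 steps on the desk profile; it is a
tractability choice, not a modelling claim.

## Fusion head

The final classifier concatenates: global-average-pooled backbone
features (16), mean-pooled ViT tokens (16), the context vector (16), and
the pooled enhanced volume (3), followed by an affine map and softmax.

# The RL reweighting stage

The agent's *state* compresses the training condition into 3C numbers per
step: per-class mean predicted probability and per-class running recall
over a sliding window of 256 samples, plus the current weight vector.
(The raw feature maps named by the architecture's state definition are
unbounded in size; the compression to fixed-length summaries is a
deliberate design choice.) The *action space* is discrete with 2C+1
actions: raise or lower one class's weight multiplicatively
(beta = 1.2) or do nothing. After each action the weight vector is
projected onto `{w in [0.25, 4]^C : mean(w) = 1}` by alternating clipping
and renormalisation. One environment step is one training mini-batch; the
mean of the four-case reward over the batch is the step reward.

The DQN itself is a small MLP (hidden width 24) trained by plain SGD on
the squared Bellman error against a delayed target network (sync every
100 steps), with uniform replay (capacity 2048, batch 32) and a linear
epsilon schedule from 1.0 to 0.05 over the first half of the stage-2
steps. Exact value iteration on tabular problems provides the test
oracle: on three small deterministic MDPs with well-separated optimal
actions the trained agent's greedy policy must equal the value-iteration
optimum.

Two readings of the policy exist in this family of methods — a
policy-gradient softmax policy and Q-learning. The package implements the
one with a complete update rule (DQN, Eqs. of the Bellman target and
squared-error loss); a softmax over Q-values is available as a readout.

# The synthetic data generator

Real Pap-smear collections cannot ship with a package; the generator
emulates the features that drive this method's behaviour and nothing
more. Each image contains an elliptical cytoplasm with an interior
elliptical nucleus on a bright background; class identity is carried by
the nucleus/cytoplasm area fraction (as in dysplasia grading), with
Gaussian texture noise (sd 6 grey levels by default) and mild geometric
jitter. Presets reproduce the published class structures: seven Herlev
classes (146/150/197/182/98/74/70; normal group 242/917 = 26.4%) and five
SipaKMeD classes (813/787/825/813/793). The published SipaKMeD total is
4049 although those rows sum to 4031; the composition table carries the
published total, since the published group percentages (39.5% normal,
40.5% abnormal) only reproduce against it.

What the generator does **not** emulate: overlapping/clustered cells,
staining variation across labs, focus artefacts, and intra-class
morphological diversity beyond the area-fraction signal. Tests passing on
synthetic data therefore demonstrate that the pipeline's mechanics work
(shapes, gradients, determinism, the imbalance response), not that the
model reaches clinical accuracy on real slides.

# Study profile and numerical choices

* **Desk profile**: 32x32 greyscale inputs, the 3-stage backbone, L = 2
  encoder blocks, 16-dim embeddings. The published protocol's 244x244
  input size is retained as the standalone preprocessing default
  (`preproc_config()`), and the splitter reproduces the published
  70/15/15 protocol with 5-fold cross-validation on train+val.
* **Split rounding**: largest-remainder apportionment per class with ties
  broken train > val > test. The published per-class split tables follow
  no single consistent rounding rule (e.g. one 150-image row splits
  105/23/22 while a 197-image row splits 138/29/30); one rule is fixed
  here and row-exact agreement is only claimed where the arithmetic
  coincides (it does for the 813-row: 569/122/122).
* **Optimisation**: Adam (lr 1e-3 stage 1, 1e-4 stage 2 by default); the
  best checkpoint is the epoch with the highest validation macro-F1,
  chosen because macro-F1 weights minority classes equally. Softmax and
  LayerNorm use max-subtraction / variance-epsilon (1e-5) stabilisation;
  cross-entropy clamps the true-class probability at 1e-12.
* **Stage order**: the supervised stage runs to completion before the RL
  stage begins. (The pseudocode sketch of the training loop interleaves
  RL episodes before the supporter stages; the prose protocol trains the
  CNN-transformer to stability first, and that order is followed here.)
* **Reward for misclassified majority samples**: 0 — the published table
  defines only three cases; the fourth is fixed at zero so the table is
  exhaustive.
* **Minority set**: classes with training frequency below 1/C, overridable
  via `rl$minority`.

## The imbalance experiment

`imbalance_experiment()` operationalises the method's core claim at desk
scale. Conditions, fixed once: a fresh two-class dataset per seed with
10:1 imbalance (300 majority / 30 minority, `two_class_specs()`), 70/15/15
split, stage 1 trained for 4 epochs, stage 2 for 12 epochs at learning
rate 1e-3, minority recall measured on the held-out test split after each
stage. Under this budget the stage-1 classifier sits in the
majority-collapsed phase of its learning trajectory (minority recall at
or near zero): the cross-entropy gradient is dominated ten-to-one by the
majority class, and escaping the collapse takes several more epochs.
Stage 2 gives the agent room to reweight: raising the minority weight to
its ceiling (1.75 vs 0.25 under the mean-1 constraint at C = 2)
multiplies the minority gradient share by seven, which accelerates the
escape. The stage-2 learning rate stays at 1e-3 rather than the 1e-4
default because reweighting can only act through continued optimisation —
at 1e-4 the classifier is effectively frozen at this scale and no
reweighting policy, good or bad, can express itself in the loss.

The experiment reports per-seed paired recalls; the acceptance check is
the median of the stage-2 minus stage-1 differences over five seeds. Runs
where the agent happens to lower the minority weight exist (the reward
signal is flat until the classifier starts predicting the minority at
all, so early Q-values are noise-driven); the median over paired seeds is
the statistic precisely so that such runs do not mask the central effect.

# Evaluation and statistics

Metrics follow the one-vs-rest macro convention: per-class precision,
recall, F1 and specificity, macro-averaged with equal class weight;
accuracy is trace/total; G-means is sqrt(macro recall x macro
specificity). The binary definition of G-means (geometric mean of
sensitivity and specificity) is extended by macro-averaging, and
multi-class specificity is per-class one-vs-rest — both stated explicitly
because published multi-class specificity values in this literature are
often not derivable from the accompanying confusion data.

The comparison battery gates on normality at alpha = 0.05 (Shapiro-Wilk):
paired t-test versus Wilcoxon signed-rank (exact null distribution for
n <= 25 without ties) for paired samples; classical equal-variance
one-way ANOVA versus Kruskal-Wallis for groups; McNemar's test on the
discordant counts for paired classifier predictions, using the exact
two-sided binomial below 25 discordant pairs and the chi-squared form
(with optional continuity correction) above. Degenerate inputs (no
discordant pairs, all-zero or zero-variance differences) are flagged
rather than forced through a test.

# Known limitations

* The autodiff engine is plain R; it is fast enough for the desk profile
  (about 0.3 s per 16-image forward/backward pass) but not for 244x244
  full-size training.
* The RL stage's benefit is demonstrated against its own stage-1
  baseline, as the protocol defines it; stage 2 also continues ordinary
  training, and the experiment does not isolate reweighting from the
  extra optimisation steps.
* The generator's class signal is one-dimensional by design; models can
  saturate it, which is why the imbalance experiment uses a short stage-1
  budget to probe the under-trained regime rather than the saturated one.
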