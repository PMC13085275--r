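---
title: "cytodx: attention-augmented CNN feature fusion for cervical cytology"
author: "cytodx authors"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Pap-smear screening produces large volumes of stained cervical-cell images
whose manual review is slow and pathologist-dependent. `cytodx` implements a
computer-aided diagnosis (CADx) pipeline for multiclass cytology
classification built from five stages:

1. **Image preparation** — images resized to a common resolution; training
   mini-batches augmented on the fly with purely geometric transforms.
2. **Attention-augmented lightweight CNNs** — a multi-head self-attention
   module inserted between the last convolutional stage and the
   classification head of a compact CNN, trained end-to-end with categorical
   cross-entropy under SGD with momentum.
3. **Dual deep-layer feature extraction** — per image, one length-`C` vector
   from the backbone's last pooling descriptor and one from the
   self-attention layer.
4. **Wavelet fusion and cross-network ensembling** — the two vectors are
   concatenated (length `2C`) and compressed by a 1-D Haar discrete wavelet
   transform (DWT), keeping only approximation coefficients at decomposition
   level 1 or 2; fused sets from several backbones are concatenated and
   ranked by per-feature one-way ANOVA F-ratios, with a top-`k` sweep to pick
   the operating point.
5. **Classification and evaluation** — seven classical classifiers (linear /
   quadratic / cubic / Gaussian-kernel SVM, euclidean and cosine KNN with
   `k = 10`, LDA) under repeated stratified 5-fold cross-validation, with
   macro sensitivity / specificity / precision / F1 / MCC, one-vs-rest
   ROC/AUC, and a one-way ANOVA significance test across classifiers.

Grad-CAM heatmaps explain which image regions drive each decision.

## The self-attention module

Given an intermediate feature map `F` of shape `H x W x C`, the map is
flattened into a sequence `X` (`N x C`, `N = H*W`, row `r = (i-1)*W + j`).
Trainable projections give `Q = X W_Q`, `K = X W_K`, `V = X W_V` with
`W_Q, W_K, W_V` of shape `C x d`. The embedding dimension is split across
`h` heads, `d = h * d_k`, in contiguous column blocks, and each head computes
scaled dot-product attention

    Attention_i = softmax(Q_i K_i' / sqrt(d_k)) V_i,

row-wise softmax, so attention weights per query position sum to one. Heads
are concatenated and projected back by `W_O` (`d x C`):

    SA(X) = Concat(Attention_1, ..., Attention_h) W_O.

Design choices (made once, where the formulation leaves freedom):

* **`d = C`.** The attention output must have length `C` per position for the
  layer-width contracts of the extraction stage (512 for ResNet-18-class
  backbones, 1280 for the MobileNet/EfficientNetB0 class, both with `h = 8`,
  so `d_k` is 64 or 160; the toy backbone uses `C = 16`, `d_k = 2`).
* **Head slicing** is by contiguous blocks of the joint projection — the
  standard convention.
* **No positional encoding** is used, making the operator permutation-
  equivariant over positions; tests assert this property.
* **Extraction taps the post-`W_O` output** `SA(X)`, the attention-enhanced
  representation, not the pre-projection concatenation.

### Where the module sits, and which layers feed the feature sets

The module is inserted *between the last convolutional layer and the final
pooling*: `conv stack -> flatten -> attention -> position-mean pool -> FC ->
softmax`. Five named endpoints are tappable: `last_conv`, `global_pool`,
`attention_seq`, `attention_pooled`, `logits`.

One wiring question was genuinely open: if "the last pooling layer" pooled
the attention output, its features would be numerically identical to the
mean-pooled attention sequence and the dual-layer concatenation would
duplicate itself. Because the two layers are meant to carry complementary
information (pooling = compact global morphology; attention = contextual,
relation-weighted evidence), `cytodx` defines:

* `extract_pooling_features()` = global average pool of the **last conv
  map** (`global_pool`), the backbone's own pooled descriptor;
* `extract_attention_features()` = mean over positions of **`SA(X)`**
  (`attention_pooled`), which is also what the classification head consumes.

Both are length `C`, preserving every width contract, and the fused
representation is non-degenerate.

## Training

Defaults follow the study recipe: SGD with momentum 0.9, weight decay 1e-4,
fixed learning rate 0.001 (no schedule), mini-batch 5, 50 epochs; categorical
cross-entropy `-(sum y_c log yhat_c)` with probabilities clamped at 1e-12.
All layers (im2col convolution, max pooling, attention, FC) carry
hand-derived backward passes; the test-suite checks every gradient against
central finite differences.

Inputs are zero-centred (`x - 0.5` on `[0, 1]` intensities) before the first
convolution — the standard input normalisation for image networks; without
it, activations ride on a large constant background component and small
networks converge to uniform predictions.

Augmentation is geometric only — scaling 0.6–2.6, shearing ±59°, x/y
translation ±46 px, rotation ±90°, random axis reflections — applied on the
fly to training mini-batches only, never to validation or test images.
Out-of-frame pixels are reflect-padded, which avoids black-corner artefacts
that would contaminate Grad-CAM maps. The ±46 px translation presumes
224 × 224 inputs: on the small desk-scale fixtures used in the examples
below it would translate the whole cell out of frame, so the desk runs
disable augmentation (the policy itself is unit-tested separately).

The three named lightweight backbones are **reduced, randomly initialised
conv stacks** with the canonical last-stage channel counts (1280 / 1280 /
512). No pretrained ImageNet weights are bundled or downloaded; the named
stacks exist so that every shape contract of the extraction and fusion
stages is computed, not assumed. All learning experiments run on `toy_cnn`
(three conv blocks, `C = 16`).

## Haar-DWT fusion

The concatenated dual-layer vector (length `2C`) is processed row-wise by
the orthonormal Haar analysis step

    CA_i = (v_{2i-1} + v_{2i}) / sqrt(2),   CD_i = (v_{2i-1} - v_{2i}) / sqrt(2),

recursively on the running CA for level 2; only the final approximation
coefficients are kept. With the `1/sqrt(2)` convention the step is
orthonormal, so `||CA||^2 + ||CD||^2 = ||v||^2` — the detail coefficients
are computed and *then* discarded, which keeps that Parseval identity
testable. Resulting lengths: 512/256 for a 512-channel backbone and
1280/640 for a 1280-channel backbone. All in-scope lengths are divisible by
four; odd inputs are nevertheless handled by one trailing reflected sample
so the transform is total. The transform is applied per sample to row
vectors (the only reading consistent with the published lengths), standard
DWT rather than dual-tree.

## ANOVA feature selection

For each column, `F = MSB / MSW` with degrees of freedom `(K-1, n-K)`.
Degenerate cases follow a fixed policy: zero within-class variance with
unequal class means gives `F = +Inf` (ranked first); a globally constant
column gives `F = 0` with undefined p (ranked last); ties break on the lower
column index so selection is deterministic. p-values are reported for
inspection only — selection is rank-based top-`k`, with no multiple-testing
correction. The default sweep grid is 100..1500 by 100, covering the
1536-column three-network level-2 pool.

## Classifiers

SVMs use one-vs-one voting with box constraint 1 and kernel scale
`sqrt(p)` (equivalently `gamma = 1/p`), quadratic/cubic via polynomial
kernels with offset 1 — an approximation of a proprietary "automatic" kernel
scaling, documented as such. Per-class ROC scores are aggregated pairwise
decision margins. Both KNNs use `k = 10` (euclidean on standardised
features; cosine on raw features, since the cosine metric is scale-free per
row) with neighbour-vote fractions as scores; distance ties resolve by
sample index and vote ties by the lower class index. LDA falls back to a
ridge-regularised pooled-covariance discriminant when the within-class
covariance is singular. Standardisation statistics are always fit on the
training fold only — a canary test with extreme test-fold values verifies
that no test statistics leak.

Metrics binarise the confusion matrix one-vs-rest per class:
`Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)`, `Prec = TP/(TP+FP)`,
`F1 = 2TP/(2TP+FP+FN)`,
`MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Macro values
are unweighted means over classes (the multiclass MCC is the mean of
per-class binary MCCs — the binary formula is what is defined; the
multiclass generalisation was an open choice). Overall accuracy is
trace/total. Zero denominators define the metric as 0 and set a flag.

Cross-validation is stratified 5-fold with 5 repeats (the repeat count was
an open choice; 5 balances variance estimation against runtime). Metric
means and variances are taken over repeats, each repeat scored from its
pooled test-fold confusion matrix. The across-classifier one-way ANOVA uses
the per-fold accuracies of the first repeat — 7 classifiers × 5 folds gives
the canonical `df = (6, 28)` with total 34.

## Grad-CAM

The gradient of the target class logit is taken with respect to the last
convolutional activation map (default; full spatial resolution before the
attention module — the attention sequence endpoint is also supported).
Channel weights are spatial means of the gradient; the raw map is
`ReLU(sum_k w_k A_k)`, bilinearly upsampled to image size and divided by its
maximum, so an identically zero map stays zero and is flagged rather than
amplified. Overlays blend a piecewise-linear jet colormap
(`clamp(1.5 - |4v - c0|, 0, 1)` with channel centres 3.5 / 2 / 0.5, mapping
0 to blue, 0.5 to green and 1 to red) over the image with weight `alpha`, so
overlays are bit-reproducible across platforms.

One subtlety the test design reflects: in a two-class problem where classes
differ *only* in nucleus size, the smaller-nucleus class is evidenced by the
*absence* of nuclear activation, and its CAM provably anti-localises (with a
linear head the two class scores are anti-correlated). The nucleus-focus
sanity check therefore uses a fixture whose classes differ only in the
nucleus *stain*, with identical cytoplasm — there, every class's evidence
lives at nucleus pixels, and the trained toy model's heatmaps score the
nucleus above the cytoplasm for essentially all correctly classified images.
A radius-contrast check is retained for the large-nucleus class, where
positive localisation is expected.

## The synthetic fixture generator

`fixture_spec()` renders each cell as two concentric filled ellipses — a
chromatin-dense nucleus inside a paler cytoplasm on a bright slide
background — plus Gaussian texture noise and a per-class stain hue, with an
optional nucleus-only hue. The nucleus radius is drawn per image
(`N(mean, sd)`), with a mild random axis ratio that preserves area
`pi * r^2`; position and orientation jitter randomly. Per-image substreams
are derived from one top-level seed, so datasets are reproducible under
partial regeneration, and emitted label histograms equal the requested
class counts exactly.

What it emulates: class-specific nuclear morphology, nucleus-to-cytoplasm
ratio, stain variation, class imbalance (e.g. the 613/113/163/74
composition of a public LBC dataset, 963 images). What it does not:
photo-realistic chromatin texture, overlapping cells, debris, slide-level
batch effects, or stain normalisation issues. Passing tests therefore
demonstrate the *mechanics* of the pipeline — shapes, invariants, learning
and localisation on controlled signal — not clinical performance.

`synthetic_feature_spec()` plants `k` informative columns whose class means
are equally spaced `effect_size * noise_sd` apart (class-to-level assignment
randomised per column) among exchangeable Gaussian noise columns, and
returns the ground-truth index set, enabling exact recovery-rate
measurement.

## Problem sizes and numerical choices

Experiments in the tests and the acceptance script are desk-scale by
design: 5 classes × 50 images at 48 × 48 px, toy backbone, 5 epochs at
learning rate 0.02 for the pipeline study; 2 × 30 images at 64 × 64 px and
8 epochs for the explainability study; 500 × 1536 with 50 planted columns
for the selection study. Table-scale defaults (224 × 224, lr 0.001, 50
epochs, full augmentation) remain the package defaults for real data. The
softmax epsilon is 1e-12; SVM cost is 1; LDA ridge is `1e-6 * mean(diag(S))`.
On the synthetic study the qualitative ordering of the four settings
reproduces the design's motivation: end-to-end softmax classification of a
small CNN is the weakest route, and classical classifiers on selected,
fused dual-layer features are the strongest.

## Known limitations

* The named lightweight backbones are reduced random-weight stacks: useful
  for contracts and wiring, not for transfer learning until weights are
  supplied.
* Pure-R convolution backprop is appropriate for the toy scale; training
  224 px backbones end-to-end would need compiled kernels or an external
  framework.
* The SVM kernel-scale rule approximates a toolbox's proprietary automatic
  scaling.
* Grad-CAM explanations are qualitative; no expert-annotated masks exist
  for quantitative localisation scoring.
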