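---
title: "Block-based compressive sensing with a CNN classifier: methods and design"
author: "BlockCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-based compressive sensing with a CNN classifier: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

BlockCS studies a practical question in image-based phenotyping: how far can
labelled RGB images be compressed by compressive sensing (CS) before a
convolutional classifier trained on the reconstructions stops working? The
package implements the whole loop — codec, classifier, metrics, synthetic
data, command line — so the accuracy-versus-compression trade-off can be
measured end to end on a single desk machine.

## The codec model

An N×N image plane (default N = 256) is tiled into B×B blocks (B = 8), each
block is centred by subtracting 128 (the JPEG convention), transformed by
the orthonormal type-II 2-D DCT, and vectorized to v ∈ R^L with L = B² = 64.
Acquisition is linear: Y = A v, with a single M×L matrix A of i.i.d.
N(0, 1/M) entries shared by every block and every colour channel.
Compression ratio is CR = L/M, so M ∈ {32, 16, 8, 4, 2} gives the sweep
CR ∈ {2, 4, 8, 16, 32}.

Reconstruction is orthogonal matching pursuit (OMP): per iteration, select
the column of A most correlated with the residual (columns L2-normalized
for this comparison only), refit Y by least squares on the accumulated
support, update the residual. Natural-image DCT blocks are only
approximately sparse, so OMP here acts as a greedy M-term approximation
rather than an exact-sparse solver; at M = L it reduces to an invertible
linear solve and the codec becomes lossless up to 8-bit rounding.

Key numerical choices, all open in the underlying description of the
method and fixed here as package conventions:

* **DCT normalization** — orthonormal, so Parseval holds exactly and block
  energy is preserved; a constant block c maps to a single DC coefficient
  B·c.
* **Vectorization order** — column-major, (r, c) → (c−1)·B + r, R's native
  `as.vector`. Any fixed bijection is equivalent for Gaussian acquisition;
  zig-zag ordering would buy nothing because A has no structure to exploit.
* **Gaussian scale** — Var = 1/M keeps ‖Av‖ ≈ ‖v‖ in expectation.
  Normalizing columns inside the selection step (only) makes atom choice
  scale-invariant without changing the least-squares fit.
* **Stopping rule** — dual criterion: residual ≤ 1e-6·‖Y‖, or M atoms
  selected, whichever first. With non-sparse blocks the atom budget is the
  binding constraint; the tolerance matters in the M = L limit and for
  genuinely sparse inputs.
* **Degenerate atoms** — all-zero or numerically dependent columns
  (Cholesky pivot ≤ 1e-12 of the diagonal scale) are skipped and never
  re-examined, so the Gram factorization stays well conditioned.
* **One shared A** — generated once from a stored seed and recorded in the
  compressed header, so encoder and decoder agree by exchanging 24 bytes of
  header rather than an M×L matrix.
* **Clipping and rounding** — intermediate math is floating point
  throughout; values are clipped to [0, 255] and rounded to 8 bits only at
  final decode.

The `.bcs` container stores the header (magic, version, N, B, M, seed,
channels) followed by raw little-endian doubles; payload size is exactly
channels · (N/B)² · M values, i.e. 1/CR of the uncompressed element count.

## The classifier

The classifier is a softmax CNN trained by minibatch SGD with momentum on
categorical cross-entropy. Two presets share one engine:

* `"alexnet"` — the classic five-stage stack (96/256/384/384/256 filters,
  11/5/3/3/3 kernels, overlapping 3×2 max-pooling, two 4096-unit hidden
  dense layers with dropout), native input 227×227. It exists so the
  full-scale architecture is runnable; training it to its published
  accuracies requires the external photographic corpus and is out of scope
  for the test suite.
* `"small"` — three conv stages (8/16/32 filters, 3×3 kernels, 2×2
  pooling), one 64-unit hidden dense layer with dropout, native input
  64×64. This is the preset the desk-scale experiments use.

Training defaults mirror the study's predetermined parameters: SGD,
learning rate 0.001, batch size 64, dropout 0.4, 100 epochs (the scaled
experiments below use 30). Momentum 0.9 and cross-entropy loss are package
choices — the method description fixes the optimizer family and rate but
neither a momentum nor a loss; cross-entropy with a softmax head is the
standard pairing, and 0.9 is the conventional momentum for image CNNs.
Dropout sits on the hidden dense layers only, and there is no data
augmentation and no early stopping (both deliberately out of scope).
Images are resized to the network's native input at the classifier
boundary, scaled to [−0.5, 0.5]; weights use He initialization. Every
stochastic ingredient — initialization, shuffling, dropout — derives from
one seed, so runs are bit-reproducible.

The convolution engine (im2col + BLAS GEMM, C++ via RcppArmadillo) is part
of the package; its backpropagation is validated against finite-difference
gradients in the test suite, and an overfit check confirms the small preset
can memorize a small set.

## Evaluation metrics

Evaluation is one-vs-rest on a C×C confusion matrix (rows = true class):
precision TP/(TP+FP), recall TP/(TP+FN), F1 their harmonic mean; overall
accuracy is the multiclass reduction of (TP+TN)/total, i.e. trace/total.
Macro averages are unweighted means across classes. Two policies worth
stating: a zero denominator yields 0 with a warning rather than an error,
so sweeps over degenerate small fixtures complete; and report tables round
half away from zero at two decimals, matching how such tables are usually
printed. Reported loss columns are mean cross-entropy × 100 so they share
the percent scale of the other columns.

## Synthetic data: what it emulates and what it does not

The fixture generator replaces a photographic vegetable corpus with four
parametric classes, one row per class in `fixtureStyles()`: a base colour,
a shape-mask family (cluster of discs / elongated taper / wobbled ellipse /
capsule), and a texture frequency and amplitude. Pose is randomized
(rotation, translation, scale), a sinusoidal texture modulates the object,
and i.i.d. Gaussian pixel noise (sd 8 gray levels) is added everywhere.
The noise default is a compromise fixed in advance: large enough that CS
reconstruction error interacts with a noise floor, small enough that
classes stay separable. The minimum pairwise base-colour distance is
roughly 93 gray levels, so foreground mean colours separate any two classes
by well over 40 gray levels — the margin the fixture contract asserts.

What this emulates: class-consistent colour/shape/texture statistics,
pose variation, sensor noise, and an 8-bit RGB pipeline. What it does not:
natural image backgrounds, lighting variation, intra-class diversity of
real specimens, or the heavy-tailed spectra of photographs. Passing the
end-to-end tests therefore shows that the pipeline is correct and that the
qualitative accuracy-versus-CR trend holds under controlled conditions; it
does not certify accuracy numbers on photographic data.

## Problem sizes for the desk-scale experiments

The scaled experiments fix, as package choices: 10 fixture images at
128×128 for the PSNR sweep; 400 images (100 per class) at 64×64, split
70/10/20 with per-class stratification, trained 30 epochs on the small
preset for the end-to-end runs; 200 seeded trials for the 4-sparse OMP
oracle comparison and 100 for the 1-sparse exhaustive search. The
compression trend is asserted as a 5-seed majority of
accuracy(CR = 2) ≥ accuracy(CR = 32) on one fixed split.

## Known limitations

* OMP cost grows with M (least-squares refits up to M atoms per block);
  the implementation uses an incremental Cholesky factorization, but very
  large N at M = 64 is still the slowest corner of the codec.
* The measurement payload is stored as raw doubles; quantizing or entropy
  coding Y (out of scope) would change the practical compression rate.
* The CNN engine is single-threaded and CPU-only by design; it targets
  desk-scale reproducibility, not large-scale training.
* Accuracy at high CR on the synthetic classes is dominated by mean-colour
  survival; photographic data would likely degrade faster with CR.

## A worked example

```{r example}
library(BlockCS)

img <- generateClassImage("carrot", size = 64, seed = 1)
cfg <- CodecConfig(resizeTo = 64L, measurements = 32L, seed = 1L)  # CR = 2
rec <- decodeImage(encodeImage(img, cfg))
psnr(img, rec)

ds <- generateDataset(FixtureSpec(imagesPerClass = 100L, imageSize = 64L))
sp <- splitDataset(ds, c(0.7, 0.1, 0.2), seed = 1)
model <- trainModel(buildModel(4, preset = "small"),
                    transcodeDataset(sp$train, cfg),
                    transcodeDataset(sp$validation, cfg),
                    TrainConfig(epochs = 30L))
evaluateModel(model, transcodeDataset(sp$test, cfg))$accuracy
```
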