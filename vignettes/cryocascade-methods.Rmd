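---
title: "Progressive denoising of cryo-EM particle images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive denoising of cryo-EM particle images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-particle cryo-electron microscopy produces large stacks of 2D
projection images of a biomolecule at unknown orientations.  Because the
electron dose must stay low, the images are dominated by noise: the
signal-to-noise ratio (SNR), understood throughout this package as the
ratio of signal pixel variance to noise pixel variance, commonly sits
near 0.1.  The downstream step that suffers most is 2D clustering by
projection orientation, whose class averages feed 3D reconstruction:
at SNR 0.1 generic clustering algorithms confuse orientations badly.

`cryocascade` implements a cascade of three convolutional denoising
autoencoders that removes this noise *progressively*, together with the
simulation, enhancement, evaluation and clustering machinery needed to
exercise it end to end on synthetic data.

## The model

Each block is an encoder--decoder network.  With `EC` the encoder, `DC`
the decoder, and `x` an input image, a block computes

    z = EC(x),    y = DC(z),    y = f(x) = DC(EC(x)),

and the cascade composes three blocks, `f3(f2(f1(x)))`, optionally
followed by per-image histogram equalization.

**Why a cascade.**  A single denoiser trained to jump straight from
SNR 0.1 to clean data faces an input/target gap so large that training is
unstable; trained on mildly corrupted data it does not match the real
noise level.  The cascade splits the journey into three short hops:
block 1 maps SNR-low images to the same images at SNR-mid, block 2
mid to high, block 3 high to clean.  Each hop is an easy regression, and
composing the hops denoises fully.

**Architecture of one block.**  The encoder has 3 modules, each of two
3x3 stride-1 convolutions (32 feature channels, ReLU, same-padding)
followed by 2x2 max pooling and dropout; after three poolings a
`H x W` image has a `H/8 x W/8` spatial latent grid.  The decoder
mirrors it with three upsampling-deconvolutions -- 2x nearest-neighbour
upsampling followed by a 3x3 convolution and dropout -- and a final 3x3
convolution that collapses the 32 channels into the single output
channel (linear output).  Same-padding everywhere makes the block
shape-preserving end to end for sides divisible by 8.  The default
block has 74,593 parameters (`nParams(blockSpec())`).

Design choices behind this (details the architecture sketch above does
not pin down):

* *Upsampling-deconvolution rather than stride-2 transposed
  convolution.*  The two are equally expressive at equal parameter
  count; the upsample-then-convolve form cannot produce checkerboard
  artifacts, which matters when the output feeds a pixel-space distance
  computation (the neighbourhood graphs below).
* *Dropout rate 0.5*, placed after each pooling layer and after each
  decoder convolution, active only during training.  With only a few
  thousand training images per block, this much regularization is what
  keeps the block from memorizing the replicated projections.
* *Weight initialization*: seeded LeCun-uniform (uniform on
  `+-sqrt(3 / fan_in)`), biases zero.  All randomness -- initialization,
  minibatch shuffling, dropout masks -- derives from explicit integer
  seeds, so training is bit-reproducible.
* *Optimization*: RMSprop (decay 0.9, epsilon 1e-7), learning rate 3e-3,
  minibatch 8, mean-square-error loss, 20 epochs by default.  The batch
  size and learning rate were chosen by a small sweep scoring training
  health on the block-1 task: on a few-hundred-image stack, 20 epochs at
  batch 32 perform so few RMSprop updates that the network settles into
  the degenerate "predict the mean target image" optimum (every output
  identical); batch 8 at learning rate 3e-3 escapes it and yields
  class-distinct, input-dependent outputs.  The training loop and
  backward pass are implemented in C++ (RcppArmadillo) in single
  precision with im2col/GEMM convolutions; a finite-difference test in
  the suite verifies the analytic gradients.

## Two-phase training

**Phase 1: pre-training on simulated tiers.**  `buildDatasets()`
produces four index-aligned training stacks: the same clean projections
corrupted at SNR 0.1, 0.4 and 0.6, plus the clean tier.  Block j is
trained on (tier j, tier j+1) pairs by index; the three blocks are
independent and could be trained in parallel.

**Phase 2: pseudo-supervised fine-tuning on the target stack.**  Real
target stacks have no clean references, so fine-tuning substitutes a
*neighbourhood-mean* target: for each image, the pixelwise average of
its k = 30 most similar images (Euclidean distance on raw pixels, self
included).  Images of similar orientation share signal while their noise
is independent, so the mean attenuates noise variance by roughly 1/k and
approximates the missing clean target.  Fine-tuning proceeds
sequentially: block 1 is tuned with the raw target stack as input and
the neighbourhood means of its own pre-trained outputs as targets; its
output becomes block 2's input, and so on.  Each fine-tuned block starts
from its pre-trained weights.

Two target conventions are implemented.  The default (`block1_fixed`)
computes the neighbourhood-mean targets once, from block 1's pre-trained
outputs, and reuses that target stack for blocks 2 and 3, so every block
is tuned toward the same clean-approximating images.  The alternative
(`per_block`) recomputes the targets from each block's own pre-trained
outputs on its own inputs.  We measured both on the packaged experiment:
in `per_block` mode, blocks 2 and 3 receive inputs far cleaner than the
tiers they were pre-trained on and are then tuned toward neighbourhood
means of their *own* distorted outputs, and the per-stage PSNR can
decrease; `block1_fixed` anchors all blocks to one good target stack and
preserved the monotone stage-by-stage improvement, so it is the
default.  Whether neighbourhoods should be computed on raw images or on
block outputs is similarly open; the implementation uses block outputs,
where the noise is already partly removed and similarity is more
reliable (a switch selects the raw-input variant).

**Enhancement.**  The cascade output concentrates gray values in a
narrow range, so the final step remaps each image through its empirical
CDF (histogram equalization, 256 bins over the image's own range).  The
remap is monotone and rank-preserving; a constant image passes through
unchanged.  Equalization is a *contrast* aid for viewing: it
deliberately reshapes the intensity histogram toward uniform, which
moves pixel values away from the clean reference and, on smooth blob
phantoms, stretches the flat background across the full dynamic range.
Fidelity metrics (PSNR) and the clustering evaluation therefore use the
un-enhanced cascade output; the enhanced output's PSNR and macro-F1 are
also computed by the acceptance script for transparency.

## The synthetic-data generator

The simulator emulates the canonical study conditions: projections of a
3D density at 4 fixed orientations, replicated 1,000 times per
orientation and tier, corrupted at SNR 0.1 / 0.4 / 0.6 plus a clean
tier (16,000 training images), with a 4,000-image test stack at SNR 0.1
projected from a *different* phantom -- mirroring a train-on-one-protein,
test-on-others split.

* *Phantoms* are sums of random anisotropic Gaussian blobs and solid
  ellipsoids (default 6 components, giving projections a lumpy,
  protein-like level of structural detail) placed near the volume
  centre, normalized to peak density 1.  Train and test phantoms use
  distinct derived seeds.
* *Projection* rotates the volume about its centre (ZYZ Euler angles,
  trilinear interpolation, zero outside the grid) and sums along the
  z-axis.  With trilinear interpolation, projections of a spherically
  symmetric blob agree across orientations to about 0.3--1% of the peak
  on a 64^3 grid (curvature error for narrow blobs, grid-truncation
  asymmetry for wide ones); 90-degree in-plane rotations are exact.
* *Noise* is additive i.i.d. Gaussian, calibrated as
  `sigma = sqrt(pooledVar(clean) / SNR)` with the signal variance pooled
  over the clean stack.  This variance-ratio definition of SNR matches
  common cryo-EM simulation practice and makes the calibration testable (the empirical
  variance ratio of every generated tier lands within a few percent of
  its target).
* *Normalization*: each dataset is min-max normalized to [0, 1] using
  the clean tier's range; noisy values may exceed [0, 1] and are stored
  unclipped.  Clipping happens only on export to 8-bit PNG.  PSNR uses
  peak 1 under this convention.
* *Image side* defaults to 64 (the side must be divisible by 8 for the
  three poolings).
* *Orientations*: a tilt series 16 degrees apart
  (`defaultOrientations()`), shared by the training and test stacks.
  This choice, together with the 6-component phantoms, was calibrated
  once: with widely separated views, raw-image k-means at SNR 0.1 is
  already perfect (macro-F1 1.0) and denoising has nothing left to
  improve, whereas on hard, realistic stacks the raw baseline sits in
  the mid-range and the clustering lift appears exactly where it
  degrades.  At 16-degree separation the raw baseline lands around 0.5
  while clean projections still cluster perfectly, so the phenomenon
  the cascade exists for is actually observable.

What the generator does *not* emulate: the contrast transfer function,
structured/correlated noise, ice gradients, particle-picking errors, or
orientation jitter within a class.  Passing tests on this generator
therefore demonstrate the machinery end to end -- calibration, training
dynamics, progressive improvement, clustering lift -- but not performance
on real micrographs, whose noise is a complicated instrument-and-sample
mixture.

## Evaluation

* **PSNR**: per image, `10 * log10(maxVal^2 / MSE)`; peak 1 for [0, 1]
  stacks; infinite values (identical images) are capped at 100 dB before
  averaging.
* **Empirical SNR**: pooled variance of the clean stack over pooled
  variance of the residual; used to validate the simulator.
* **Clustering**: k-means (seeded, 10 restarts, 100-iteration cap) or
  Ward hierarchical clustering on flattened pixels, cut at K = 4.
  Unsupervised cluster indices are matched to true classes by the
  optimal one-to-one assignment on the contingency table (Hungarian
  algorithm; the table is zero-padded when K differs from the class
  count).  Per matched class, precision = TP/(TP+FP) and
  recall = TP/(TP+FN) over image memberships; F1 is their harmonic
  mean; macro averages are unweighted class means (classes are balanced
  by construction, so macro and micro nearly coincide).  The optimal
  matching rule and the macro averaging convention are this package's
  choices; precision/recall for unsupervised clusters is undefined
  without them.

## Problem sizes used by the test and acceptance suites

The packaged experiments run at a reduced but faithful scale chosen so a
complete run is comfortable on a laptop core: two phantoms, 4
orientations, 64 x 64 images, 200 training images per tier (50 per
class), 200 test images, 20 epochs per block for both phases, k = 30
neighbourhoods, and the default 32-channel block.  Unit tests use
smaller stacks (8--32 pixel sides, 2--8 channels) to keep each property
check fast.  The single-DAE baseline in the comparison is exactly one
cascade block trained low-to-clean and fine-tuned with the same
per-block protocol (20 + 20 epochs), matching how each cascade block is
treated individually.

## Numerical notes and degenerate inputs

* Training arithmetic is single precision; parameters cross the R/C++
  boundary as doubles, so serialized blocks restore bit-identical
  inference.
* Convolutions use zero same-padding, so outputs carry a thin border
  halo (the outermost pixels see truncated neighbourhoods); interior
  pixels converge noticeably faster during training.
* Ties in neighbour selection break toward the lower image index;
  distances within a neighbourhood are non-decreasing by construction.
* A constant image: rejected by noise calibration (zero signal
  variance), rejected by the correlation metric (undefined), passed
  through unchanged by equalization.
* `epochs = 0` is a supported no-op everywhere, which makes the
  "fine-tuning disabled" cascade exactly the pre-trained one.
* Noisy stacks may contain values outside [0, 1]; all metrics operate
  on the unclipped values.

## Known limitations

* The noise model is additive white Gaussian only; no CTF, no noise
  correlation.  Gains measured here are an upper bound on what the same
  architecture achieves on real data.
* Neighbourhood quality degrades at very low SNR; if the k nearest
  neighbours mix orientations, the mean target blurs across classes and
  fine-tuning can soften genuine features.  At the packaged scale this
  is structural: the canonical k = 30 against only 50 test images per
  class means even a perfect similarity metric draws most of a
  neighbourhood from fewer than 2k same-class candidates, and measured
  neighbourhood purity is well below 1.  Larger target stacks (the
  canonical 1,000 per class) relax this.
* The clustering lift over the raw baseline is real but modest at this
  scale (macro-F1 around 0.5 raw to around 0.6 denoised on the packaged
  experiment); the k-means margin over a single DAE is likewise small
  and seed-sensitive.
* The simulator's phantoms are blob mixtures; real macromolecules
  have sharper internal structure, which equalization can exaggerate.
* Absolute PSNR values depend on the normalization and peak convention;
  only differences between methods evaluated under one convention are
  meaningful.
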