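# cryocascade

Progressive denoising of single-particle cryo-EM projection images with a
cascade of convolutional denoising autoencoders, in R.

## The problem

Single-particle cryo-electron microscopy yields stacks of 2D projection
images of a biomolecule at unknown orientations.  Because the electron
dose must stay low, the images are extremely noisy — signal-to-noise
ratios (signal pixel variance over noise pixel variance) near **0.1**
are typical.  The step that suffers most is clustering the images by
projection orientation, whose class averages feed 3D reconstruction:
at SNR 0.1, generic clustering algorithms confuse orientations badly.

`cryocascade` is for computational structural-biology and image-analysis
practitioners who want a fully reproducible, self-contained testbed for
*progressive* denoising: no external data, no GPU, no Python — the
networks are implemented in RcppArmadillo and every stage is seeded.

## The method

Each block is a convolutional encoder–decoder

    z = EC(x),   y = DC(z),   f(x) = DC(EC(x))

(3 encoder modules of two 3×3 convolutions + 2×2 max-pooling; 3
upsampling-deconvolutions and a channel-collapsing convolution in the
decoder; 32 channels; dropout 0.5; 74,593 parameters).  Three blocks are
composed so that noise is removed in steps:

| block | pre-trained mapping |
|-------|---------------------|
| f1 | SNR 0.1 images → SNR 0.4 images |
| f2 | SNR 0.4 images → SNR 0.6 images |
| f3 | SNR 0.6 images → clean images |

Pre-training uses simulated projections of a 3D phantom with
SNR-calibrated additive Gaussian noise (`sigma = sqrt(var(signal)/SNR)`).
On a target stack with no clean references, each block is then
**fine-tuned pseudo-supervisedly**: the target for image *x* is the
pixelwise mean of its k = 30 most similar stack mates (noise is
independent across images, so the mean approximates the clean image),
computed on the block's own pre-trained outputs; blocks are tuned
sequentially, each feeding the next.  The final output is optionally
histogram-equalized — a monotone CDF remap that spreads the concentrated
gray values for viewing and clustering.

Denoising quality is scored by PSNR (`10·log10(peak²/MSE)`, peak 1);
clustering by k-means / Ward hierarchical clustering on pixels, with
clusters matched to orientation classes by optimal assignment and scored
with matched-class precision, recall and F1.

## Worked example

A complete miniature experiment (two phantoms, 4 orientations, 64×64
images, 200 training images per tier, 200 test images at SNR 0.1,
20 epochs per block; a few minutes on one CPU core):

```r
library(cryocascade)

plan  <- simulationPlan(nPerClass = 50, imageSide = 64, seed = 1)
ds    <- buildDatasets(plan)           # 4 aligned training tiers + test stack
empiricalSNR(cleanRef(ds$test), ds$test)
#> [1] 0.1001091                        # calibration hits the 0.1 target

model <- pretrainCascade(ds$train, blockSpec(),
                         trainConfig(epochs = 20, seed = deriveSeed(1, "pretrain")))
res   <- finetuneCascade(model, ds$test,
                         trainConfig(epochs = 20, seed = deriveSeed(1, "finetune")))

psnrVsClean(ds$test)@meanDb                               # raw noisy input
psnrVsClean(ds$test, pixels(res$record@stacks$X4))@meanDb # cascade output
```

On this run the raw test stack scores 5.5 dB against the clean
references and the fine-tuned cascade output 22.2 dB — a 16.7 dB gain —
with mean PSNR increasing monotonically across the three fine-tuned
stages (21.70 → 21.83 → 22.17 dB) and beating a single autoencoder
trained straight from low-SNR to clean under the same protocol
(21.72 dB).  Clustering the denoised images also recovers the
orientation classes better than clustering the raw ones
(k-means macro-F1 0.59 vs 0.52) — the regime where the raw baseline is
noise-limited and denoising decides the outcome:

```r
a <- clusterStack(res$record@stacks$X4, 4, "kmeans", seed = deriveSeed(1, "cluster"))
scoreClustering(a, labels(ds$test))@macroF1
```

A command-line front end wrapping the same functions is installed at
`inst/scripts/cryocascade`
(`cryocascade simulate|pretrain|finetune|denoise|evaluate --config <yaml>`).

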