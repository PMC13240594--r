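---
title: "Few-shot particle picking with hierarchical residual adapters: models and methods"
author: "cryofsl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot particle picking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryofsl)
```

# The problem

Particle picking locates the (x, y) centers of individual protein
projections in cryo-EM micrographs — images with extremely low
signal-to-noise ratio where particles are faint contrast variations over a
noisy background. Supervised pickers need large annotated corpora and
generalize poorly to new targets; annotating micrographs is the
bottleneck, counted per micrograph rather than per particle. `cryofsl`
implements a few-shot alternative: a frozen hierarchical image encoder is
adapted to a new protein with lightweight residual adapters trained from as
few as K = 1–10 annotated micrographs, the adapted features are decoded
into a segmentation mask, and a structured localization pipeline converts
the mask into particle coordinates exported as RELION-dialect STAR files.

# The adapter model

Let stage $i \in \{1..4\}$ of the encoder process feature maps of
embedding width $D_i$ through $\mathrm{depths}[i]$ blocks. Before every
block $(i, j)$ an adapter computes a residual modulation of the block
input $\mathrm{feat}_{(i,j)}$:

$$\mathrm{feat}^{adapter}_{(i,j)} = L^{shared}_i\!\left(\sigma\!\left(
  L^{unshared}_{(i,j)}\!\left(P^{emb}_i\,\mathrm{feat}_{(i,j)} +
  P^{fft}_i\,s_i\right)\right)\right), \qquad
  \mathrm{feat}^{final}_{(i,j)} = \mathrm{feat}_{(i,j)} +
  \mathrm{feat}^{adapter}_{(i,j)}$$

where $\sigma$ is the exact (erf-based) GELU, $P^{emb}_i : D_i \to d_i$
projects the embeddings into the bottleneck $d_i = \lfloor D_i /
\mathrm{reduction}\rfloor$, and $P^{fft}_i : 1 \to d_i$ projects a
high-pass FFT stream $s_i$ of the input micrograph. The unshared layer
$L^{unshared}_{(i,j)} : d_i \to d_i$ is specific to the block; the
up-projection $L^{shared}_i : d_i \to D_i$ is shared by all blocks of the
stage. The default configuration targets a four-stage hierarchical
encoder with widths 144/288/576/1152, depths 2/6/36/4 (48 adapters) and a
1/32 bottleneck.

Design choices where the formulation left room:

* **Shared-layer scope.** The up-projection is shared per stage, not
  globally: stage widths differ, so a single global map is dimensionally
  impossible. (`buildAdapterStack` allocates one per stage.)
* **Stage-1 bottleneck.** $144/32 = 4.5$ is floored to $d_1 = 4$; a floor
  of 1 is applied only when `clampBottleneck` is requested.
* **Zero initialization.** Shared up-projections (weights and biases)
  start at zero, so the adapted model is exactly the pretrained model at
  initialization — the standard way to keep few-shot training stable. The
  suite verifies identity to < 1e-6.
* **Biases** are included on all adapter layers; their cost is negligible.
* **FFT stream.** The micrograph is high-pass filtered once at full
  resolution with a Gaussian transfer function
  $H(f) = 1 - e^{-f^2/(2 f_c^2)}$, $f_c$ = `fftCutoffFraction` (default
  0.25) of Nyquist — Gaussian rather than brick-wall to avoid ringing —
  then average-pooled to each stage's grid and standardized per stage.
  DC gain is exactly zero, so constant images map to zero streams.

# The encoder contract and the surrogate

The encoder is pluggable: anything exposing per-stage widths, per-block
inputs accepting an additive pre-block modification, and 2x spatial
reduction between stages satisfies the contract. Full-scale runs would
plug in an externally supplied pretrained hierarchical vision transformer
checkpoint; nothing is downloaded by this package. For self-contained
desk-scale work `buildSurrogateEncoder` provides a small frozen tower
honoring the same contract: a linear patch embedding (stride 2 by
default), residual token-MLP blocks, and mean-pool + linear downsampling
between stages. Its parameters are drawn once from a seeded Gaussian and
never trained — the suite checks bit-identical serialization across a full
training run.

# Training

`trainFewShot` updates only the adapter stack and a small decoder head
with Adam on the balanced binary cross-entropy with logits,

$$\ell(z, t) = -\big[w_{+}\, t \log \sigma(z) + (1 - t) \log(1 -
\sigma(z))\big],$$

averaged over pixels. "Balanced" is interpreted as class-frequency
weighting: in `auto` mode $w_{+}$ is the per-batch background/foreground
pixel ratio clipped to [1, 100] (particle masks are sparse), with a
fallback to 1 on degenerate batches. Images are bilinearly resized to the
working resolution (masks: nearest, preserving labels), standardized to
zero mean and unit variance, and their FFT streams precomputed. Defaults
follow the full-scale protocol — batch size 2, Adam at 1e-4, up to 4000
epochs, 1024 px inputs; no early stopping (no stopping rule is defined
beyond the epoch cap) and no augmentation.

The decoder head fuses **all** stage outputs: each stage's token map is
nearest-upsampled to stage-1 resolution, linearly projected to a common
width (default 16), summed, passed through a GELU and a zero-initialized
linear map to one logit channel, then bilinearly upsampled to the working
resolution. A head reading only the final 1/16-resolution stage cannot
localize particles a few pixels wide; fusing the early high-resolution
stages mirrors how full-scale mask decoders consume hierarchical skip
features. Zero-initializing the last layer makes an untrained model output
a uniform probability of 0.5.

Because no deep-learning framework is available to R, the forward pass,
backpropagation and Adam are implemented directly in base matrix algebra;
the test suite validates every gradient path against central finite
differences (relative error below 1e-4 at eps = 1e-6).

## Desk-scale study conditions

All tests and the acceptance script run a scaled-down analogue of the
5-shot protocol, chosen once as the package's reference conditions:
synthetic 128 x 128 micrographs with 12 soft-edged disk particles of 16 px
at SNR 4 and minimum separation 1.5 diameters; surrogate encoder with
widths 16/32/64/128, depths 2/2/2/2, patch stride 2; adapter reduction 4
(the 1/32 default would leave 0–4 bottleneck channels at these widths);
head width 16; learning rate 1e-3 — larger than the full-scale 1e-4
because the surrogate model is orders of magnitude smaller and trained for
at most 150–300 epochs rather than thousands — batch size 2, 150 epochs.
Under these conditions training takes about a minute on one CPU and
reaches F1 = 1.0 on held-out synthetic micrographs; the acceptance
script reports the exact numbers it computes at run time.

# Synthetic micrographs

`simulateMicrograph` renders particles as disks of amplitude 1 with a
1-pixel cosine-tapered edge (a hard edge aliases and makes
distance-transform tests brittle) on a zero background, then adds i.i.d.
Gaussian noise. SNR is defined operationally as amplitude² over noise
variance — the field uses SNR loosely, and one fixed definition is needed
for calibration tests — so noise has standard deviation
$1/\sqrt{\mathrm{snr}}$. The ground-truth mask is exactly the union of
hard rasterized disks and the ground-truth coordinates are the continuous
centers. Placement is rejection sampling with a bounded retry budget;
overlaps are forced by setting `minSeparation` below one diameter with
`allowOverlap`. Identical specs give bit-identical output.

What the simulator does *not* emulate: CTF oscillations, ice and carbon
contamination, aggregation, orientation-dependent projection structure, or
correlated noise. Passing the synthetic oracles therefore demonstrates
the correctness of the machinery (adapters, training, localization,
metrics) under controlled low-SNR conditions, not performance on real
micrographs, which depends on the pretrained encoder plugged in at full
scale.

# Mask-to-coordinates localization

`masksToParticles` composes: strict binarization (`> threshold`),
Euclidean distance transform, multi-scale peak detection (local maxima of
the Gaussian-smoothed distance map at scales 1/2/4 px, finer scales taking
precedence; peaks below 0.25 of the expected radius in raw distance are
discarded; minimum peak spacing half the expected diameter),
marker-controlled watershed (ordered flooding of the negated distance map
restricted to the foreground), geometric filtering (region area within
[0.3, 3] of the expected disk area and contour circularity
$4\pi A / P^2 \ge 0.6$), a second recovery pass on the residual
foreground (finest scale only, halved distance floor) for closely packed
particles, and deduplication at 0.6 of the expected diameter with pass-1
priority, then higher distance value, then (y, x) order — a total order,
so the pipeline is deterministic.

Numerical details that matter:

* **Peak suppression window.** Candidate maxima are found with a maximum
  filter of *half* the minimum spacing, and the greedy spacing test allows
  a 1 px quantum: rasterized-and-smoothed maxima of two disks at exactly
  the minimum spacing sit about a pixel closer than the true centers, and
  a full-width window would merge them.
* **Perimeter estimator.** Circularity uses the Moore-traced contour arc
  length with diagonal steps weighted $\sqrt 2$; counting border pixels
  overestimates perimeters so severely that a rasterized disk could never
  pass a calibrated circularity floor. Circularity is clipped at 1.
* **Border regions are kept** by default (`dropBorder = FALSE`); dropping
  them silently would bias counts.
* All thresholds are exposed in `postprocessConfig`; the defaults are
  calibrated on the synthetic oracles (exact recovery of 50-disk fields,
  splitting of overlapping pairs down to 0.5 diameter center gaps).

# Evaluation and statistics

`matchParticles` pairs predictions with ground truth one-to-one within a
radius (half the expected diameter is the conventional choice), greedily
nearest-first and then completed to maximum cardinality with augmenting
paths — pure greedy matching provably under-counts on conflict chains,
whereas the completed matching equals the optimal-assignment count (the
suite checks this exhaustively on small instances against an independent
Kuhn-algorithm oracle). Precision, recall and F1 follow the usual
formulas with 0/0 resolving to 0; IoU is computed on rasterized disk
unions of the two coordinate sets, since the quantity of interest is the
spatial overlap of the picked areas.

`compareMethods` reproduces the comparison procedure: per method, dataset
and metric, per-micrograph values are paired against the reference method;
a Shapiro–Wilk gate records whether the paired differences look Gaussian
(metric distributions across micrographs are typically skewed, which is
why a nonparametric test is used throughout); the paired Wilcoxon
signed-rank test with normal approximation, midranks and tie correction
yields $z$ and a two-sided $p$; the effect size is the rank-biserial
correlation $r = z/\sqrt N$; and Benjamini–Hochberg adjustment is applied
jointly over all method-by-dataset tests of the same metric. The reported
statistic is $\min(W^+, W^-)$; $z$ carries the sign of the rank-sum
direction, which matches the sign of the median difference in
non-degenerate cases. Fewer than 5 valid pairs flags the entry
untestable; all-zero differences give the degenerate result $p = 1$,
$z = 0$ with a warning.

# Worked example

```{r example, eval = FALSE}
spec <- syntheticSpec(seed = 100)            # 128^2, 12 disks of 16 px, SNR 4
shots <- simulateFewShotDataset(spec, K = 5)
encoder <- buildSurrogateEncoder(seed = 1)
model <- trainFewShot(shots, encoder,
                      config = trainConfig(inputSize = 128,
                                           learningRate = 1e-3,
                                           maxEpochs = 150, seed = 1))
heldSpec <- spec; heldSpec$seed <- 6001
held <- simulateMicrograph(heldSpec)
prob <- predictMask(model, held$micrograph)
picks <- masksToParticles(prob, postprocessConfig(expectedDiameterPx = 16))
precisionRecallF1(matchParticles(picks, held$particles, matchRadius = 8))
writeStar(picks, "picks.star")
```

# Known limitations

* The surrogate encoder is a frozen random tower: it validates the
  adapter/training/localization machinery but carries no pretrained
  semantics; real-data performance requires an external full-scale
  encoder checkpoint.
* The simulator omits CTF, contamination and correlated noise (above).
* The geometric filter assumes roughly convex, disk-like particles;
  heavily aggregated or elongated shapes will be merged or rejected.
* Training determinism holds per platform (BLAS reduction order may vary
  across builds).
* `wilcoxonPaired` uses the normal approximation; for very small N an
  exact test would be preferable, and the implementation warns below 5
  informative pairs.
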