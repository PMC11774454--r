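---
title: "Task-based image-quality bounds for accelerated multi-coil MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based image-quality bounds for accelerated multi-coil MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senseIO)
```

## The problem

When k-space is under-sampled to accelerate an MRI acquisition, modern
learned reconstruction methods can produce images that look clean and score
well on data-fidelity metrics (RMSE) and perceptual metrics (SSIM) even when
the acquired data no longer contain the information needed for a diagnostic
task.  A reconstruction cannot create task-relevant information: by the
data-processing inequality, no observer acting on a reconstructed image can
outperform the ideal observer (IO) acting on the raw measurement data.  The
IO's performance in the raw data space is therefore an upper bound on what
any reconstruction-plus-observer pipeline can achieve, and tracking that
bound as a function of the acceleration factor shows directly which
accelerations still permit the task at all.

senseIO implements this programme end to end for binary signal-detection
tasks in a stylized multi-coil SENSE (sensitivity-encoding) acquisition:
stochastic object ensembles, the forward model, analytic and learned
observers in the data space, reconstruction baselines with image-space
observers, and ROC/AUC evaluation across acceleration factors.

## Measurement model

For coil $i$ of $C$, the measurement is

$$ g_i = \Phi F S_i f + n_i, $$

where $f$ is the object on an $H \times W$ grid, $S_i$ a complex coil
sensitivity map, $F$ the unitary DC-centered 2-D DFT, $\Phi$ a Cartesian
mask selecting phase-encode rows, and $n_i$ complex Gaussian noise.  Design
choices a user should know:

* **Noise convention.**  "Standard deviation $\sigma$" means independent
  $N(0, \sigma^2)$ on the real and on the imaginary part of every acquired
  sample (`noiseModel(sigma)`, default 15).  Noise is added on acquired
  lines only; unacquired lines are exactly zero and carry no data.
* **Mask family.**  `makeCartesianMask(H, R)` keeps every $R$-th row
  starting at offset 0.  With that offset the masks *nest*: rows kept at
  $R = 8$ are a subset of those at $R = 4$, which makes the analytic bound
  exactly monotone in $R$ rather than only statistically so.  A
  `centerFraction` option forces central lines on (it breaks exact
  nesting and is off by default).
* **Coils.**  `simulateCoilMaps()` places coils uniformly on the circle
  circumscribing the grid; magnitudes fall off as a Gaussian in distance
  from the coil centre, phases are linear in that distance, and maps are
  normalized so $\sum_i |S_i(r)|^2 = 1$.  This is a stylization chosen for
  reproducibility, not a field simulation; the normalization makes the
  fully sampled root-sum-of-squares reconstruction exactly invertible,
  which the tests exploit.

## Object models and task

The gold-standard object model for this kind of study is a learned
generative model of anatomy trained on clinical images.  senseIO
substitutes two parametric generators that run anywhere in milliseconds,
and `readEnsemble()` accepts any external 2-D ensemble (NIfTI) so a
learned model can be plugged in later:

* **Lumpy background** (`sampleLumpyBackground()`): DC offset plus a
  Poisson($\bar N$) number of Gaussian lumps with centres uniform over the
  grid.  Lumps are truncated at the grid edge (no wraparound); the
  ensemble-mean test accounts for that truncation exactly.  Defaults
  ($\bar N = 60$, amplitude 8, width 4 mm, offset 10 on $64^2$) give a
  smooth background of mean intensity near 20 in arbitrary units.
* **Stylized brain** (`makeStylizedBrain()`): skull and brain ellipses,
  two ventricles and a cortical rim with seed-jittered geometry, plus a
  tissue mask marking a white-matter-like region for signal placement.  It
  is not an anatomically validated segmentation.

The signal is a rotationally symmetric Gaussian with amplitude 0.7 and
standard deviation 2 mm (defaults of `signalModel()`), placed either at a
fixed location (SKE, signal known exactly) or uniformly at random over the
tissue mask / a discrete candidate set (SKS).  With the default 1 mm pixel
the 2 mm width maps to $\sigma = 2$ px.

**Intensity scale.**  Detectability depends only on the signal and the
noise: $d' = \|s\|/\sigma$ with $\|s\| \approx 2.5$ for the default
signal, so the sweep default $\sigma = 1$ puts the full-sampling ideal
observer at AUC $\approx 0.95$ — a mid-to-high operating point where
acceleration effects are visible in both directions.  Tests that target a
specific detectability instead set $\sigma = \|s\|/d'$.  The *background*
scale does not enter $d'$ but governs how reconstructed images look: with
background intensities near 20 and unit-scale noise, magnitude images are
in the usual high per-pixel SNR regime, RMSE/SSIM behave like ordinary
image-quality numbers, and the signal is a subtle ~3% contrast lesion.
With a background of order the noise, images are Rayleigh-noise dominated
and image-space observers collapse regardless of reconstruction — a
regime that makes the bound comparison degenerate, which is why the
defaults avoid it.

## Observers

* **Analytic SKE/BKE ideal observer** (`skeBkeStatistic()`): in complex
  Gaussian noise with known background $b$ and signal $s$, the exact
  log-likelihood ratio is
  $t(g) = \mathrm{Re}\langle s, g - b\rangle/\sigma^2 - \|s\|^2/2\sigma^2$
  over sampled entries.  Its detectability is $d' = \|s\|/\sigma$ and its
  ROC area is $\Phi(d'/\sqrt 2)$, equivalently $\tfrac12 +
  \tfrac12\,\mathrm{erf}(d'/2)$ (`skeBkeAnalyticAuc()`).  (Care: the two
  equivalent forms are a classic source of $\Phi$-vs-erf transcription
  slips; the package's Monte-Carlo tests pin the relation down.)
* **Analytic SKS mixture observer** (`sksBkeStatistic()`): exact IO for a
  discrete location mixture, computed with log-sum-exp.  Location
  uncertainty strictly degrades performance, which the tests verify.
* **Hotelling observer** (`fitHotelling()`): the optimal linear observer,
  estimated as $w = \Sigma_\alpha^{-1}(\mu_1 - \mu_0)$ with the pooled
  covariance shrunk toward its diagonal,
  $\Sigma_\alpha = (1-\alpha)\hat\Sigma + \alpha\,\mathrm{diag}\hat\Sigma$.
  Shrinkage (default 0.01; the sweep uses 0.05) keeps the solve well posed
  at the sample sizes used here.  Image-space Hotelling observers are usually
  given a region of interest around the signal; restricting the support is
  always admissible for a bound comparison (any observer is).
* **CNN ideal-observer approximation** (`trainCnnIO()`): a convolutional
  classifier with sigmoid readout trained by binary cross-entropy, whose
  optimum is a monotone transform of the likelihood ratio.  Depth is grown
  stage by stage (defaults: start at 2 convolutional layers, add 1 per
  stage, at most 5 stages) and growth stops when validation AUC — the
  quantity of interest, not the loss — improves by less than 0.005.
  Multi-coil complex data enter as $2C$ real channels ordered coil-major
  (Re, Im); each coil's zero-filled k-space is first taken to the image
  domain by the per-coil unitary inverse DFT.  That transform is
  invertible and noise-whitening, so the observer still faces exactly the
  raw-data task, while the signal becomes spatially localized and
  convolution-friendly; learning a global Fourier-domain template through
  small kernels and pooling would be needlessly hard.  Inputs are centered
  by the per-pixel training-mean image — removing any static background
  pattern that would otherwise dominate the dynamic range — and scaled per
  channel.  Within each stage, training proceeds epoch by epoch with the
  best-epoch weights kept by validation AUC (these small networks overfit
  within a few epochs, so early stopping is the operative regularizer).  The network itself (3x3
  kernels, 8 channels, average pooling down to $8 \times 8$, dense logit
  readout, Adam) is implemented in compiled code in the package; all
  training is seeded and the returned model carries its per-stage AUC
  trace.

## Reconstruction baselines and metrics

`reconRSOS()` (zero-filled per-coil inverse DFT, root sum of squares),
`reconCgSense()` (conjugate-gradient solution of the Tikhonov-regularized
normal equations; the provenance records the residual trace and the
quadratic-objective trace — the latter is what CG provably decreases
monotonically, so that is what the tests assert), and `trainReconNet()`, a
deliberately small two-resolution-level encoder–decoder with a global
residual connection (about 3k parameters at the default width 12) trained
on rSOS inputs against fully sampled references.  It plays the role of a
deep-learning reconstruction baseline at CPU scale and is an analog of
such methods, not a reproduction of any published network.

`rmse()` and `ssim()` implement the traditional metrics; SSIM uses a
Gaussian window (sd 1.5 px, truncated at 3 sd, renormalized at borders)
with the standard constants $K_1 = 0.01$, $K_2 = 0.03$ and a dynamic range
defaulting to the reference's intensity range.

## The acceleration sweep

`runAccelerationSweep(sweepConfig(...))` ties everything together.  For
each $R$ it computes the analytic data-space bound, simulates training and
evaluation ensembles, trains the learned reconstructor for that $R$, fits
a Hotelling observer on every reconstruction method's images, and reports
AUC (rank estimator with Hanley–McNeil standard errors) plus mean
RMSE/SSIM.  `compareBounds()` then reports the bound-minus-observer gap per
R with its combined standard error, flags violations beyond 2 SE, and
juxtaposes the RMSE/SSIM ordering of methods against their AUC ordering to
surface discordances — the situation where a method "wins" on traditional
metrics while the detection task says otherwise.

Two facts make the comparison sound even though the sweep's backgrounds are
random (BKS) while the analytic bound assumes a known background: the
SKE/BKE ideal observer upper-bounds the BKS ideal observer (extra knowledge
cannot hurt), and the data-processing inequality bounds every image-space
observer by the data-space IO.  So the analytic column is a valid — if
conservative — ceiling for every other column.

## Problem sizes and determinism

The reference experiment runs at $64 \times 64$ with 8 coils.  Sample
sizes were chosen so every Monte-Carlo comparison carries a standard error
well below the effects being tested: $10^4$ paired draws for oracle
agreement (AUC SE $\approx 0.004$), 4000 training / 2000 validation draws
per hypothesis for the CNN observer, 700–2000 draws per hypothesis for
image-observer AUCs in the sweep, and 96 image pairs for the small
reconstructor.  Everything stochastic takes an explicit seed: phantom
sampling, noise, network initialization and minibatch shuffling; a sweep
rerun with the same configuration reproduces every number bit for bit.

## Limitations

* The parametric object models emulate smooth anatomy-like variability but
  not learned anatomical realism; absolute AUC values in this package
  characterize the simulation, not any clinical system.  Passing tests
  show the machinery is correct and internally consistent, not that a
  particular scanner setting is safe.
* The BKS ideal observer is intractable; on BKS tasks the CNN observer's
  AUC is an *estimate* of the bound, reported with a standard error, and
  is never asserted optimal.
* Coil phases, masks and noise are stylized; non-Cartesian trajectories,
  field inhomogeneity and calibration-based coil-map estimation are out of
  scope.
* The learned reconstructor is intentionally tiny; it demonstrates the
  metric/task discordance phenomenon but is not representative of
  state-of-the-art reconstruction quality.
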