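---
title: "Stacked competitive networks for low-dose CT denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked competitive networks for low-dose CT denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Computed tomography reconstructs a map of linear attenuation coefficients
$\mu(x, y)$ from X-ray transmission measurements. Radiation dose scales
with the photon budget per ray, so low-dose protocols reduce the blank-scan
count $b_0$; the price is Poisson noise in the measurements, which filtered
back-projection (FBP) turns into grainy mottle and, near strongly
attenuating structures such as bone, radiating streak artifacts.

`ldctscn` implements a *post-reconstruction* denoiser: a convolutional
network is trained on aligned pairs of low-dose (LDCT) and normal-dose
(NDCT) slices and learns the mapping $R : X \to Y$ from degraded to clean
image. Because clinical paired data cannot ship with a package, `ldctscn`
also implements the full simulation chain that manufactures such pairs
from first principles, so every experiment is reproducible from a single
seed.

## The simulation chain

**Phantoms.** `random_phantom_spec()` describes a family of synthetic
abdominal slices: a soft-tissue body disk, a few low-contrast ellipses,
and two or three bone-like inserts. `generate_phantom(spec, seed)`
rasterizes one member by pixel-centre membership (no anti-aliasing), so a
phantom is piecewise constant and line integrals through it have exact
closed forms — this is what makes the projector testable against
first-principles oracles.

The family's defaults are deliberately calibrated to a *difficult*
low-dose regime. The body disk's attenuation (0.038/mm over a 180 mm
diameter) gives water-equivalent path lengths comparable to a large
abdomen (line integrals up to about 8, i.e. transmitted fractions of a few
$10^{-4}$), and the bone inserts guarantee photon-starved rays. Without
this calibration a small water-like phantom at $b_0 = 10^5$ photons is
nearly noise-free and there is nothing for a denoiser to do; with it, the
simulated LDCT images carry the same mottle and streaks — and sit in the
same PSNR band (low thirties in dB) — as published low-dose abdominal CT.
The limits of the generator are equally deliberate: piecewise-constant
ellipses lack anatomical texture, the source is monoenergetic (no beam
hardening), and scatter is not modelled. Conclusions about *relative*
denoiser behaviour transfer; absolute clinical image quality does not.

**Forward model.** `siddon_project()` computes fan-beam line integrals
$l_i = \int_{r_i} \mu \, ds$ with the exact parametric pixel-crossing walk
(Siddon's algorithm): every traversed pixel contributes its intersection
length times its attenuation, with no interpolation error. The geometry is
a rotating point source (400 mm from the rotation centre) and a flat
413 mm detector (400 mm behind the centre, 512 bins), 1024 views over
360°. Noise follows the standard transmission model

$$ z_i \sim \text{Poisson}\!\left(b_0 e^{-l_i} + r\right), $$

with $r$ an electronic-noise floor (`simulate_counts()`), and the noisy
line integrals are re-estimated as
$\hat l_i = \ln\left(b_0 / \max(z_i - r, \varepsilon)\right)$ with a
one-count floor $\varepsilon$ so photon-starved rays stay finite
(`counts_to_sinogram()`); negative estimates are clipped, since a ray
cannot measure more than the blank scan on average.

**Reconstruction.** `fbp_reconstruct()` is textbook flat-detector fan-beam
FBP: cosine pre-weighting $d_{so}/\sqrt{d_{so}^2 + s^2}$ on the virtual
detector through the isocentre, frequency-domain ramp filtering with the
band-limited kernel (zero-padded to the next power of two past $2 n_{bins}$),
optional Hann apodization, then back-projection with the fan-beam
$1/U^2$ distance weight and linear interpolation between bins. A full-turn
scan measures every ray twice, hence a factor $\tfrac12$. The default
filter is Hann; the *dataset generator* uses the unapodized ramp for both
members of each pair so the LDCT image keeps its full noise texture — a
Hann window would pre-solve part of the denoising problem and hide the
streaks the network is supposed to learn.

## The network

The building unit is the **competitive block**. Given an input feature map
$A$, the block convolves it at several kernel scales $k \in K$ (all with
same-size zero padding so the maps align), adds biases, rectifies, and
combines the scales by an element-wise maximum, per pixel and per filter:

$$ \Phi(A) = \max_{k \in K} \; \mathrm{ReLU}\!\left(W_k * A + b_k\right). $$

The max is a *competition*: at every output element exactly one scale
wins, so the block adaptively selects its receptive field — small kernels
where fine detail matters, large ones where context does. A stack of such
blocks (`scn_descriptor()`, `init_scn()`, `scn_forward()`) is a fully
convolutional image-to-image network; the final block has one output
filter and a *linear* head (maximum of affine responses, no terminal
rectifier), so the network can reproduce the full output range. With a
single scale, $|K| = 1$, a block reduces exactly to a plain rectified
convolution — which is how the package expresses the CNN ablation
baselines (`variant_scales("cnn3")`).

Training (`fine_tune()`) minimizes squared error plus weight decay over
aligned patch pairs $(x_i, y_i)$:

$$ L = \frac1N \sum_{i=1}^{N} \lVert R(x_i) - y_i \rVert_2^2
       \;+\; \alpha \sum \lVert W \rVert_F^2 , $$

with the sum over pixels inside each patch, the mean over the batch, and
the decay over all convolution kernels (biases excluded). Optimization
runs Adam for the first half of the epochs and plain stochastic gradient
descent for the second, with the learning rate stepping down by decades
from $10^{-2}$ to $10^{-5}$. Greedy layer-wise pretraining
(`pretrain_blocks()`) is available: each hidden block, with a throwaway
linear head, learns to reconstruct its own input from the low-dose patches
before supervised fine-tuning.

## Numerical design choices

* **Double-precision public operators, single-precision training.** Every
  public operator (projection, FBP, block forward, network inference) runs
  in double precision so tests can pin them against independent oracles at
  tight tolerances. The training loop runs through fused single-precision
  kernels: one im2col matrix per block at the largest kernel size (smaller
  scales are column subsets), one SGEMM per scale, rectifier and max fused.
  The fused forward agrees with the double path to ~$10^{-7}$ and the
  gradients match finite differences to ~$10^{-6}$ relative — orders of
  magnitude below the stochastic-gradient noise floor — while roughly
  doubling single-core throughput.
* **Maxout backward without cached pre-activations.** For a rectified
  block, the winning scale's rectified response *is* the block output, so
  the gradient mask of scale $s$ is simply
  `(amax == s) & (out > 0)`. Ties break toward the smaller scale, in the
  forward and backward passes alike, so gradient always flows to exactly
  one scale per element.
* **Best-validation checkpointing.** After every epoch the model is scored
  (PSNR) on held-out validation images; the weights returned are the best
  seen, not the last — the late low-learning-rate epochs cannot silently
  degrade the model.
* **Seed discipline.** Every stochastic stage (phantom draws, photon
  noise, weight init, shuffling) consumes a child seed derived from one
  master seed, and seeding is scoped (`with_seed()`) so the caller's RNG
  state is never disturbed. One seed reproduces an experiment
  bit-for-bit.

## A worked toy experiment

The package's study profile is CPU-scale: 64×64 phantoms, a
proportionally scaled acquisition (128 bins, 256 views), a 3-block
16-filter SCN with scales {1, 3, 5}, roughly 2000 patch pairs of 16×16
at stride 4 from twelve training slices, 30 epochs.

```{r}
library(ldctscn)
cfg <- experiment_config(variant = "scn3", seed = 1L)
res <- run_experiment(cfg, out_dir = "scn3_run")
res$report            # held-out PSNR / RMSE / SSIM of the network output
res$report_ldct       # the same metrics for the raw LDCT input
res$psnr_gain_db      # mean improvement over the input
```

and the architecture ablation on an identical dataset:

```{r}
ab <- run_ablation(cfg, variants = c("cnn3", "scn3"))
sapply(ab, `[[`, "psnr_gain_db")
```

## What the tests do and do not establish

The test suite pins the physics against independent oracles (dense line
sampling for the projector, analytic disk values for the ramp filter and
round trip, Poisson moments for the noise model), the network against
brute-force enumeration (multi-scale maxout, hand-computed losses,
finite-difference gradients), and the bookkeeping (patch counts,
provenance, reproducibility) exactly. The end-to-end toy study
demonstrates that training *improves* the low-dose input on held-out
phantoms from unseen slices — at toy scale the improvement is on the
order of one dB, limited by the 16-filter capacity, the ~2000-patch
budget and the 30-epoch budget, not by the physics. Full-scale results
(deep 96-filter networks, $\sim 10^6$ patches of 100×100, clinical data)
are outside what a CPU test suite can reproduce; the defaults of
`train_config()` record that regime, and nothing in the implementation is
specific to the toy sizes.

## Limitations

* 2-D fan-beam slices only; no helical or cone-beam geometry.
* Monoenergetic forward model: no beam hardening, no scatter, no detector
  cross-talk; the electronic noise floor is a mean offset, not a full
  read-out model.
* Phantoms are piecewise-constant ellipse composites — adequate for
  studying noise and streaks, blind to anatomical texture.
* The denoiser operates purely in the image domain; sinogram-domain or
  iterative (model-based) reconstruction methods are out of scope.
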