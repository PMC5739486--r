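# ldctscn — stacked competitive networks for low-dose CT denoising

Low-dose computed tomography trades radiation exposure for image quality:
fewer photons per ray (a lower blank-scan count *b₀*) means Poisson noise
in the measured transmissions, which filtered back-projection turns into
mottle and — behind strongly attenuating structures — radiating streak
artifacts. `ldctscn` studies a learned, image-domain remedy on fully
synthetic data: it simulates paired normal-dose / low-dose slices from
first principles and trains a **stacked competitive network (SCN)** to map
the degraded image back to the clean one.

## The core algorithm

The network is a stack of *competitive blocks*. Block input *A* is
convolved at several kernel scales *k* ∈ *K* (same-size zero padding keeps
the maps aligned), rectified, and the scales compete element-wise:

    Φ(A) = max_{k ∈ K}  ReLU(W_k * A + b_k)

per pixel and per filter — a multi-scale maxout that adaptively selects
its receptive field. The final block has one filter and a linear head.
With |K| = 1 a block reduces exactly to a plain rectified convolution,
which is how the CNN ablation baselines are expressed. Training minimizes

    L = (1/N) Σᵢ ‖R(xᵢ) − yᵢ‖² + α Σ ‖W‖²_F

over aligned low-dose/normal-dose patch pairs (Adam for the first half of
the epochs, plain SGD for the second, learning rate stepping down by
decades from 1e-2 to 1e-5), with optional greedy layer-wise pretraining.

The physics chain behind the training pairs: ellipse attenuation phantoms
(`generate_phantom`), exact Siddon ray-driven fan-beam projection
(`siddon_project`), Poisson counts z ~ Poisson(b₀·e^{−l} + r)
(`simulate_counts`), the log-transform estimate l̂ = ln(b₀/max(z−r, ε))
(`counts_to_sinogram`), and fan-beam filtered back-projection with a
band-limited ramp and optional Hann apodization (`fbp_reconstruct`).
PSNR / RMSE / SSIM scoring lives in `eval_report`.

## Worked example

The CPU-scale study profile: 64×64 abdominal-style phantoms, a
proportionally scaled fan-beam acquisition, b₀ = 10⁵ photons, a 3-block
16-filter SCN-3 (scales 1/3/5), ~2000 patch pairs, 30 epochs — about
5 minutes on one core.

```r
library(ldctscn)
cfg <- experiment_config(variant = "scn3", seed = 1L)
res <- run_experiment(cfg)
res$report_ldct   # the raw low-dose input vs the normal-dose reference
#> eval_report over 3 image(s):
#>   psnr_db  35.8227 +/- 3.0289
#>   rmse     0.0169 +/- 0.0063
#>   ssim     0.8839 +/- 0.0573
res$report        # the trained network's output
#> eval_report over 3 image(s):
#>   psnr_db  36.8592 +/- 2.3690
#>   rmse     0.0147 +/- 0.0043
#>   ssim     0.9215 +/- 0.0388
res$psnr_gain_db
#> [1] 1.036531
```

The architecture ablation (identical dataset across variants):

```r
ab <- run_ablation(cfg, variants = c("cnn3", "scn3"))
sapply(ab, `[[`, "psnr_gain_db")
#>       cnn3       scn3
#> -0.8007192  1.0365313
```

At this toy scale the multi-scale competition is what makes the gain
positive: on the identical data the single-scale CNN-3 baseline *loses*
0.8 dB while the SCN-3 gains 1.0 dB.

A thin command-line front end wrapping these functions ships in
`inst/cli/ldctscn` (subcommands `simulate`, `reconstruct`, `train`,
`evaluate`, `run`, `ablate`), and example phantom specifications in
`inst/extdata/`.

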