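# petldm

Conditional 3D latent diffusion for CT-to-PET synthesis, in R, with the
full SUV-space evaluation suite and a seeded phantom generator.

PET measures tracer uptake (in standardized uptake value, SUV, units) that
CT cannot provide, but PET is expensive and unevenly available. Synthesizing
PET from CT is a one-to-many translation problem: uptake is only partially
constrained by anatomy. `petldm` is aimed at researchers studying this
translation task and its evaluation methodology — it implements the whole
pipeline at desk scale (one CPU, no imaging download), from paired-volume
preprocessing through two-stage generative training to lesion-level
evaluation and cohort statistics.

## What is inside

* **Stage I** — a KL-regularized 3D variational autoencoder compressing a
  PET volume `y` into a 3-channel latent at 4× reduced resolution
  (`q(z|y) = N(μ(y), diag(σ²(y)))`, `z = μ + σ⊙ε`), trained with
  `L1 + w_KL·KL + w_p·perceptual + w_adv·adversarial`
  (defaults `1e-6, 0.001, 0.01`).
* **Stage II** — a DDPM over the latents: scaled-linear noise schedule
  (`β: 0.0015 → 0.0195`, `T = 1000` at the full profile), forward
  corruption `z_t = √ᾱ_t z_0 + √(1−ᾱ_t) ε`, a conditional 3D diffusion
  U-Net `ε_θ(z_t, t, c(x))` (channels `[32, 64, 64]`, one residual block
  per level, self-attention at the two deepest levels) trained on the
  noise-prediction MSE, and reverse sampling in posterior-mean
  (`reverse_step_printed`) or ancestral (`reverse_step_ancestral`) form.
* **Anatomy-guided preprocessing** — RAS reorientation, resampling,
  CT/PET intensity clipping, lung-base-to-head cropping (built-in threshold
  lung segmenter or an external mask), fixed-size crop/pad.
* **Evaluation** — masked MAE / PSNR / 3D SSIM in SUV space; lesion
  detection via connected components and greedy one-to-one overlap
  matching (precision, recall, false positives per scan); lesion SUV MSE
  and NMSE (%); lesion volume MAPE and Pearson r; mean ± SD with Student-t
  95% CIs; exact paired Wilcoxon signed-rank tests.
* **Phantoms** — a seeded generator of paired CT/PET volumes with lesion,
  lung, and body masks, NIfTI output and CSV manifests, emulating the
  anatomical coupling the task assumes (see the methods vignette).

## Worked example

```r
library(petldm)

spec <- phantom_spec(grid_shape = c(32, 32, 16), spacing = c(6, 6, 12),
                     lesion_count_range = c(3, 3),
                     ct_noise_sd = 0, pet_noise_sd = 0)
case <- generate_case(spec, case_seed = 7)
case$ct
#> <volume3d CT-HU> 32x32x16 voxels, spacing 6x6x12 mm, RAS, range [-1e+03, 70]
case$pet
#> <volume3d PET-SUV> 32x32x16 voxels, spacing 6x6x12 mm, RAS, range [0, 10.7]

pp <- preprocess_case(case$ct, case$pet, lung_mask = case$lung_mask,
                      lesion_mask = case$lesion_mask,
                      target_spacing = c(6, 6, 12),
                      target_shape = c(32, 32, 16))

# evaluate a degraded copy of the reference against the reference
ctx <- eval_context(pp$body_mask, Q = 30)
set.seed(1)
noisy <- unclass(pp$pet) + array(rnorm(length(pp$pet), sd = 0.2), dim(pp$pet))
mae_masked(pp$pet, noisy, ctx)    # 0.158  (SUV; mean |error| over the body)
psnr_masked(pp$pet, noisy, ctx)   # 43.58  (dB, relative to Q = 30)
ssim3d_masked(pp$pet, noisy, ctx) # 0.968  (7x7x7 local structural similarity)

gt   <- extract_lesions(pp$lesion_mask, threshold = 0.5, min_voxels = 1)
pred <- extract_lesions(volume3d(noisy, c(6, 6, 12), "RAS", "PET-SUV"),
                        threshold = 2.5)       # >= 2.5 SUV, >= 3 voxels
m <- match_lesions(gt, pred)
c(m$tp, m$fp, m$fn)
#> 1 0 2   (two reference lesions fall below the 3-voxel minimum at this
#>          coarse spacing — see the vignette's limitations section)

# the cohort CI convention: Student-t interval from summary moments
ci_from_moments(303.05, 22.16, n = 150)
#>   ci_low  ci_high
#> 299.47   306.63
```

Training end to end at the toy profile (`run_config("toy")`): generate a
cohort with `generate_cohort()`, load it with `load_cohort()`, then
`train_stage1()` → `train_stage2()` → `synthesize()` →
`evaluate_cohort()`. A thin command-line front end with subcommands
(`phantoms`, `preprocess`, `train-vae`, `train-ldm`, `synthesize`,
`evaluate`) is installed at `inst/cli/petldm`.

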