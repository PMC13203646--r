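---
title: "Conditional latent diffusion for CT-to-PET synthesis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional latent diffusion for CT-to-PET synthesis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

PET carries physiologic information (tracer uptake in standardized uptake
value, SUV, units) that CT cannot provide, but PET is costly and not
uniformly available. Translating a CT volume into a plausible PET volume is
an inherently one-to-many problem: uptake is only partially constrained by
anatomy, so several uptake patterns are compatible with one CT appearance.
`petldm` implements a two-stage conditional latent diffusion approach to
this translation task for the lung-base-to-head field of view, together with
the complete SUV-space and lesion-level evaluation suite and a seeded
phantom generator, so that every stage is testable on one CPU with no
imaging download.

## The model

**Stage I — KL-regularized autoencoder.** A 3D convolutional encoder
$E$ maps a PET volume $y$ to a Gaussian posterior
$q(z \mid y) = \mathcal N(\mu(y), \mathrm{diag}(\sigma^2(y)))$, sampled via
the reparameterization $z = \mu + \sigma \odot \varepsilon$. Two stride-2
stages give a $4\times$ per-axis spatial reduction (a $96\times96\times64$
volume becomes a 3-channel $24\times24\times16$ latent). The decoder $D$
regresses SUV directly (no final activation). The training objective is

$$\mathcal L_{AE} = \lVert y - D(E(y)) \rVert_1
  + w_{KL}\,\mathcal L_{KL} + w_p\,\mathcal L_p + w_{adv}\,\mathcal L_{adv},$$

with $\mathcal L_{KL} = \tfrac12\sum_i (\mu_i^2 + \sigma_i^2 -
\log \sigma_i^2 - 1)$ summed over the latent elements of a sample and
averaged over the batch, and defaults $w_{KL} = 10^{-6}$, $w_p = 0.001$,
$w_{adv} = 0.01$.

**Stage II — DDPM in latent space.** The forward process corrupts a clean
latent with Gaussian noise, $z_t = \sqrt{\bar\alpha_t}\,z_0 +
\sqrt{1-\bar\alpha_t}\,\varepsilon$, under a scaled-linear schedule
($\sqrt{\beta_t}$ affine in $t$; $\beta_1 = 0.0015$ to
$\beta_{1000} = 0.0195$ at the full profile, with $\bar\alpha_0 = 1$ by
convention). A conditional U-Net $\epsilon_\theta(z_t, t, c(x))$ predicts
the corrupting noise by minimizing
$\lVert \varepsilon - \epsilon_\theta \rVert_2^2$, with the CT condition
$c(x)$ concatenated channel-wise to the latent at every call. Sampling
starts from $z_T \sim \mathcal N(0, I)$ and iterates the reverse step to
$t = 1$; `reverse_step_printed()` is the posterior-mean update, and
`reverse_step_ancestral()` additionally injects the posterior variance
$\tilde\beta_t = \frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t}\beta_t$ (the
standard DDPM sampler; the default). Both are provided because reverse
updates are sometimes written in the mean-only form while standard DDPM
schedulers implement the ancestral one; which a given study used is often
not determinable from its text, so the choice is a configuration key.

## Tunable parameters

| key | default (full / toy) | meaning |
|---|---|---|
| `input_size` | 96×96×64 / 32×32×16 | voxel grid after preprocessing |
| `vae_channels`, `unet_channels` | [32, 64, 64] / [8, 16, 16] | per-level feature channels |
| `latent_channels` | 3 | latent channels |
| `T`, `beta_start`, `beta_end` | 1000, 0.0015, 0.0195 / 50, 0.008, 0.20 | diffusion schedule |
| `learning_rate`, `batch_size` | 1e-4, 2 / 2e-3, 4 | Adam settings |
| `epochs_vae`, `epochs_diffusion` | 5, 150 / 60, 300 | training lengths |
| `hu_window` | [-1000, 1000] HU | CT clip window (covers lung-to-bone) |
| `suv_max` | 30 SUV | PET clip; also the metric dynamic range Q |
| `target_spacing` | 2×2×3 mm / 6×6×12 mm | resampling spacing |
| `lesion_threshold`, `lesion_min_voxels`, `lesion_connectivity` | 2.5 SUV, 3, 26 | predicted-lesion definition |

The toy profile is the test surface; the full (`"paper"`) profile records
the reference architecture and is not intended for CPU training.

### Why the toy schedule differs from a truncated full schedule

With $T = 50$ and the full-profile beta range, $\bar\alpha_T \approx 0.64$:
the forward process would retain most of the signal at its endpoint while
sampling starts from pure noise — a train/inference mismatch. The toy
profile therefore preserves the *terminal signal-to-noise level* of the
full-length schedule ($\bar\alpha_T \approx 10^{-2}$ via $\beta$ from 0.008
to 0.20) rather than the beta endpoints, keeping the scaled-linear rule.

### Latent standardization

Diffusion operates on standardized latents: the mean training-latent field
is subtracted and each channel is divided by the SD of the residuals
(stored as `scale_meta` in the stage-I checkpoint and inverted before
decoding). Standardizing by a per-channel SD alone leaves the shared
anatomical component dominating the latent scale; after centring, the
case-specific (condition-dependent) residual *is* the unit-scale signal, so
the conditional pathway dominates the noise-prediction objective instead of
being a ~10%-scale perturbation. At desk scale this is the difference
between a denoiser that uses its condition and one that ignores it.

### Conditioning

`make_condition()` defaults to a trilinear downsample of the normalized CT
to the latent grid (one channel, deterministic). The alternative mode
encodes the CT with the frozen stage-I encoder mean (3 channels in the same
representation space as the latents being denoised). The toy profile uses
the encoder mode: diagnostics showed that at 8×8×4 resolution through the
small U-Net, the single-channel downsampled CT carries too little anatomy —
the implied clean-latent estimate at high noise levels was worse than an
unconditional mean — whereas encoder conditioning lets the network learn a
near-identity mapping from condition features to latent structure. The full
profile keeps the downsampling default.

## The phantom generator

`phantom_spec()` / `generate_case()` emulate the paired structure the
translation task assumes: a soft tissue body ellipsoid (40 HU) with two
low-attenuation lungs (-750 HU) in air (-1000 HU); smooth background uptake
(1 SUV with a fixed anatomical profile and a small per-case amplitude drawn
from U(0.05, 0.15)); spherical lesions whose SUV (U(4, 12)) is drawn
independently of HU but which carry a +30 HU CT correlate, making the
CT-to-PET mapping learnable yet one-to-many; additive Gaussian noise (20 HU
/ 0.1 SUV by default), with PET clipped at zero. Body and lung sizes and
lung positions jitter per case (about ±15%), emulating inter-patient
anatomical variability — without it, the cohort-mean PET is a near-oracle
predictor and conditioning on CT carries no signal, which would make the
translation task degenerate. Lesions are spheres in world coordinates, so
ground-truth volumes are analytically checkable against
$\tfrac43\pi r^3$.

What the phantoms do *not* emulate: tracer kinetics, scanner point-spread
functions, attenuation/reconstruction physics, respiratory motion, and the
textural heterogeneity of real uptake. Passing the desk-scale tests
therefore demonstrates that the pipeline's machinery (geometry handling,
losses, gradients, schedule algebra, metrics, seeding) is correct and that
the model can extract anatomical conditioning signal — not that clinical
PET synthesis quality is achieved.

## Preprocessing

Orientation is standardized to RAS; volumes are resampled (trilinear for
images, nearest for masks) with centre-aligned voxels; CT is clipped to
[-1000, 1000] HU and mapped to [-1, 1]; PET is clipped to [0, 30] SUV with
no rescaling (all metrics are computed in SUV units). The field of view is
restricted from the inferior lung extent superiorly to the head: lungs come
either from a supplied mask file or from the built-in threshold segmenter
(HU < -400 inside the body mask, two largest 26-connected components) —
sufficient because the crop only needs the inferior lung extent. A centred
fixed-size crop/pad (odd remainders to the far side) yields the uniform
grid. The evaluation mask B is the body mask (HU > -500, largest component,
holes filled so the lungs stay inside) computed on the cropped CT.

## Evaluation suite

Global metrics are restricted to B: MAE, PSNR
($10\log_{10}(Q^2/\mathrm{MSE}_B)$ with $Q = 30$; identical inputs are
reported as a documented 300 dB sentinel), and 3D SSIM with a uniform
7×7×7 window, $c_1 = (0.01Q)^2$, $c_2 = (0.03Q)^2$, symmetric boundary
reflection, averaged over B. Lesion analysis extracts connected components
of `{pet >= 2.5 SUV}` with at least 3 voxels under 26-connectivity
(reference lesions are the components of the reference mask), matches
predictions to references greedily one-to-one by descending voxel overlap
(admissible iff ≥ 1 shared voxel; ties to the smaller predicted label), and
reports subject-averaged precision and recall (subjects with undefined
values are excluded from the respective mean and counted), false positives
per scan, lesion SUV MSE and NMSE (%) over the union of reference lesion
voxels, and volume agreement (MAPE with an $\epsilon = 10^{-6}$ guard, and
Pearson r) over matched lesions. Cohort summaries are mean ± sample SD with
Student-t 95% CIs — the convention that reproduces the published intervals
from their printed moments at n = 150 (the normal-z critical value does
not). Paired comparisons use a two-sided Wilcoxon signed-rank test: zero
differences dropped, average ranks under ties, an exact null distribution
(dynamic programming over doubled ranks, equivalent to enumerating all
$2^m$ sign assignments) for up to 25 non-zero differences, and a
tie-corrected normal approximation with continuity correction otherwise.

## Numerical choices

* Timesteps are 1-indexed externally with $\bar\alpha_0 = 1$, making the
  $t = 1$ reverse step well defined.
* $\sigma$ is parameterized as $\exp(\frac12\log\sigma^2)$; the KL is
  computed in log-variance form.
* The perceptual term is an analytic operator: the L1 average of the
  gradient-difference magnitude at two scales plus a DC (mean-difference)
  term — zero iff the inputs are identical, exactly linear under scaling of
  the output difference, and deterministic on CPU (a learned feature
  extractor can be plugged in).
* The discriminator is a 3-layer 3D patch network under the least-squares
  GAN objective; it is off (`w_adv = 0`) in the toy profile.
* In the decoder, level-transition convolutions run before each
  nearest-neighbour upsample (channel reduction at the coarser grid); the
  per-level channel ladder is unchanged. Residual and attention output
  layers are zero-initialized so blocks start as identities.
* Per-case seeds derive from the cohort seed by a fixed integer recurrence;
  every artifact embeds a configuration hash, and two runs with identical
  configuration and seeds are bit-identical.

## Problem sizes used by the test-suite

Stage-I recovery trains on 64 noiseless 32×32×16 phantoms (40 epochs) and
evaluates masked reconstruction MAE on 8 held-out cases. The end-to-end run
uses a 64-case noiseless cohort split 48/8/8, trains both stages at the toy
profile, synthesizes one PET per held-out CT under the ancestral sampler,
and compares masked MAE against the voxelwise mean of the training PETs
(the natural no-information baseline). The noiseless cohorts keep the
learning-signal comparison undiluted by voxel noise that would affect the
model and the baseline identically.

## Known limitations

* At the toy compression (3 latent channels, 8/16/16 ladder), focal lesions
  of one or two voxels fall below the representable detail scale of the
  autoencoder: they are smoothed away in reconstructions regardless of
  training length. Masked MAE is dominated by anatomy, so stage-I recovery
  and the end-to-end comparison remain meaningful, but lesion-level recall
  of the toy synthesis pipeline is near zero by construction. The full
  profile has 4× the channel capacity at 3× the resolution; this
  limitation is a property of the desk-scale configuration, not of the
  method's structure.
* One PET sample is generated per CT (fixed inference protocol); the
  conditional distribution is not otherwise explored (no uncertainty maps).
* The threshold-based lung segmenter assumes lung-like attenuation is
  present; on volumes without it, an external mask must be supplied.
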