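# Stage II: DDPM machinery in latent space — noise schedule, forward
# corruption, training objective, reverse sampling, and CT-condition
# assembly. Timesteps are 1-indexed externally with the convention
# alpha_bar_0 = 1, which makes the final (t = 1) reverse step well defined.

#' Build a scaled-linear DDPM noise schedule
#'
#' `sqrt(beta_t)` is affine in `t`:
#' `beta_t = (sqrt(beta_start) + (t-1)/(T-1) * (sqrt(beta_end) -
#' sqrt(beta_start)))^2`, so `beta_1 = beta_start` and `beta_T = beta_end`
#' exactly. `alpha_t = 1 - beta_t`, `alpha_bar_t = prod_{s<=t} alpha_s`.
#'
#' @param T_steps Number of timesteps (default 1000).
#' @param beta_start,beta_end Schedule endpoints (defaults 0.0015, 0.0195).
#' @param kind Schedule type; only `"scaled_linear"` is provided.
#' @return A `noise_schedule`: list with `T`, `beta`, `alpha`, `alpha_bar`.
#' @export
make_schedule <- function(T_steps = 1000L, beta_start = 0.0015,
                          beta_end = 0.0195, kind = "scaled_linear") {
  kind <- match.arg(kind, "scaled_linear")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("need 0 < beta_start <= beta_end < 1")
  T_steps <- as.integer(T_steps)
  if (T_steps < 1) stop("T must be >= 1")
  sqb <- if (T_steps == 1) sqrt(beta_start) else
    sqrt(beta_start) + (seq_len(T_steps) - 1) / (T_steps - 1) *
      (sqrt(beta_end) - sqrt(beta_start))
  beta <- sqb^2
  alpha <- 1 - beta
  structure(list(T = T_steps, beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "noise_schedule")
}

check_t <- function(t, s) {
  if (length(t) != 1 || t < 1 || t > s$T || t != round(t))
    stop("timestep t must be an integer in 1..", s$T)
  as.integer(t)
}

#' Forward diffusion: corrupt a clean latent at timestep t
#'
#' `z_t = sqrt(alpha_bar_t) * z0 + sqrt(1 - alpha_bar_t) * eps`. The
#' marginal variance of `z_t` is preserved for unit-variance `z0`.
#'
#' @param z0 Clean latent array.
#' @param t Timestep in 1..T.
#' @param eps Standard-normal draw, same shape as `z0`.
#' @param s A [make_schedule()] schedule.
#' @return Noisy latent `z_t`.
#' @export
forward_sample <- function(z0, t, eps, s) {
  t <- check_t(t, s)
  if (!identical(dim(z0), dim(eps)) && length(z0) != length(eps))
    stop("eps shape must match z0")
  ab <- s$alpha_bar[t]
  sqrt(ab) * z0 + sqrt(1 - ab) * eps
}

#' Noise-prediction training objective
#'
#' Mean squared error between predicted and true corruption noise.
#'
#' @param eps_pred,eps Arrays of identical shape.
#' @return Scalar MSE.
#' @export
training_loss <- function(eps_pred, eps) {
  if (length(eps_pred) != length(eps)) stop("shape mismatch")
  mean((eps_pred - eps)^2)
}

#' Reverse diffusion step, posterior-mean form
#'
#' `z_{t-1} = (z_t - (1 - alpha_t)/sqrt(1 - alpha_bar_t) * eps_pred) /
#' sqrt(alpha_t)`, with no stochastic term: the update is exactly the
#' posterior mean. With an oracle noise predictor the full chain t = T..1
#' inverts the forward mean process to machine precision.
#'
#' @param zt Latent at timestep `t`.
#' @param t Timestep in 1..T.
#' @param eps_pred Noise prediction.
#' @param s A [make_schedule()] schedule.
#' @return Latent at timestep `t - 1`.
#' @export
reverse_step_printed <- function(zt, t, eps_pred, s) {
  t <- check_t(t, s)
  (zt - (1 - s$alpha[t]) / sqrt(1 - s$alpha_bar[t]) * eps_pred) /
    sqrt(s$alpha[t])
}

#' Reverse diffusion step, ancestral (posterior-variance) form
#'
#' The posterior mean of [reverse_step_printed()] plus
#' `sqrt(beta_tilde_t) * noise` with
#' `beta_tilde_t = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t`
#' (and `alpha_bar_0 = 1`, so no noise is added at t = 1). This is the
#' standard DDPM ancestral sampler; `beta_tilde_t <= beta_t` for all t.
#'
#' @inheritParams reverse_step_printed
#' @param noise Standard-normal draw, same shape as `zt`.
#' @return Latent at timestep `t - 1`.
#' @export
reverse_step_ancestral <- function(zt, t, eps_pred, s, noise) {
  t <- check_t(t, s)
  mean_part <- reverse_step_printed(zt, t, eps_pred, s)
  if (t == 1) return(mean_part)
  ab_prev <- s$alpha_bar[t - 1]
  beta_tilde <- (1 - ab_prev) / (1 - s$alpha_bar[t]) * s$beta[t]
  mean_part + sqrt(beta_tilde) * noise
}

#' Assemble the CT conditioning tensor
#'
#' Default mode trilinearly downsamples the normalized CT to the latent
#' spatial grid (one channel, deterministic, no extra training). The
#' `"encoder"` mode instead encodes the CT with the stage-I encoder mean
#' (`latent_ch` channels).
#'
#' @param ct_norm Preprocessed, normalized CT ([volume3d()] or 3D array).
#' @param latent_spatial_shape Integer triple of the latent grid.
#' @param mode `"downsample"` or `"encoder"`.
#' @param vae Stage-I model, required for `mode = "encoder"`.
#' @return 4D condition array at latent resolution.
#' @export
make_condition <- function(ct_norm, latent_spatial_shape,
                           mode = c("downsample", "encoder"), vae = NULL) {
  mode <- match.arg(mode)
  x <- as_tensor3(ct_norm)
  if (mode == "encoder") {
    if (is.null(vae)) stop("encoder conditioning requires the stage-I model")
    return(vae_encode(vae, x)$mu)
  }
  shp <- as.integer(latent_spatial_shape)
  if (any(dim(x) %% shp != 0))
    stop("latent spatial shape must divide the input shape")
  out <- cpp_resample3d(x, c(1, 1, 1), shp, dim(x) / shp, 0L)
  dim(out) <- c(shp, 1L)
  out
}

#' Sample a synthetic PET volume for one CT
#'
#' Starts from seeded Gaussian noise `z_T`, runs the reverse chain t = T..1
#' with the chosen step rule (condition concatenated at every denoiser
#' call), decodes the final latent with the stage-I decoder and clips the
#' result to non-negative SUV. Bit-identical output under a fixed seed.
#'
#' @param dn Trained [denoiser_init()] model.
#' @param ct_norm Preprocessed normalized CT.
#' @param s Noise schedule.
#' @param vae Trained stage-I model.
#' @param scale Latent standardization (`scale_meta`: list with `center`
#'   field and per-channel `scale`); inverted before decoding. `NULL` for
#'   identity.
#' @param mode `"ancestral"` (default) or `"printed"` reverse step.
#' @param seed Integer seed for `z_T` and the ancestral noise stream.
#' @param cond_mode Condition assembly mode, see [make_condition()].
#' @return A `"PET-SUV"` [volume3d()] (geometry copied from `ct_norm` when
#'   available, else unit spacing).
#' @export
sample_pet <- function(dn, ct_norm, s, vae, scale = NULL,
                       mode = c("ancestral", "printed"), seed = 1L,
                       cond_mode = "downsample") {
  mode <- match.arg(mode)
  x <- as_tensor3(ct_norm)
  latent_shape <- dim(x) %/% 4L
  cond <- make_condition(x, latent_shape, cond_mode, vae)
  L <- dn$cfg$latent_ch
  with_seed(seed, {
    z <- array(rnorm(prod(latent_shape) * L), c(latent_shape, L))
    for (t in seq(s$T, 1)) {
      eps_pred <- predict_noise(dn, z, t, cond)
      z <- if (mode == "printed") reverse_step_printed(z, t, eps_pred, s)
      else reverse_step_ancestral(z, t, eps_pred, s,
                                  array(rnorm(length(z)), dim(z)))
    }
    if (!is.null(scale)) z <- latent_destandardize(z, scale)
    y <- vae_decode(vae, z)
    y <- pmax(y, 0)
    sp <- if (inherits(ct_norm, "volume3d")) vol_spacing(ct_norm) else c(1, 1, 1)
    volume3d(array(y, dim(x)), sp, "RAS", "PET-SUV")
  })
}
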