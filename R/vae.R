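# Stage I: KL-regularized 3D variational autoencoder compressing PET volumes
# into the latent space used by diffusion. Two stride-2 stages give a 4x
# spatial reduction per axis (96x96x64 -> 24x24x16 at the full profile); the
# latent has 3 channels. SiLU activations throughout, no final decoder
# activation so SUV values are regressed directly. In the decoder the
# level-transition convolutions run before each nearest-neighbour upsample
# (channel reduction at the coarser grid), keeping the per-level channel
# ladder while avoiding wide convolutions at full resolution.

as_tensor4 <- function(v) {
  if (inherits(v, "volume3d") || inherits(v, "mask3d"))
    v <- array(as.numeric(v), dim(v))
  if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L)
  v
}

#' Initialize a PET autoencoder
#'
#' @param ch Feature channel ladder (three entries; the stated architecture
#'   uses `c(32, 64, 64)`, the desk-scale test profile `c(8, 16, 16)`).
#' @param latent_ch Latent channels (default 3).
#' @param in_ch Input channels (1 for a PET volume).
#' @return A `vae` object (parameters + config). Initialization draws from
#'   the caller's RNG stream.
#' @export
vae_init <- function(ch = c(32, 64, 64), latent_ch = 3L, in_ch = 1L) {
  stopifnot(length(ch) == 3L)
  params <- list(
    e1 = nn_conv_init(in_ch, ch[1], stride = 1),
    e2 = nn_conv_init(ch[1], ch[2], stride = 2),
    e3 = nn_conv_init(ch[2], ch[3], stride = 2),
    e4 = nn_conv_init(ch[3], 2L * latent_ch, stride = 1),
    d1 = nn_conv_init(latent_ch, ch[3], stride = 1),
    d2 = nn_conv_init(ch[3], ch[2], stride = 1),
    d2b = nn_conv_init(ch[2], ch[2], stride = 1),
    d3 = nn_conv_init(ch[2], ch[1], stride = 1),
    d4 = nn_conv_init(ch[1], in_ch, stride = 1)
  )
  structure(list(params = params,
                 cfg = list(ch = ch, latent_ch = as.integer(latent_ch),
                            in_ch = as.integer(in_ch))),
            class = "vae")
}

#' Encode a PET volume into latent mean and scale
#'
#' The encoder predicts per-element mean and log-variance of the Gaussian
#' latent posterior; `sigma = exp(logvar / 2)` is strictly positive by
#' construction.
#'
#' @param vae A [vae_init()] model.
#' @param y PET volume (3D array / [volume3d()]).
#' @param train Keep forward caches for backprop.
#' @return List with `mu`, `sigma`, `logvar` (4D arrays, `latent_ch`
#'   channels) and, when `train = TRUE`, a `cache`.
#' @export
vae_encode <- function(vae, y, train = FALSE) {
  x <- as_tensor4(y)
  if (any(dim(x)[1:3] %% 4L != 0))
    stop("input dimensions must be divisible by 4 (two stride-2 stages)")
  p <- vae$params
  c1 <- conv_fwd(p$e1, x);  a1 <- silu_fwd(c1$y)
  c2 <- conv_fwd(p$e2, a1$y); a2 <- silu_fwd(c2$y)
  c3 <- conv_fwd(p$e3, a2$y); a3 <- silu_fwd(c3$y)
  c4 <- conv_fwd(p$e4, a3$y)
  L <- vae$cfg$latent_ch
  mu <- c4$y[, , , seq_len(L), drop = FALSE]
  logvar <- c4$y[, , , L + seq_len(L), drop = FALSE]
  out <- list(mu = mu, logvar = logvar, sigma = exp(logvar / 2))
  if (train) out$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                               c3 = c3, a3 = a3, c4 = c4)
  out
}

vae_encode_bwd <- function(vae, cache, dmu, dlogvar) {
  p <- vae$params
  gy <- array(0, dim(cache$c4$y))
  L <- vae$cfg$latent_ch
  gy[, , , seq_len(L)] <- dmu
  gy[, , , L + seq_len(L)] <- dlogvar
  b4 <- conv_bwd(p$e4, cache$c4$x, gy)
  g <- silu_bwd(cache$a3, b4$gx)
  b3 <- conv_bwd(p$e3, cache$c3$x, g)
  g <- silu_bwd(cache$a2, b3$gx)
  b2 <- conv_bwd(p$e2, cache$c2$x, g)
  g <- silu_bwd(cache$a1, b2$gx)
  b1 <- conv_bwd(p$e1, cache$c1$x, g)
  list(gx = b1$gx,
       grads = list(e1 = b1$grads, e2 = b2$grads, e3 = b3$grads, e4 = b4$grads))
}

#' Draw a latent sample by the reparameterization trick
#'
#' `z = mu + sigma * eps`, elementwise.
#'
#' @param out An encoder output (list with `mu` and `sigma`).
#' @param noise Standard-normal draw with the shape of `mu`.
#' @return Latent array `z`.
#' @export
reparameterize <- function(out, noise) {
  if (!identical(dim(out$mu), dim(noise))) stop("noise shape must match mu")
  out$mu + out$sigma * noise
}

#' Decode a latent tensor to a PET volume
#'
#' No final activation: SUV values are regressed directly and may be
#' negative; clip at export/evaluation time.
#'
#' @param vae A [vae_init()] model.
#' @param z Latent 4D array.
#' @param train Keep forward caches.
#' @return 3D array of PET values (plus `cache` when training, as a list).
#' @export
vae_decode <- function(vae, z, train = FALSE) {
  p <- vae$params
  c1 <- conv_fwd(p$d1, z); a1 <- silu_fwd(c1$y)
  u1 <- upsample_nearest2_fwd(a1$y)
  c2 <- conv_fwd(p$d2, u1); a2 <- silu_fwd(c2$y)
  c2b <- conv_fwd(p$d2b, a2$y); a2b <- silu_fwd(c2b$y)
  c3 <- conv_fwd(p$d3, a2b$y); a3 <- silu_fwd(c3$y)
  u2 <- upsample_nearest2_fwd(a3$y)
  c4 <- conv_fwd(p$d4, u2)
  y <- c4$y
  if (dim(y)[4] == 1L) dim(y) <- dim(y)[1:3]
  if (!train) return(y)
  list(y = y, cache = list(c1 = c1, a1 = a1, dim1 = dim(a1$y), c2 = c2,
                           a2 = a2, c2b = c2b, a2b = a2b, c3 = c3, a3 = a3,
                           dim3 = dim(a3$y), c4 = c4))
}

vae_decode_bwd <- function(vae, cache, gy) {
  p <- vae$params
  if (length(dim(gy)) == 3L) dim(gy) <- c(dim(gy), 1L)
  b4 <- conv_bwd(p$d4, cache$c4$x, gy)
  g <- upsample_nearest2_bwd(b4$gx, cache$dim3)
  g <- silu_bwd(cache$a3, g)
  b3 <- conv_bwd(p$d3, cache$c3$x, g)
  g <- silu_bwd(cache$a2b, b3$gx)
  b2b <- conv_bwd(p$d2b, cache$c2b$x, g)
  g <- silu_bwd(cache$a2, b2b$gx)
  b2 <- conv_bwd(p$d2, cache$c2$x, g)
  g <- upsample_nearest2_bwd(b2$gx, cache$dim1)
  g <- silu_bwd(cache$a1, g)
  b1 <- conv_bwd(p$d1, cache$c1$x, g)
  list(gz = b1$gx,
       grads = list(d1 = b1$grads, d2 = b2$grads, d2b = b2b$grads,
                    d3 = b3$grads, d4 = b4$grads))
}

#' KL divergence of the latent posterior from a unit Gaussian
#'
#' `0.5 * sum(mu^2 + sigma^2 - log(sigma^2) - 1)`, summed over latent
#' elements of one sample (batch handling: mean over samples, applied by the
#' training loop). Non-negative, zero exactly at `mu = 0, sigma = 1`.
#'
#' @param out Encoder output with `mu` and `logvar` (or `sigma`).
#' @return Scalar KL value.
#' @export
kl_loss <- function(out) {
  logvar <- out$logvar %||% log(out$sigma^2)
  0.5 * sum(out$mu^2 + exp(logvar) - logvar - 1)
}

kl_grads <- function(out) {
  logvar <- out$logvar %||% log(out$sigma^2)
  list(dmu = out$mu, dlogvar = 0.5 * (exp(logvar) - 1))
}

#' L1 reconstruction loss
#'
#' Mean absolute difference over all voxels.
#'
#' @param y,y_hat Arrays of identical shape.
#' @return Scalar.
#' @export
recon_loss <- function(y, y_hat) {
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch")
  mean(abs(y - y_hat))
}

recon_grad <- function(y, y_hat) {
  sign(y_hat - y) / length(y)
}

# forward differences along each axis, same-size (last plane zero)
grad3 <- function(v) {
  d <- dim(v)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[-d[1], , ] <- v[-1, , ] - v[-d[1], , ]
  gy[, -d[2], ] <- v[, -1, ] - v[, -d[2], ]
  gz[, , -d[3]] <- v[, , -1] - v[, , -d[3]]
  list(gx = gx, gy = gy, gz = gz)
}

grad3_transpose <- function(g) {
  # adjoint of grad3: scatter each difference back onto its two voxels
  d <- dim(g$gx)
  out <- array(0, d)
  out[-1, , ] <- out[-1, , ] + g$gx[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] - g$gx[-d[1], , ]
  out[, -1, ] <- out[, -1, ] + g$gy[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] - g$gy[, -d[2], ]
  out[, , -1] <- out[, , -1] + g$gz[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] - g$gz[, , -d[3]]
  out
}

perc_scale_terms <- function(y, yh, eps = 1e-12) {
  gy <- grad3(y); gh <- grad3(yh)
  dx <- gy$gx - gh$gx; dy <- gy$gy - gh$gy; dz <- gy$gz - gh$gz
  mag <- sqrt(dx^2 + dy^2 + dz^2 + eps^2)
  list(loss = mean(mag), dx = dx, dy = dy, dz = dz, mag = mag)
}

#' Analytic perceptual loss (multi-scale gradient-difference magnitude)
#'
#' A fixed feature operator: the L1 average of the magnitude of the spatial
#' gradient-difference vector between the two volumes, computed at full
#' resolution and after 2x average pooling, plus a DC (global mean
#' difference) term. It is zero iff the inputs are identical, scales
#' linearly when the output difference is scaled, and being analytic keeps
#' training fully deterministic on CPU. A learned feature extractor can be
#' plugged in via `operator`.
#'
#' @param y,y_hat Arrays of identical shape (3D).
#' @param operator Optional replacement `function(y, y_hat) -> scalar`.
#' @return Scalar loss (>= 0).
#' @export
perceptual_loss <- function(y, y_hat, operator = NULL) {
  if (!is.null(operator)) return(operator(y, y_hat))
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  if (!identical(dim(y), dim(y_hat))) stop("shape mismatch")
  s1 <- perc_scale_terms(y, y_hat)$loss
  s2 <- perc_scale_terms(avgpool2_fwd(y), avgpool2_fwd(y_hat))$loss
  0.5 * (s1 + s2) + abs(mean(y) - mean(y_hat))
}

perceptual_grad <- function(y, y_hat) {
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  t1 <- perc_scale_terms(y, y_hat)
  g1 <- grad3_transpose(list(gx = -t1$dx / t1$mag / length(t1$mag),
                             gy = -t1$dy / t1$mag / length(t1$mag),
                             gz = -t1$dz / t1$mag / length(t1$mag)))
  yp <- avgpool2_fwd(y); yhp <- avgpool2_fwd(y_hat)
  t2 <- perc_scale_terms(yp, yhp)
  g2s <- grad3_transpose(list(gx = -t2$dx / t2$mag / length(t2$mag),
                              gy = -t2$dy / t2$mag / length(t2$mag),
                              gz = -t2$dz / t2$mag / length(t2$mag)))
  g2 <- avgpool2_bwd(g2s, dim(y))
  gdc <- array(-sign(mean(y) - mean(y_hat)) / length(y), dim(y))
  0.5 * (g1 + g2) + gdc
}

as_tensor3 <- function(v) {
  if (inherits(v, "volume3d")) v <- array(as.numeric(v), dim(v))
  if (length(dim(v)) == 4L && dim(v)[4] == 1L) dim(v) <- dim(v)[1:3]
  v
}

#' Initialize a 3D patch discriminator
#'
#' Three stride-2/1 convolution layers with SiLU activations producing a
#' patch map of realness scores; used with the least-squares GAN objective.
#' Disabled entirely when the adversarial weight is zero.
#'
#' @param ch Two hidden channel counts.
#' @return A `discriminator` object.
#' @export
disc_init <- function(ch = c(8, 16)) {
  structure(list(params = list(
    c1 = nn_conv_init(1L, ch[1], stride = 2),
    c2 = nn_conv_init(ch[1], ch[2], stride = 2),
    c3 = nn_conv_init(ch[2], 1L, stride = 1)
  )), class = "discriminator")
}

disc_fwd <- function(disc, x, train = FALSE) {
  p <- disc$params
  x <- as_tensor4(x)
  c1 <- conv_fwd(p$c1, x); a1 <- silu_fwd(c1$y)
  c2 <- conv_fwd(p$c2, a1$y); a2 <- silu_fwd(c2$y)
  c3 <- conv_fwd(p$c3, a2$y)
  if (!train) return(c3$y)
  list(y = c3$y, cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3))
}

disc_bwd <- function(disc, cache, gy) {
  p <- disc$params
  b3 <- conv_bwd(p$c3, cache$c3$x, gy)
  g <- silu_bwd(cache$a2, b3$gx)
  b2 <- conv_bwd(p$c2, cache$c2$x, g)
  g <- silu_bwd(cache$a1, b2$gx)
  b1 <- conv_bwd(p$c1, cache$c1$x, g)
  list(gx = b1$gx, grads = list(c1 = b1$grads, c2 = b2$grads, c3 = b3$grads))
}

#' Least-squares GAN terms for the autoencoder and discriminator
#'
#' Generator term: `mean((D(y_hat) - 1)^2)`; discriminator term:
#' `0.5 * (mean((D(y) - 1)^2) + mean(D(y_hat)^2))`. A discriminator that
#' outputs a constant 1/2 yields 1/4 for both.
#'
#' @param y,y_hat Real and reconstructed volumes (same shape).
#' @param disc A [disc_init()] discriminator.
#' @return List with `gen_term` and `disc_term`.
#' @export
adversarial_losses <- function(y, y_hat, disc) {
  d_real <- disc_fwd(disc, y)
  d_fake <- disc_fwd(disc, y_hat)
  list(gen_term = mean((d_fake - 1)^2),
       disc_term = 0.5 * (mean((d_real - 1)^2) + mean(d_fake^2)))
}

# gradient of the generator term w.r.t. y_hat
adversarial_gen_grad <- function(y_hat, disc) {
  f <- disc_fwd(disc, y_hat, train = TRUE)
  gd <- 2 * (f$y - 1) / length(f$y)
  g <- disc_bwd(disc, f$cache, gd)$gx
  if (dim(g)[4] == 1L) dim(g) <- dim(g)[1:3]
  g
}

# discriminator parameter gradients for one (real, fake) pair
adversarial_disc_grads <- function(y, y_hat, disc) {
  fr <- disc_fwd(disc, y, train = TRUE)
  ff <- disc_fwd(disc, y_hat, train = TRUE)
  gr <- disc_bwd(disc, fr$cache, (fr$y - 1) / length(fr$y))$grads
  gf <- disc_bwd(disc, ff$cache, ff$y / length(ff$y))$grads
  tree_add(gr, gf)
}

#' Composite autoencoder objective
#'
#' `recon + w_kl * kl + w_p * perceptual + w_adv * adversarial`.
#'
#' @param terms List with `recon`, `kl`, `perceptual`, `adversarial`
#'   (missing terms count as 0).
#' @param weights List with `w_kl`, `w_p`, `w_adv` (defaults 1e-6, 0.001,
#'   0.01).
#' @return Scalar total loss.
#' @export
total_vae_loss <- function(terms,
                           weights = list(w_kl = 1e-6, w_p = 0.001,
                                          w_adv = 0.01)) {
  (terms$recon %||% 0) +
    weights$w_kl * (terms$kl %||% 0) +
    weights$w_p * (terms$perceptual %||% 0) +
    weights$w_adv * (terms$adversarial %||% 0)
}
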