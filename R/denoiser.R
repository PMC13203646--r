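# Conditional 3D diffusion U-Net predicting the corrupting noise
# eps_theta(z_t, t, c(x)). Composition per level: one residual block
# (GroupNorm + SiLU + 3x3x3 conv, time embedding added between convs),
# single-head self-attention at the two deepest levels, stride-2 conv
# downsampling and nearest-upsample + conv upsampling, additive skip
# connections at matching resolutions.

#' Sinusoidal timestep embedding
#'
#' Standard sin/cos positional features of an (integer) diffusion timestep.
#' The embedding norm is bounded by `sqrt(dim)`.
#'
#' @param t Timestep (>= 1).
#' @param dim Even embedding dimension.
#' @return Numeric vector of length `dim`.
#' @export
timestep_embedding <- function(t, dim) {
  if (dim %% 2 != 0) stop("embedding dim must be even")
  half <- dim %/% 2
  freqs <- if (half > 1) exp(-log(10000) * (0:(half - 1)) / (half - 1)) else 1
  c(sin(t * freqs), cos(t * freqs))
}

rb_init <- function(C, temb_dim, groups = 4L) {
  list(gn1 = nn_gn_init(C, groups),
       conv1 = nn_conv_init(C, C),
       temb = nn_lin_init(temb_dim, C),
       gn2 = nn_gn_init(C, groups),
       conv2 = nn_conv_init(C, C, zero = TRUE))  # block starts as identity
}

rb_fwd <- function(p, x, temb) {
  g1 <- gn_fwd(p$gn1, x); s1 <- silu_fwd(g1$y)
  c1 <- conv_fwd(p$conv1, s1$y)
  tp <- lin_fwd(p$temb, temb)
  h <- c1$y + rep(tp, each = prod(dim(c1$y)[1:3]))
  g2 <- gn_fwd(p$gn2, h); s2 <- silu_fwd(g2$y)
  c2 <- conv_fwd(p$conv2, s2$y)
  list(y = x + c2$y,
       cache = list(g1 = g1, s1 = s1, c1 = c1, g2 = g2, s2 = s2, c2 = c2))
}

rb_bwd <- function(p, cache, gy, temb) {
  b2 <- conv_bwd(p$conv2, cache$c2$x, gy)
  g <- silu_bwd(cache$s2, b2$gx)
  n2 <- gn_bwd(p$gn2, cache$g2, g)
  gh <- n2$gx
  gtp <- colSums(matrix(gh, ncol = dim(gh)[4]))
  lb <- lin_bwd(p$temb, temb, gtp)
  b1 <- conv_bwd(p$conv1, cache$c1$x, gh)
  g <- silu_bwd(cache$s1, b1$gx)
  n1 <- gn_bwd(p$gn1, cache$g1, g)
  list(gx = gy + n1$gx, gtemb = lb$gv,
       grads = list(gn1 = n1$grads, conv1 = b1$grads, temb = lb$grads,
                    gn2 = n2$grads, conv2 = b2$grads))
}

#' Initialize the conditional diffusion U-Net
#'
#' @param ch Feature channel ladder (three levels; stated architecture
#'   `c(32, 64, 64)`, desk-scale test profile `c(8, 16, 16)`).
#' @param latent_ch Latent (output) channels.
#' @param cond_ch Condition channels concatenated onto the latent input
#'   (1 for a downsampled CT, `latent_ch` for encoder-based conditioning).
#' @param temb_dim Time-embedding dimension (even).
#' @param groups GroupNorm groups (must divide every channel count).
#' @return A `denoiser` object. Attention is enabled exactly at the two
#'   deepest levels.
#' @export
denoiser_init <- function(ch = c(32, 64, 64), latent_ch = 3L, cond_ch = 1L,
                          temb_dim = 32L, groups = 4L) {
  stopifnot(length(ch) == 3L, temb_dim %% 2 == 0)
  in_ch <- latent_ch + cond_ch
  params <- list(
    t1 = nn_lin_init(temb_dim, temb_dim),
    t2 = nn_lin_init(temb_dim, temb_dim),
    conv_in = nn_conv_init(in_ch, ch[1]),
    rb1 = rb_init(ch[1], temb_dim, groups),
    down1 = nn_conv_init(ch[1], ch[2], stride = 2),
    rb2 = rb_init(ch[2], temb_dim, groups),
    attn2 = nn_attn_init(ch[2], groups),
    down2 = nn_conv_init(ch[2], ch[3], stride = 2),
    rb3 = rb_init(ch[3], temb_dim, groups),
    attn3 = nn_attn_init(ch[3], groups),
    up1 = nn_conv_init(ch[3], ch[2]),
    rb4 = rb_init(ch[2], temb_dim, groups),
    attn4 = nn_attn_init(ch[2], groups),
    up2 = nn_conv_init(ch[2], ch[1]),
    rb5 = rb_init(ch[1], temb_dim, groups),
    gn_out = nn_gn_init(ch[1], groups),
    conv_out = nn_conv_init(ch[1], latent_ch, zero = TRUE)
  )
  structure(list(params = params,
                 cfg = list(ch = ch, latent_ch = as.integer(latent_ch),
                            cond_ch = as.integer(cond_ch),
                            temb_dim = as.integer(temb_dim),
                            groups = as.integer(groups),
                            attention = c(FALSE, TRUE, TRUE))),
            class = "denoiser")
}

#' Predict the corrupting noise for a noisy latent
#'
#' @param dn A [denoiser_init()] model.
#' @param zt Noisy latent, 4D array (`latent_ch` channels).
#' @param t Timestep (1..T).
#' @param cond Condition tensor at latent spatial resolution (`cond_ch`
#'   channels).
#' @param train Keep forward caches for backprop.
#' @return Latent-shaped noise prediction (plus `cache` when training).
#' @export
predict_noise <- function(dn, zt, t, cond, train = FALSE) {
  p <- dn$params
  if (t < 1) stop("timestep must be >= 1")
  dz <- dim(zt); dc <- dim(cond)
  if (!identical(dz[1:3], dc[1:3]))
    stop("condition spatial shape must equal the latent spatial shape")
  if (any(dz[1:3] %% 4L != 0))
    stop("latent spatial dimensions must be divisible by 4 (two stride-2 levels)")
  x <- array(c(zt, cond), c(dz[1:3], dz[4] + dc[4]))
  e0 <- timestep_embedding(t, dn$cfg$temb_dim)
  h1v <- lin_fwd(p$t1, e0); h1s <- silu_fwd(h1v)
  temb <- lin_fwd(p$t2, h1s$y)

  cin <- conv_fwd(p$conv_in, x)
  r1 <- rb_fwd(p$rb1, cin$y, temb)
  dn1 <- conv_fwd(p$down1, r1$y)
  r2 <- rb_fwd(p$rb2, dn1$y, temb)
  a2 <- attn_fwd(p$attn2, r2$y)
  dn2 <- conv_fwd(p$down2, a2$y)
  r3 <- rb_fwd(p$rb3, dn2$y, temb)
  a3 <- attn_fwd(p$attn3, r3$y)
  u1c <- upsample_nearest2_fwd(a3$y)
  up1 <- conv_fwd(p$up1, u1c)
  s1 <- up1$y + a2$y
  r4 <- rb_fwd(p$rb4, s1, temb)
  a4 <- attn_fwd(p$attn4, r4$y)
  u2c <- upsample_nearest2_fwd(a4$y)
  up2 <- conv_fwd(p$up2, u2c)
  s2 <- up2$y + r1$y
  r5 <- rb_fwd(p$rb5, s2, temb)
  go <- gn_fwd(p$gn_out, r5$y)
  so <- silu_fwd(go$y)
  out <- conv_fwd(p$conv_out, so$y)
  if (!train) return(out$y)
  list(y = out$y,
       cache = list(e0 = e0, h1v = h1v, h1s = h1s, temb = temb, cin = cin,
                    r1 = r1, dn1 = dn1, r2 = r2, a2 = a2, dn2 = dn2, r3 = r3,
                    a3 = a3, dim_a3 = dim(a3$y), up1 = up1, r4 = r4, a4 = a4,
                    dim_a4 = dim(a4$y), up2 = up2, r5 = r5, go = go, so = so,
                    out = out, in_dims = c(dz[4], dc[4])))
}

predict_noise_bwd <- function(dn, cache, gy) {
  p <- dn$params
  temb <- cache$temb
  gtemb <- numeric(length(temb))

  bo <- conv_bwd(p$conv_out, cache$out$x, gy)
  g <- silu_bwd(cache$so, bo$gx)
  ngo <- gn_bwd(p$gn_out, cache$go, g)
  b5 <- rb_bwd(p$rb5, cache$r5$cache, ngo$gx, temb); gtemb <- gtemb + b5$gtemb
  g_s2 <- b5$gx                     # splits to up2 and skip r1
  bu2 <- conv_bwd(p$up2, cache$up2$x, g_s2)
  g <- upsample_nearest2_bwd(bu2$gx, cache$dim_a4)
  ba4 <- attn_bwd(p$attn4, cache$a4, g)
  b4 <- rb_bwd(p$rb4, cache$r4$cache, ba4$gx, temb); gtemb <- gtemb + b4$gtemb
  g_s1 <- b4$gx                     # splits to up1 and skip a2
  bu1 <- conv_bwd(p$up1, cache$up1$x, g_s1)
  g <- upsample_nearest2_bwd(bu1$gx, cache$dim_a3)
  ba3 <- attn_bwd(p$attn3, cache$a3, g)
  b3 <- rb_bwd(p$rb3, cache$r3$cache, ba3$gx, temb); gtemb <- gtemb + b3$gtemb
  bd2 <- conv_bwd(p$down2, cache$dn2$x, b3$gx)
  ba2 <- attn_bwd(p$attn2, cache$a2, bd2$gx + g_s1)   # skip gradient joins
  b2 <- rb_bwd(p$rb2, cache$r2$cache, ba2$gx, temb); gtemb <- gtemb + b2$gtemb
  bd1 <- conv_bwd(p$down1, cache$dn1$x, b2$gx)
  b1 <- rb_bwd(p$rb1, cache$r1$cache, bd1$gx + g_s2, temb)
  gtemb <- gtemb + b1$gtemb
  bin <- conv_bwd(p$conv_in, cache$cin$x, b1$gx)

  lb2 <- lin_bwd(p$t2, cache$h1s$y, gtemb)
  gh1 <- silu_bwd(cache$h1s, lb2$gv)
  lb1 <- lin_bwd(p$t1, cache$e0, gh1)

  nl <- cache$in_dims[1]
  gin <- bin$gx
  list(gzt = gin[, , , seq_len(nl), drop = FALSE],
       gcond = gin[, , , nl + seq_len(cache$in_dims[2]), drop = FALSE],
       grads = list(t1 = lb1$grads, t2 = lb2$grads, conv_in = bin$grads,
                    rb1 = b1$grads, down1 = bd1$grads, rb2 = b2$grads,
                    attn2 = ba2$grads, down2 = bd2$grads, rb3 = b3$grads,
                    attn3 = ba3$grads, up1 = bu1$grads, rb4 = b4$grads,
                    attn4 = ba4$grads, up2 = bu2$grads, rb5 = b5$grads,
                    gn_out = ngo$grads, conv_out = bo$grads))
}
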