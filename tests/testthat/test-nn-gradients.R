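# Finite-difference verification of the hand-written backward passes on
# tiny tensors. Each block perturbs a handful of randomly chosen parameter
# and input entries and compares against central differences.

pl <- asNamespace("petldm")

expect_close_grad <- function(analytic, numeric, tol = 1e-4) {
  rel <- abs(analytic - numeric) /
    pmax(1e-8, pmax(abs(analytic), abs(numeric)))
  expect_lt(max(rel), tol)
}

test_that("conv3d backward matches finite differences (weights, bias, input)", {
  set.seed(11)
  for (stride in c(1L, 2L)) {
    x <- array(rnorm(5 * 5 * 4 * 2), c(5, 5, 4, 2))
    p <- pl$nn_conv_init(2, 3, stride = stride)
    f <- pl$conv_fwd(p, x)
    wmask <- array(rnorm(length(f$y)), dim(f$y))
    b <- pl$conv_bwd(p, x, wmask)
    loss_w <- function(w) { p2 <- p; p2$w <- w
      sum(pl$conv_fwd(p2, x)$y * wmask) }
    idx <- sample(length(p$w), 6)
    expect_close_grad(b$grads$w[idx], fd_grad(loss_w, p$w, idx))
    loss_x <- function(xx) sum(pl$conv_fwd(p, xx)$y * wmask)
    idx <- sample(length(x), 6)
    expect_close_grad(b$gx[idx], fd_grad(loss_x, x, idx))
    expect_equal(b$grads$b, apply(wmask, 4, sum), tolerance = 1e-10)
  }
})

test_that("group norm backward matches finite differences", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 3 * 8), c(4, 4, 3, 8))
  p <- pl$nn_gn_init(8, 4)
  p$gamma <- runif(8, 0.5, 1.5); p$beta <- rnorm(8)
  f <- pl$gn_fwd(p, x)
  wm <- array(rnorm(length(f$y)), dim(f$y))
  b <- pl$gn_bwd(p, f, wm)
  loss_x <- function(xx) sum(pl$gn_fwd(p, xx)$y * wm)
  idx <- sample(length(x), 8)
  expect_close_grad(b$gx[idx], fd_grad(loss_x, x, idx))
  loss_g <- function(g) { p2 <- p; p2$gamma <- g; sum(pl$gn_fwd(p2, x)$y * wm) }
  expect_close_grad(b$grads$gamma, fd_grad(loss_g, p$gamma, 1:8))
})

test_that("attention backward matches finite differences", {
  set.seed(13)
  x <- array(rnorm(3 * 3 * 2 * 8), c(3, 3, 2, 8))
  p <- pl$nn_attn_init(8, 4)
  p$wo <- matrix(rnorm(64, sd = 0.3), 8, 8)  # non-zero so gradients flow
  f <- pl$attn_fwd(p, x)
  wm <- array(rnorm(length(f$y)), dim(f$y))
  b <- pl$attn_bwd(p, f, wm)
  for (nm in c("wq", "wk", "wv", "wo")) {
    loss_p <- function(w) { p2 <- p; p2[[nm]] <- w
      sum(pl$attn_fwd(p2, x)$y * wm) }
    idx <- sample(length(p[[nm]]), 4)
    expect_close_grad(b$grads[[nm]][idx], fd_grad(loss_p, p[[nm]], idx))
  }
  loss_x <- function(xx) sum(pl$attn_fwd(p, xx)$y * wm)
  idx <- sample(length(x), 6)
  expect_close_grad(b$gx[idx], fd_grad(loss_x, x, idx))
})

test_that("full denoiser backward matches finite differences", {
  set.seed(14)
  dn <- denoiser_init(c(8, 16, 16), 3, 1, 16, 4)
  # perturb the zero-initialized layers so every path carries gradient
  rnd <- function(a, sd) array(rnorm(length(a), sd = sd), dim(a))
  dn$params$conv_out$w <- rnd(dn$params$conv_out$w, 0.05)
  for (rb in c("rb1", "rb2", "rb3", "rb4", "rb5"))
    dn$params[[rb]]$conv2$w <- rnd(dn$params[[rb]]$conv2$w, 0.05)
  for (at in c("attn2", "attn3", "attn4"))
    dn$params[[at]]$wo <- matrix(rnorm(length(dn$params[[at]]$wo), sd = 0.1),
                                 nrow(dn$params[[at]]$wo))
  zt <- array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  cond <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  f <- predict_noise(dn, zt, 7, cond, train = TRUE)
  wm <- array(rnorm(length(f$y)), dim(f$y))
  b <- pl$predict_noise_bwd(dn, f$cache, wm)
  for (leaf in list(c("conv_in", "w"), c("down1", "w"), c("up2", "w"),
                    c("t2", "w"))) {
    g_an <- b$grads[[leaf[1]]][[leaf[2]]]
    loss_p <- function(w) {
      d2 <- dn; d2$params[[leaf[1]]][[leaf[2]]] <- w
      sum(predict_noise(d2, zt, 7, cond) * wm)
    }
    idx <- sample(length(g_an), 3)
    expect_close_grad(g_an[idx],
                      fd_grad(loss_p, dn$params[[leaf[1]]][[leaf[2]]], idx),
                      tol = 5e-3)
  }
  loss_z <- function(z) sum(predict_noise(dn, z, 7, cond) * wm)
  idx <- sample(length(zt), 4)
  expect_close_grad(b$gzt[idx], fd_grad(loss_z, zt, idx), tol = 1e-3)
})

test_that("VAE encoder/decoder backward match finite differences", {
  set.seed(15)
  v <- vae_init(c(8, 16, 16), 3)
  y <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  enc <- vae_encode(v, y, train = TRUE)
  dmu <- array(rnorm(length(enc$mu)), dim(enc$mu))
  dlv <- array(rnorm(length(enc$mu)), dim(enc$mu))
  eb <- pl$vae_encode_bwd(v, enc$cache, dmu, dlv)
  loss_e <- function(w) {
    v2 <- v; v2$params$e2$w <- w
    e <- vae_encode(v2, y)
    sum(e$mu * dmu) + sum(e$logvar * dlv)
  }
  idx <- sample(length(v$params$e2$w), 4)
  expect_close_grad(eb$grads$e2$w[idx], fd_grad(loss_e, v$params$e2$w, idx))

  z <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  dec <- vae_decode(v, z, train = TRUE)
  wm <- array(rnorm(length(dec$y)), dim(dec$y))
  db <- pl$vae_decode_bwd(v, dec$cache, wm)
  loss_d <- function(w) { v2 <- v; v2$params$d2b$w <- w
    sum(vae_decode(v2, z) * wm) }
  idx <- sample(length(v$params$d2b$w), 4)
  expect_close_grad(db$grads$d2b$w[idx], fd_grad(loss_d, v$params$d2b$w, idx))
  loss_z <- function(zz) sum(vae_decode(v, zz) * wm)
  idx <- sample(length(z), 4)
  expect_close_grad(db$gz[idx], fd_grad(loss_z, z, idx))
})

test_that("perceptual and adversarial generator gradients match finite differences", {
  set.seed(16)
  y <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  yh <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  g <- pl$perceptual_grad(y, yh)
  loss <- function(h) perceptual_loss(y, h)
  idx <- sample(length(yh), 6)
  expect_close_grad(g[idx], fd_grad(loss, yh, idx), tol = 1e-3)

  d <- disc_init()
  yh2 <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  g2 <- pl$adversarial_gen_grad(yh2, d)
  loss2 <- function(h) adversarial_losses(array(0, dim(h)), h, d)$gen_term
  idx <- sample(length(yh2), 4)
  expect_close_grad(g2[idx], fd_grad(loss2, yh2, idx), tol = 1e-3)
})
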