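# Minimal dense 3D neural-network layers with explicit forward/backward
# passes. Activations are (X, Y, Z, C) arrays; a batch is a list of such
# arrays. Parameters live in nested named lists of numeric arrays so the
# optimizer can walk them generically. All initializers draw from the
# caller's RNG stream, keeping whole-network initialization seedable.

nn_conv_init <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = 1L,
                         zero = FALSE) {
  fan_in <- k^3 * in_ch
  w <- if (zero) array(0, c(k, k, k, in_ch, out_ch)) else
    array(rnorm(k^3 * in_ch * out_ch, sd = sqrt(2 / fan_in)),
          c(k, k, k, in_ch, out_ch))
  list(w = w, b = numeric(out_ch), stride = as.integer(stride),
       pad = as.integer(pad))
}

conv_fwd <- function(p, x) {
  list(y = cpp_conv3d_fwd(x, p$w, p$b, p$stride, p$pad), x = x)
}

conv_bwd <- function(p, x, gy) {
  g <- cpp_conv3d_bwd(x, p$w, gy, p$stride, p$pad)
  list(gx = g$gx, grads = list(w = g$gw, b = g$gb))
}

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, x = x, s = s)
}

silu_bwd <- function(cache, gy) {
  gy * (cache$s * (1 + cache$x * (1 - cache$s)))
}

nn_gn_init <- function(C, groups = 4L, eps = 1e-5) {
  if (C %% groups != 0) stop("channels must be divisible by groups")
  list(gamma = rep(1, C), beta = rep(0, C), groups = as.integer(groups),
       eps = eps)
}

gn_fwd <- function(p, x) {
  d <- dim(x)
  C <- d[4]
  g <- p$groups
  cpg <- C %/% g
  nvox <- prod(d[1:3])
  xm <- matrix(x, ncol = C)            # spatial-major, channel columns
  cm <- .colMeans(xm, nvox, C)
  cm2 <- .colMeans(xm * xm, nvox, C)
  gi_of <- rep(seq_len(g), each = cpg)
  m_g <- vapply(seq_len(g), function(gi) mean(cm[gi_of == gi]), numeric(1))
  v_g <- vapply(seq_len(g), function(gi) mean(cm2[gi_of == gi]), numeric(1)) -
    m_g^2
  istd <- 1 / sqrt(v_g + p$eps)
  ctr <- m_g[gi_of]
  scl <- istd[gi_of]
  xhat <- (xm - rep(ctr, each = nvox)) * rep(scl, each = nvox)
  ym <- xhat * rep(p$gamma, each = nvox) + rep(p$beta, each = nvox)
  list(y = array(ym, d), xhat = xhat, istd = istd, dims = d)
}

gn_bwd <- function(p, cache, gy) {
  d <- cache$dims
  C <- d[4]
  g <- p$groups
  cpg <- C %/% g
  nvox <- prod(d[1:3])
  gym <- matrix(gy, ncol = C)
  ggamma <- colSums(gym * cache$xhat)
  gbeta <- colSums(gym)
  gxhat <- gym * rep(p$gamma, each = nvox)
  gi_of <- rep(seq_len(g), each = cpg)
  cmh <- .colMeans(gxhat, nvox, C)
  cmx <- .colMeans(gxhat * cache$xhat, nvox, C)
  mh_g <- vapply(seq_len(g), function(gi) mean(cmh[gi_of == gi]), numeric(1))
  mx_g <- vapply(seq_len(g), function(gi) mean(cmx[gi_of == gi]), numeric(1))
  gxm <- rep(cache$istd[gi_of], each = nvox) *
    (gxhat - rep(mh_g[gi_of], each = nvox) -
       cache$xhat * rep(mx_g[gi_of], each = nvox))
  list(gx = array(gxm, d), grads = list(gamma = ggamma, beta = gbeta))
}

nn_lin_init <- function(n_in, n_out, zero = FALSE) {
  w <- if (zero) matrix(0, n_in, n_out) else
    matrix(rnorm(n_in * n_out, sd = sqrt(1 / n_in)), n_in, n_out)
  list(w = w, b = numeric(n_out))
}

lin_fwd <- function(p, v) {
  # v: vector (length n_in) or matrix (rows = items)
  if (is.matrix(v)) sweep(v %*% p$w, 2, p$b, `+`) else
    drop(v %*% p$w) + p$b
}

lin_bwd <- function(p, v, gy) {
  if (!is.matrix(v)) {
    list(gv = drop(p$w %*% gy),
         grads = list(w = outer(v, gy), b = gy))
  } else {
    list(gv = gy %*% t(p$w),
         grads = list(w = t(v) %*% gy, b = colSums(gy)))
  }
}

# Single-head self-attention over flattened spatial positions, with
# pre-GroupNorm and a residual connection (the standard diffusion U-Net
# attention block).
nn_attn_init <- function(C, groups = 4L) {
  sdq <- sqrt(1 / C)
  list(gn = nn_gn_init(C, groups),
       wq = matrix(rnorm(C * C, sd = sdq), C, C),
       wk = matrix(rnorm(C * C, sd = sdq), C, C),
       wv = matrix(rnorm(C * C, sd = sdq), C, C),
       wo = matrix(0, C, C))  # zero init: block starts as identity
}

attn_fwd <- function(p, x) {
  d <- dim(x)
  C <- d[4]
  gn <- gn_fwd(p$gn, x)
  M <- matrix(gn$y, ncol = C)
  q <- M %*% p$wq
  k <- M %*% p$wk
  v <- M %*% p$wv
  S <- (q %*% t(k)) / sqrt(C)
  S <- S - apply(S, 1, max)
  A <- exp(S)
  A <- A / rowSums(A)
  O <- A %*% v
  y <- x + array(O %*% p$wo, d)
  list(y = y, gn = gn, M = M, q = q, k = k, v = v, A = A, O = O, dims = d)
}

attn_bwd <- function(p, cache, gy) {
  d <- cache$dims
  C <- d[4]
  G <- matrix(gy, ncol = C)
  gWo <- t(cache$O) %*% G
  gO <- G %*% t(p$wo)
  gA <- gO %*% t(cache$v)
  gv <- t(cache$A) %*% gO
  gS <- cache$A * (gA - rowSums(gA * cache$A))
  gq <- (gS %*% cache$k) / sqrt(C)
  gk <- (t(gS) %*% cache$q) / sqrt(C)
  gM <- gq %*% t(p$wq) + gk %*% t(p$wk) + gv %*% t(p$wv)
  gWq <- t(cache$M) %*% gq
  gWk <- t(cache$M) %*% gk
  gWv <- t(cache$M) %*% gv
  gnb <- gn_bwd(p$gn, cache$gn, array(gM, d))
  list(gx = gy + gnb$gx,
       grads = list(gn = gnb$grads, wq = gWq, wk = gWk, wv = gWv, wo = gWo))
}

upsample_nearest2_fwd <- function(x) {
  d <- dim(x)
  ix <- rep(seq_len(d[1]), each = 2)
  iy <- rep(seq_len(d[2]), each = 2)
  iz <- rep(seq_len(d[3]), each = 2)
  x[ix, iy, iz, , drop = FALSE]
}

upsample_nearest2_bwd <- function(gy, in_dim) {
  gx <- array(0, in_dim)
  d2 <- dim(gy)
  for (dx in 1:2) for (dy in 1:2) for (dz in 1:2) {
    gx <- gx + gy[seq(dx, d2[1], by = 2), seq(dy, d2[2], by = 2),
                  seq(dz, d2[3], by = 2), , drop = FALSE]
  }
  gx
}

avgpool2_fwd <- function(x) {
  # 2x average pooling of a 3D array (trailing odd planes dropped)
  d <- dim(x)
  h <- d %/% 2L
  x <- x[seq_len(2 * h[1]), seq_len(2 * h[2]), seq_len(2 * h[3]), drop = FALSE]
  out <- array(0, h)
  for (dx in 1:2) for (dy in 1:2) for (dz in 1:2)
    out <- out + x[seq(dx, 2 * h[1], 2), seq(dy, 2 * h[2], 2), seq(dz, 2 * h[3], 2),
                   drop = FALSE] / 8
  out
}

avgpool2_bwd <- function(gy, in_dim) {
  gx <- array(0, in_dim)
  h <- dim(gy)
  for (dx in 1:2) for (dy in 1:2) for (dz in 1:2)
    gx[seq(dx, 2 * h[1], 2), seq(dy, 2 * h[2], 2), seq(dz, 2 * h[3], 2)] <-
      gx[seq(dx, 2 * h[1], 2), seq(dy, 2 * h[2], 2), seq(dz, 2 * h[3], 2)] + gy / 8
  gx
}

# ---- parameter-tree utilities -------------------------------------------

# Apply f(leaf_a, leaf_b) over two parameter trees with identical structure.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) {
      if (is.list(a[[nm]]) || is.numeric(a[[nm]]))
        out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    }
    out
  } else if (is.numeric(a)) f(a, b) else a
}

tree_zero <- function(a) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_zero(a[[nm]])
    out
  } else if (is.numeric(a)) a * 0 else a
}

tree_add <- function(a, b) tree_map2(a, b, `+`)
tree_scale <- function(a, s) tree_map2(a, a, function(x, y) x * s)

# Hyperparameter leaves (stride, pad, groups, eps) are integer-valued
# scalars stored as numeric; exclude them from optimization by name.
NON_TRAINABLE <- c("stride", "pad", "groups", "eps")

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, path) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% NON_TRAINABLE) next
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      p <- p - lr * mhat / (sqrt(vhat) + eps)
      list(p = p, m = m, v = v)
    } else list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v, character(0))
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
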