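# Independent brute-force oracles used to cross-check the package
# implementations on small fixtures. These are deliberately written as
# direct loops / enumerations, not via the package's own code paths.

# flood-fill connected-component labelling
oracle_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- ord > 0 & ord <= switch(as.character(connectivity),
                                  "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z] || lab[x, y, z] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(x, y, z))
    lab[x, y, z] <- nxt
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        n <- cur + c(offs$dx[k], offs$dy[k], offs$dz[k])
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] && lab[n[1], n[2], n[3]] == 0L) {
          lab[n[1], n[2], n[3]] <- nxt
          queue[[length(queue) + 1]] <- n
        }
      }
    }
  }
  lab
}

oracle_mae <- function(y, y_hat, B) {
  acc <- 0; n <- 0
  d <- dim(y)
  for (z in seq_len(d[3])) for (yy in seq_len(d[2])) for (x in seq_len(d[1]))
    if (B[x, yy, z]) { acc <- acc + abs(y[x, yy, z] - y_hat[x, yy, z]); n <- n + 1 }
  acc / n
}

oracle_psnr <- function(y, y_hat, B, Q) {
  acc <- 0; n <- 0
  d <- dim(y)
  for (z in seq_len(d[3])) for (yy in seq_len(d[2])) for (x in seq_len(d[1]))
    if (B[x, yy, z]) { acc <- acc + (y[x, yy, z] - y_hat[x, yy, z])^2; n <- n + 1 }
  10 * log10(Q^2 / (acc / n))
}

# symmetric (edge-inclusive) reflection of an out-of-range index
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_ssim <- function(y, y_hat, B, Q, k1 = 0.01, k2 = 0.03, win = 7L) {
  r <- (win - 1) %/% 2
  c1 <- (k1 * Q)^2; c2 <- (k2 * Q)^2
  d <- dim(y)
  vals <- c()
  for (z in seq_len(d[3])) for (yy in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!B[x, yy, z]) next
    wx <- c(); wy <- c()
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      i <- reflect1(x + dx, d[1]); j <- reflect1(yy + dy, d[2])
      l <- reflect1(z + dz, d[3])
      wx <- c(wx, y[i, j, l]); wy <- c(wy, y_hat[i, j, l])
    }
    n <- length(wx)
    mx <- sum(wx) / n; my <- sum(wy) / n
    vx <- sum(wx * wx) / n - mx^2
    vy <- sum(wy * wy) / n - my^2
    cxy <- sum(wx * wy) / n - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# exact two-sided signed-rank p by enumerating all 2^m sign assignments
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    signs <- as.integer(intToBits(code))[1:m]
    vs[code + 1] <- sum(r[signs == 1])
  }
  p_le <- mean(vs <= v_obs + 1e-12)
  p_ge <- mean(vs >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# maximum-cardinality one-to-one matching by exhaustive assignment search
oracle_max_matching <- function(overlap) {
  # overlap: n_gt x n_pred matrix of overlap voxel counts
  n_gt <- nrow(overlap); n_pred <- ncol(overlap)
  best <- 0
  rec <- function(g, used_pred, count) {
    if (g > n_gt) { best <<- max(best, count); return(invisible()) }
    rec(g + 1L, used_pred, count)
    for (p in seq_len(n_pred)) {
      if (!used_pred[p] && overlap[g, p] > 0) {
        used_pred[p] <- TRUE
        rec(g + 1L, used_pred, count + 1L)
        used_pred[p] <- FALSE
      }
    }
  }
  rec(1L, logical(n_pred), 0L)
  best
}
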