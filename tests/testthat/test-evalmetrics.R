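make_ctx <- function(B, Q = 30) eval_context(mask3d(B, c(1, 1, 1)), Q = Q)

test_that("masked MAE matches hand sums and never grows with zero-error voxels", {
  set.seed(51)
  y <- array(runif(4 * 4 * 4, 0, 10), c(4, 4, 4))
  B <- array(TRUE, dim(y))
  ctx <- make_ctx(B)
  expect_equal(mae_masked(y, y, ctx), 0)
  expect_equal(mae_masked(y, y + 3, ctx), 3)
  # 4-voxel mask with residuals (1, -1, 2, 0) -> 1.0
  B4 <- array(FALSE, dim(y)); B4[1:4, 1, 1] <- TRUE
  yh <- y; yh[1:4, 1, 1] <- y[1:4, 1, 1] + c(1, -1, 2, 0)
  expect_equal(mae_masked(y, yh, make_ctx(B4)), 1.0)
  # enlarging B with zero-residual voxels cannot increase MAE
  B5 <- B4; B5[1, 2, 1] <- TRUE
  expect_lte(mae_masked(y, yh, make_ctx(B5)), mae_masked(y, yh, make_ctx(B4)))
  expect_error(eval_context(mask3d(array(FALSE, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
})

test_that("masked PSNR follows its closed form, log identities and the cap", {
  y <- array(5, c(4, 4, 4))
  B <- array(TRUE, dim(y))
  ctx <- make_ctx(B, Q = 30)
  expect_equal(psnr_masked(y, y + 3, ctx), 10 * log10(100))
  # halving the residuals adds exactly 10 log10(4) dB
  set.seed(52)
  yh <- y + rnorm(length(y))
  p1 <- psnr_masked(y, yh, ctx)
  p2 <- psnr_masked(y, y + (yh - y) / 2, ctx)
  expect_equal(p2 - p1, 10 * log10(4), tolerance = 1e-10)
  # doubling Q adds the same amount
  expect_equal(psnr_masked(y, yh, make_ctx(B, Q = 60)) - p1, 10 * log10(4),
               tolerance = 1e-10)
  expect_warning(cap <- psnr_masked(y, y, ctx), "infinite")
  expect_equal(cap, 300)
})

test_that("masked 3D SSIM respects its fixed points, sign and symmetry", {
  set.seed(53)
  y <- array(runif(10 * 10 * 8, 0, 20), c(10, 10, 8))
  B <- array(TRUE, dim(y))
  ctx <- make_ctx(B)
  expect_equal(ssim3d_masked(y, y, ctx), 1, tolerance = 1e-12)
  # constant pair: stabilizers prevent 0/0
  k <- array(4, dim(y))
  expect_equal(ssim3d_masked(k, k, ctx), 1, tolerance = 1e-12)
  # anticorrelated zero-local-mean input drives SSIM negative: on a
  # checkerboard the window means vanish, so the covariance term (equal to
  # minus the variance) dominates
  idx <- expand.grid(i = 1:10, j = 1:10, k = 1:8)
  z <- array(10 * (-1)^(idx$i + idx$j + idx$k), c(10, 10, 8))
  expect_lt(ssim3d_masked(z, -z, ctx), 0)
  # symmetry
  yh <- y + rnorm(length(y))
  expect_equal(ssim3d_masked(y, yh, ctx), ssim3d_masked(yh, y, ctx),
               tolerance = 1e-12)
  expect_lte(ssim3d_masked(y, yh, ctx), 1)
  expect_error(ssim3d_masked(y[, , 1:4], yh[, , 1:4],
                             make_ctx(B[, , 1:4, drop = FALSE])), "window")
})

test_that("global metrics agree with brute-force loop oracles on small grids", {
  set.seed(54)
  d <- c(9, 8, 7)
  y <- array(runif(prod(d), 0, 25), d)
  yh <- y + rnorm(prod(d))
  B <- array(runif(prod(d)) > 0.3, d)
  ctx <- make_ctx(B)
  expect_equal(mae_masked(y, yh, ctx), oracle_mae(y, yh, B), tolerance = 1e-10)
  expect_equal(psnr_masked(y, yh, ctx), oracle_psnr(y, yh, B, 30),
               tolerance = 1e-10)
  # SSIM oracle is slow: restrict the mask to a handful of voxels
  Bs <- array(FALSE, d); Bs[c(1, 30, 200, 400)] <- TRUE
  ctxs <- make_ctx(Bs)
  expect_equal(ssim3d_masked(y, yh, ctxs), oracle_ssim(y, yh, Bs, 30),
               tolerance = 1e-10)
})

test_that("lesion extraction follows threshold, size and connectivity rules", {
  # background-only PET
  bg <- small_vol(array(1, c(8, 8, 8)))
  expect_equal(extract_lesions(bg, threshold = 2.5)$n, 0)
  # noiseless 3-lesion phantom
  case <- generate_case(noiseless_toy_spec(lesion_count_range = c(3L, 3L)), 5)
  ls <- extract_lesions(case$pet, threshold = 2.5, min_voxels = 1L)
  expect_equal(ls$n, 3)
  expect_equal(sort(ls$voxels), sort(tabulate(oracle_label(
    unclass(case$pet) >= 2.5, 26))))
  # volumes are voxel count x voxel volume
  expect_equal(ls$volumes_mm3, ls$voxels * prod(vol_spacing(case$pet)))
  # two cubes touching only at a corner voxel: 26-conn merges, 6-conn splits
  x <- array(0, c(8, 8, 8))
  x[2:3, 2:3, 2:3] <- 5
  x[4:5, 4:5, 4:5] <- 5
  v <- small_vol(x)
  expect_equal(extract_lesions(v, 2.5, 1L, connectivity = 26L)$n, 1)
  expect_equal(extract_lesions(v, 2.5, 1L, connectivity = 6L)$n, 2)
  # min_voxels filters small components
  x2 <- array(0, c(8, 8, 8)); x2[1, 1, 1] <- 9; x2[4:6, 4:6, 4] <- 9
  expect_equal(extract_lesions(small_vol(x2), 2.5, min_voxels = 3L)$n, 1)
})

test_that("greedy one-to-one matching satisfies the count identities", {
  mk <- function(x) extract_lesions(small_vol(x), 0.5, 1L)
  base <- array(0, c(12, 12, 4))
  g <- base; g[2:4, 2:4, 2] <- 1; g[8:10, 8:10, 2] <- 1
  gt <- mk(g)
  # perfect prediction
  m0 <- match_lesions(gt, mk(g))
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(2, 0, 0))
  # 3 predictions, 2 overlap distinct GT -> TP 2, FP 1, FN 0
  p <- base; p[3:5, 3:5, 2] <- 1; p[8:9, 8:9, 2] <- 1; p[1:2, 10:11, 4] <- 1
  m <- match_lesions(gt, mk(p))
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 1, 0))
  expect_equal(m$tp / (m$tp + m$fp), 2 / 3)
  expect_equal(m$tp / (m$tp + m$fn), 1)
  # the exhaustive max-matching oracle agrees with the greedy TP here
  ov <- matrix(0, gt$n, mk(p)$n)
  for (i in seq_len(gt$n)) for (j in seq_len(mk(p)$n))
    ov[i, j] <- sum(gt$labels == i & mk(p)$labels == j)
  expect_equal(m$tp, oracle_max_matching(ov))
  # one prediction spanning two GT lesions -> 1 TP + 1 FN (one-to-one)
  wide <- base; wide[2:10, 2:10, 2] <- 1
  m2 <- match_lesions(gt, mk(wide))
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 0, 1))
  # invariants on random fixtures
  set.seed(55)
  for (i in 1:5) {
    a <- mk(array(runif(12 * 12 * 4) > 0.8, c(12, 12, 4)) * 1)
    b <- mk(array(runif(12 * 12 * 4) > 0.8, c(12, 12, 4)) * 1)
    mm <- match_lesions(a, b)
    expect_equal(mm$tp + mm$fn, a$n)
    expect_equal(mm$tp + mm$fp, b$n)
  }
})

test_that("cohort detection metrics subject-average with documented exclusions", {
  mk <- function(x) extract_lesions(small_vol(x), 0.5, 1L)
  base <- array(0, c(10, 10, 4))
  # subject 1: (tp, fp, fn) = (2, 1, 0); subject 2: (1, 0, 1); 3: (0, 0, 2)
  g1 <- base; g1[2:3, 2:3, 2] <- 1; g1[7:8, 7:8, 2] <- 1
  p1 <- base; p1[2:3, 2:3, 2] <- 1; p1[7:8, 7:8, 2] <- 1; p1[1, 10, 4] <- 1
  g2 <- base; g2[2:3, 2:3, 2] <- 1; g2[7:8, 7:8, 2] <- 1
  p2 <- base; p2[2:3, 2:3, 2] <- 1
  g3 <- base; g3[2:3, 2:3, 2] <- 1; g3[7:8, 7:8, 2] <- 1
  p3 <- base
  matches <- list(match_lesions(mk(g1), mk(p1)),
                  match_lesions(mk(g2), mk(p2)),
                  match_lesions(mk(g3), mk(p3)))
  det <- detection_metrics(matches)
  expect_equal(det$recall, (1 + 0.5 + 0) / 3)
  expect_equal(det$fp_rate, 1 / 3)
  expect_equal(det$n_precision_undefined, 1)  # subject 3 has no predictions
  expect_equal(det$precision, (2 / 3 + 1) / 2)
  # perfect predictions everywhere
  perf <- detection_metrics(list(match_lesions(mk(g1), mk(g1))))
  expect_equal(c(perf$precision, perf$recall, perf$fp_rate), c(1, 1, 0))
  # two subjects with FP counts (1, 0) -> fp_rate 0.5
  det2 <- detection_metrics(matches[1:2])
  expect_equal(det2$fp_rate, 0.5)
})

test_that("lesion SUV errors and volume agreement match hand computations", {
  mk <- function(x) extract_lesions(small_vol(x), 0.5, 1L)
  g <- array(0, c(8, 8, 4)); g[2:4, 2, 2] <- 1
  gt <- mk(g)
  y <- array(1, dim(g)); y[2:4, 2, 2] <- c(5, 6, 7)
  expect_equal(lesion_suv_mse(y, y, gt), 0)
  yh <- y; yh[2:4, 2, 2] <- yh[2:4, 2, 2] + 2
  expect_equal(lesion_suv_mse(y, yh, gt), 4)
  yh2 <- y; yh2[2:4, 2, 2] <- y[2:4, 2, 2] - c(1, 2, 3)
  expect_equal(lesion_suv_mse(y, yh2, gt), 14 / 3)

  expect_equal(lesion_nmse_pct(y, y, gt), 0)
  expect_equal(lesion_nmse_pct(y, array(0, dim(y)), gt), 100)
  expect_equal(lesion_nmse_pct(y, 1.1 * y, gt), 1, tolerance = 1e-10)

  # volume agreement on matched pairs
  p <- array(0, dim(g)); p[2:4, 2:2, 2] <- 1
  m <- match_lesions(gt, mk(p))
  expect_equal(volume_mape(m, gt, mk(p)), 0)
  expect_warning(expect_true(is.na(volume_pearson(m, gt, mk(p)))),
                 "fewer than two")

  # hand example: v = (100, 200) -> vhat = (120, 160) gives 20%
  fake_gt <- list(volumes_mm3 = c(100, 200), n = 2)
  fake_pred <- list(volumes_mm3 = c(120, 160), n = 2)
  fake_match <- list(pairs = data.frame(gt = 1:2, pred = 1:2,
                                        overlap = c(5, 5)), tp = 2)
  expect_equal(volume_mape(fake_match, fake_gt, fake_pred), 20,
               tolerance = 1e-6)
  # single match v = 100 -> 150 gives 50%
  expect_equal(volume_mape(list(pairs = data.frame(gt = 1, pred = 1,
                                                   overlap = 2), tp = 1),
                           list(volumes_mm3 = 100),
                           list(volumes_mm3 = 150)), 50, tolerance = 1e-6)
  # Pearson: identity 1, affine invariance 1, anticorrelation -1
  fm3 <- list(pairs = data.frame(gt = 1:3, pred = 1:3, overlap = 1), tp = 3)
  expect_equal(volume_pearson(fm3, list(volumes_mm3 = c(1, 2, 3)),
                              list(volumes_mm3 = c(1, 2, 3))), 1)
  expect_equal(volume_pearson(fm3, list(volumes_mm3 = c(1, 2, 3)),
                              list(volumes_mm3 = 2 * c(1, 2, 3) + 5)), 1)
  expect_equal(volume_pearson(fm3, list(volumes_mm3 = c(1, 2, 3)),
                              list(volumes_mm3 = c(3, 2, 1))), -1)
})
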