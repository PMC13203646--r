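test_that("RAS reorientation permutes and flips correctly and is idempotent", {
  set.seed(1)
  v <- volume3d(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1, 2, 3), "RAS", "CT-HU")
  expect_identical(strip(reorient_to_ras(v)), strip(v))

  lps <- volume3d(unclass(v), c(1, 2, 3), "LPS", "CT-HU")
  ras <- reorient_to_ras(lps)
  expect_identical(dim(ras), c(4L, 5L, 6L))
  ref <- strip(v)[rev(seq_len(4)), rev(seq_len(5)), , drop = FALSE]
  expect_equal(strip(ras), ref)
  expect_identical(strip(reorient_to_ras(ras)), strip(ras))

  # axis permutation: ASR stores (A, S, R) along array axes 1..3
  asr <- volume3d(unclass(v), c(1, 2, 3), "ASR", "CT-HU")
  r2 <- reorient_to_ras(asr)
  expect_identical(dim(r2), c(6L, 4L, 5L))
  expect_equal(vol_spacing(r2), c(3, 1, 2))
  expect_equal(strip(r2), aperm(strip(v), c(3, 1, 2)))

  expect_error(volume3d(unclass(v), c(1, 1, 1), "QAS"), "unknown orientation")
})

test_that("resampling preserves identity, constants, and analytic ramps", {
  set.seed(2)
  v <- volume3d(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(2, 2, 2), "RAS", "CT-HU")
  expect_identical(strip(resample(v, c(2, 2, 2))), strip(v))

  k <- volume3d(array(7, c(8, 8, 8)), c(2, 2, 2), "RAS", "CT-HU")
  expect_true(all(abs(unclass(resample(k, c(3, 3, 3))) - 7) < 1e-12))

  # linear ramp along x, 2x downsample: centre-aligned trilinear values are
  # exact at interior output centres
  ramp <- volume3d(array(rep(seq_len(16), times = 8 * 8), c(16, 8, 8)),
                   c(1, 1, 1), "RAS", "CT-HU")
  down <- resample(ramp, c(2, 1, 1))
  expect_identical(dim(down)[1], 8L)
  # output centre i (1-based) sits at world (i - 0.5) * 2 -> input index
  # (world / 1) + 0.5 -> value (i - 0.5) * 2 + 0.5
  expected <- (seq_len(8) - 0.5) * 2 + 0.5
  expected <- pmin(pmax(expected, 1), 16)  # border clamping
  expect_equal(unclass(down)[, 4, 4], expected, tolerance = 1e-12)

  m <- mask3d(array(runif(8^3) > 0.5, c(8, 8, 8)), c(2, 2, 2))
  rm2 <- resample(m, c(3, 3, 3))
  expect_type(unclass(rm2), "logical")
  expect_error(resample(v, c(0, 1, 1)), "positive")
})

test_that("CT clip-normalization maps the window onto [-1, 1]", {
  v <- small_vol(array(c(-2000, -1000, 0, 1000, 2000, 500), c(1, 2, 3)),
                 modality = "CT-HU")
  out <- clip_normalize_ct(v, c(-1000, 1000))
  expect_identical(vol_modality(out), "normalized-CT")
  expect_equal(as.numeric(out), c(-1, -1, 0, 1, 1, 0.5))
  expect_error(clip_normalize_ct(v, c(100, 100)), "window")
})

test_that("PET SUV clipping bounds without rescaling", {
  v <- small_vol(array(c(-0.5, 0, 1, 29, 30, 100), c(1, 2, 3)))
  out <- clip_pet_suv(v, 30)
  expect_equal(as.numeric(out), c(0, 0, 1, 29, 30, 30))
  expect_identical(vol_modality(out), "PET-SUV")
  expect_error(clip_pet_suv(v, -1), "suv_max")
})

test_that("body mask contains lungs and lesions and fills internal holes", {
  case <- generate_case(noiseless_toy_spec(lesion_count_range = c(2L, 2L)), 13)
  B <- body_mask(case$ct)
  expect_true(all(B[case$lesion_mask]))
  expect_true(all(B[case$lung_mask]))   # holes (lungs) filled
  expect_error(body_mask(small_vol(array(-1000, c(4, 4, 4)),
                                   modality = "CT-HU")), "empty")
  # analytic check: noiseless phantom body mask equals the filled ellipsoid
  interior <- unclass(case$ct) > -500 | unclass(case$lung_mask)
  expect_identical(strip(B), interior)
})

test_that("surrogate lung segmentation recovers the phantom lungs", {
  case <- generate_case(noiseless_toy_spec(), 17)
  lm <- surrogate_lung_mask(case$ct)
  dice <- 2 * sum(lm & case$lung_mask) / (sum(lm) + sum(case$lung_mask))
  expect_gte(dice, 0.95)

  soft <- small_vol(array(40, c(6, 6, 6)), modality = "CT-HU")
  expect_warning(empty <- surrogate_lung_mask(soft), "empty")
  expect_equal(sum(empty), 0)

  # two -750 HU boxes inside a soft tissue body: both selected, 2 components
  ct <- array(40, c(12, 12, 8))
  ct[2:4, 2:4, 3:6] <- -750
  ct[8:10, 8:10, 3:6] <- -750
  lm2 <- surrogate_lung_mask(small_vol(ct, modality = "CT-HU"))
  expect_equal(sum(lm2), 2 * 3 * 3 * 4)
  expect_identical(max(oracle_label(unclass(lm2), 26)), 2L)
})

test_that("lung-base crop bounds start at the inferior lung extent", {
  m <- array(FALSE, c(8, 8, 64))
  m[4, 4, 11:41] <- TRUE   # slices 10..40 (0-based)
  b <- lung_base_crop_bounds(mask3d(m, c(1, 1, 1)))
  expect_identical(b[[3]], c(10L, 64L))
  expect_identical(b[[1]], c(0L, 8L))

  m0 <- array(FALSE, c(4, 4, 6)); m0[2, 2, 1] <- TRUE
  expect_identical(lung_base_crop_bounds(mask3d(m0, c(1, 1, 1)))[[3]], c(0L, 6L))
  expect_error(lung_base_crop_bounds(mask3d(array(FALSE, c(2, 2, 2)),
                                            c(1, 1, 1))), "external")
  # determinism: identical masks give identical bounds
  expect_identical(lung_base_crop_bounds(mask3d(m, c(1, 1, 1))),
                   lung_base_crop_bounds(mask3d(m, c(1, 1, 1))))
})

test_that("fixed-size crop/pad centres, pads symmetrically and is idempotent", {
  set.seed(3)
  v96 <- small_vol(array(rnorm(96 * 8 * 8), c(96, 8, 8)))
  expect_identical(strip(fixed_size_crop_pad(v96, c(96, 8, 8))), strip(v96))

  v100 <- small_vol(array(rnorm(100 * 8 * 8), c(100, 8, 8)))
  out <- fixed_size_crop_pad(v100, c(96, 8, 8))
  expect_equal(strip(out), strip(v100)[3:98, , ])

  v90 <- small_vol(array(rnorm(90 * 8 * 8), c(90, 8, 8)))
  out <- fixed_size_crop_pad(v90, c(96, 8, 8), pad_value = -5)
  expect_true(all(out[1:3, , ] == -5) && all(out[94:96, , ] == -5))
  expect_equal(strip(out)[4:93, , ], strip(v90))

  # odd remainder goes to the far side
  v7 <- small_vol(array(seq_len(7 * 4 * 4), c(7, 4, 4)))
  out <- fixed_size_crop_pad(v7, c(10, 4, 4), pad_value = 0)
  expect_true(all(out[1, , ] == 0))          # one plane near side
  expect_true(all(out[9:10, , ] == 0))       # two planes far side
  out2 <- fixed_size_crop_pad(out, c(10, 4, 4), pad_value = 0)
  expect_identical(strip(out2), strip(out))
})

test_that("the composed pipeline yields aligned fixed-size SUV volumes", {
  case <- generate_case(toy_spec(), 23)
  pp <- toy_preprocessed(case)
  for (obj in pp) expect_identical(dim(obj), c(32L, 32L, 16L))
  expect_gte(min(pp$pet), 0)
  expect_lte(max(pp$pet), 30)
  expect_identical(vol_modality(pp$ct_norm), "normalized-CT")
  expect_true(all(abs(pp$ct_norm) <= 1))
  expect_true(all(pp$body_mask[pp$lesion_mask]))
  # surrogate path (no lung mask supplied) agrees on the crop start
  pp2 <- preprocess_case(case$ct, case$pet,
                         target_spacing = c(6, 6, 12),
                         target_shape = c(32L, 32L, 16L))
  expect_identical(dim(pp2$pet), c(32L, 32L, 16L))
})
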