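# Shared fixtures built in code. The desk-scale phantom grid is 32x32x16 at
# 6x6x12 mm spacing (same 192x192x192 mm field of view as the full-scale
# 96x96x64 grid at 2x2x3 mm); test lesions use radii that span at least a
# couple of voxels at this coarse spacing.

toy_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 16L), spacing = c(6, 6, 12),
               lesion_radius_range = c(9, 15), ...)
}

noiseless_toy_spec <- function(...) {
  toy_spec(ct_noise_sd = 0, pet_noise_sd = 0, ...)
}

# preprocess a generated phantom case at the toy profile
toy_preprocessed <- function(case, config = run_config("toy")) {
  preprocess_case(case$ct, case$pet, lung_mask = case$lung_mask,
                  lesion_mask = case$lesion_mask,
                  target_spacing = config$target_spacing,
                  target_shape = config$input_size,
                  hu_window = config$hu_window, suv_max = config$suv_max)
}

# build a preprocessed in-memory toy cohort (cached per test session)
.cohort_cache <- new.env(parent = emptyenv())
toy_cohort <- function(n, seed, noiseless = TRUE) {
  key <- paste0("c", n, "_", seed, "_", noiseless)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  spec <- if (noiseless) noiseless_toy_spec() else toy_spec()
  cases <- list()
  for (i in seq_len(n)) {
    cs <- generate_case(spec, petldm:::derive_seed(seed, i))
    cases[[sprintf("case%03d", i)]] <- toy_preprocessed(cs)
  }
  .cohort_cache[[key]] <- cases
  cases
}

# tiny volumes for metric fixtures
small_vol <- function(values, spacing = c(1, 1, 1), modality = "PET-SUV") {
  volume3d(values, spacing, "RAS", modality)
}

# finite-difference gradient of a scalar function at selected indices
fd_grad <- function(f, x, idx, h = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# voxel data stripped of geometry attributes, for value-only comparisons
strip <- function(v) {
  a <- unclass(v)
  attributes(a) <- list(dim = dim(a))
  a
}
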