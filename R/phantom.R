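#' Specification of a paired CT/PET phantom
#'
#' Describes the study conditions emulated by the synthetic cohort: a soft
#' tissue body ellipsoid with two low-attenuation lungs, spherical
#' hypermetabolic lesions whose uptake is spatially coupled to CT anatomy
#' (each lesion carries a mild +30 HU correlate) but whose SUV amplitude is
#' drawn independently of HU, a smooth anatomical background uptake profile
#' with a small per-case amplitude, and additive Gaussian noise on both
#' modalities (PET clipped at zero, since SUV is non-negative).
#'
#' @param grid_shape Integer triple of voxel counts.
#' @param spacing Voxel spacing in mm.
#' @param body_hu,lung_hu,air_hu CT tissue levels in Hounsfield units.
#' @param background_suv Baseline soft tissue uptake (SUV).
#' @param lesion_suv_range SUV interval lesions are drawn from; its minimum
#'   must exceed the maximum background uptake so the lesion signal contract
#'   (lesion voxels hotter than all other body voxels before noise) holds.
#' @param lesion_count_range Integer interval for the per-case lesion count.
#' @param lesion_radius_range Lesion radius interval, in mm (world
#'   coordinates; spheres are rasterized on the voxel grid).
#' @param ct_noise_sd,pet_noise_sd Additive Gaussian noise SDs (HU / SUV).
#' @param seed Default cohort seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 64L),
                         spacing = c(2, 2, 3),
                         body_hu = 40, lung_hu = -750, air_hu = -1000,
                         background_suv = 1.0,
                         lesion_suv_range = c(4, 12),
                         lesion_count_range = c(0L, 5L),
                         lesion_radius_range = c(4, 12),
                         ct_noise_sd = 20, pet_noise_sd = 0.1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("grid_shape must be a positive integer triple")
  if (any(spacing <= 0)) stop("spacing must be positive")
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  if (!rng_ok(lesion_suv_range) || !rng_ok(lesion_count_range) ||
      !rng_ok(lesion_radius_range))
    stop("all ranges must be non-empty [lo, hi] intervals")
  # maximum background uptake: smooth field amplitude is at most 0.15
  if (lesion_suv_range[1] <= background_suv * 1.15)
    stop("lesion_suv_range minimum must exceed the maximum background uptake (",
         background_suv * 1.15, ")")
  if (lesion_count_range[1] < 0) stop("lesion counts must be non-negative")
  if (ct_noise_sd < 0 || pet_noise_sd < 0) stop("noise SDs must be >= 0")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 body_hu = body_hu, lung_hu = lung_hu, air_hu = air_hu,
                 background_suv = background_suv,
                 lesion_suv_range = as.numeric(lesion_suv_range),
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 ct_noise_sd = ct_noise_sd, pet_noise_sd = pet_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Anatomy layout in fractional extent coordinates, with per-case size and
# position jitter emulating inter-patient variability (the anatomical signal
# the CT condition carries). The body is an ellipsoid elongated past the
# grid in the inferior-superior direction so tissue exists at every axial
# level; lungs sit in the lower-mid grid so a "head" region remains above
# their superior extent.
phantom_geometry <- function(spec, jitter = TRUE) {
  ext <- spec$grid_shape * spec$spacing
  jb <- if (jitter) runif(3, 0.85, 1.12) else rep(1, 3)
  jl <- if (jitter) runif(3, 0.85, 1.15) else rep(1, 3)
  dz <- if (jitter) runif(1, -0.04, 0.04) else 0
  dxl <- if (jitter) runif(1, -0.02, 0.02) else 0
  list(ext = ext,
       body_c = ext * c(0.5, 0.5, 0.5),
       body_a = ext * c(0.42, 0.35, 0.55) * jb,
       lung_c1 = ext * c(0.32 + dxl, 0.5, 0.40 + dz),
       lung_c2 = ext * c(0.68 + dxl, 0.5, 0.40 + dz),
       lung_a = ext * c(0.11, 0.18, 0.20) * jl)
}

ellipsoid_q <- function(xs, ys, zs, centre, axes) {
  # squared normalized ellipsoid coordinate on the voxel-centre grid
  qx <- ((xs - centre[1]) / axes[1])^2
  qy <- ((ys - centre[2]) / axes[2])^2
  qz <- ((zs - centre[3]) / axes[3])^2
  outer(outer(qx, qy, `+`), qz, `+`)
}

#' Generate one paired CT/PET phantom case
#'
#' Fully deterministic given `(spec, case_seed)`: the same inputs always
#' produce bit-identical volumes. CT and PET share shape, spacing and
#' orientation; lesions are spheres in world (mm) coordinates rasterized on
#' the voxel grid, placed inside the body, outside the lungs, and pairwise
#' non-overlapping (with a one-voxel margin so connected components stay
#' separate under 26-connectivity).
#'
#' @param spec A [phantom_spec()].
#' @param case_seed Integer seed for this case.
#' @return List with `ct`, `pet` ([volume3d()]), `lesion_mask`, `lung_mask`
#'   ([mask3d()]), and a `lesions` data frame (centre, radius, SUV).
#' @export
generate_case <- function(spec, case_seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(case_seed, {
    d <- spec$grid_shape
    sp <- spec$spacing
    geo <- phantom_geometry(spec)
    xs <- (seq_len(d[1]) - 0.5) * sp[1]
    ys <- (seq_len(d[2]) - 0.5) * sp[2]
    zs <- (seq_len(d[3]) - 0.5) * sp[3]
    body <- ellipsoid_q(xs, ys, zs, geo$body_c, geo$body_a) <= 1
    lungs <- (ellipsoid_q(xs, ys, zs, geo$lung_c1, geo$lung_a) <= 1 |
              ellipsoid_q(xs, ys, zs, geo$lung_c2, geo$lung_a) <= 1) & body

    # smooth anatomical background profile (fixed shape, per-case amplitude)
    fx <- sin(pi * xs / geo$ext[1])
    fy <- sin(pi * ys / geo$ext[2])
    fz <- cos(pi * zs / geo$ext[3])
    field <- outer(outer(fx, fy), fz)
    amp <- runif(1, 0.05, 0.15)

    n_lesions <- if (spec$lesion_count_range[1] == spec$lesion_count_range[2])
      spec$lesion_count_range[1] else
      sample(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]), 1L)

    lesion_mask <- array(FALSE, d)
    placed <- list()
    margin <- max(sp)
    attempts_budget <- 200L
    for (j in seq_len(n_lesions)) {
      ok <- FALSE
      for (a in seq_len(attempts_budget)) {
        r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        cen <- c(runif(1, geo$body_c[1] - geo$body_a[1], geo$body_c[1] + geo$body_a[1]),
                 runif(1, geo$body_c[2] - geo$body_a[2], geo$body_c[2] + geo$body_a[2]),
                 runif(1, 0.5 * sp[3], geo$ext[3] - 0.5 * sp[3]))
        inside_body <- all(geo$body_a > r) &&
          sum(((cen - geo$body_c) / (geo$body_a - r))^2) <= 1
        clear_lungs <- sum(((cen - geo$lung_c1) / (geo$lung_a + r))^2) > 1 &&
          sum(((cen - geo$lung_c2) / (geo$lung_a + r))^2) > 1
        clear_prev <- all(vapply(placed, function(p)
          sqrt(sum((cen - p$cen)^2)) >= r + p$r + margin, logical(1)))
        if (inside_body && clear_lungs && clear_prev) {
          placed[[j]] <- list(cen = cen, r = r, suv = runif(
            1, spec$lesion_suv_range[1], spec$lesion_suv_range[2]))
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place lesion ", j, " without overlap after ",
             attempts_budget, " attempts; reduce count or radius range")
    }

    ct <- array(spec$air_hu, d)
    ct[body] <- spec$body_hu
    ct[lungs] <- spec$lung_hu
    pet <- array(0, d)
    bg <- spec$background_suv * (1 + amp * field)
    pet[body] <- bg[body]
    pet[lungs] <- 0.3 * bg[lungs]

    lesion_df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                            radius_mm = numeric(0), suv = numeric(0))
    for (p in placed) {
      dist2 <- ellipsoid_q(xs, ys, zs, p$cen, rep(p$r, 3))
      vox <- dist2 <= 1
      if (!any(vox)) { # radius below voxel size: mark the nearest voxel
        idx <- c(which.min(abs(xs - p$cen[1])), which.min(abs(ys - p$cen[2])),
                 which.min(abs(zs - p$cen[3])))
        vox[idx[1], idx[2], idx[3]] <- TRUE
      }
      lesion_mask <- lesion_mask | vox
      ct[vox] <- ct[vox] + 30     # mild anatomical correlate
      pet[vox] <- p$suv           # uptake amplitude independent of HU
      lesion_df <- rbind(lesion_df, data.frame(
        x = p$cen[1], y = p$cen[2], z = p$cen[3], radius_mm = p$r, suv = p$suv))
    }

    if (spec$ct_noise_sd > 0) ct <- ct + array(rnorm(prod(d), 0, spec$ct_noise_sd), d)
    if (spec$pet_noise_sd > 0) pet <- pet + array(rnorm(prod(d), 0, spec$pet_noise_sd), d)
    pet <- pmax(pet, 0)

    list(ct = volume3d(ct, sp, "RAS", "CT-HU"),
         pet = volume3d(array(pet, d), sp, "RAS", "PET-SUV"),
         lesion_mask = mask3d(lesion_mask, sp, "RAS"),
         lung_mask = mask3d(lungs, sp, "RAS"),
         lesions = lesion_df)
  })
}

#' Generate and write a phantom cohort
#'
#' Writes `n` cases as NIfTI files plus a CSV manifest. Per-case seeds are
#' derived deterministically from the cohort seed, so any case (or the whole
#' cohort) can be regenerated from the manifest alone.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of cases (>= 1).
#' @param seed Cohort seed.
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite an existing manifest.
#' @return The manifest data frame (columns `case_id`, `ct_path`, `pet_path`,
#'   `lesion_path`, `lung_path`, `seed`, `n_lesions`), invisibly written to
#'   `manifest.csv`.
#' @export
generate_cohort <- function(spec, n, seed, out_dir, force = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (file.exists(manifest_path) && !force)
    stop("manifest already exists at ", manifest_path, "; use force = TRUE")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cid <- sprintf("case%03d", i)
    cseed <- derive_seed(seed, i)
    case <- generate_case(spec, cseed)
    paths <- file.path(out_dir, paste0(cid, "_", c("ct", "pet", "lesion", "lung"),
                                       ".nii.gz"))
    write_volume(case$ct, paths[1])
    write_volume(case$pet, paths[2])
    write_volume(case$lesion_mask, paths[3])
    write_volume(case$lung_mask, paths[4])
    rows[[i]] <- data.frame(case_id = cid, ct_path = paths[1], pet_path = paths[2],
                            lesion_path = paths[3], lung_path = paths[4],
                            seed = cseed, n_lesions = nrow(case$lesions))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, manifest_path, row.names = FALSE)
  manifest
}
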