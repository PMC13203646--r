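#' Reorient a volume to RAS axis order
#'
#' Permutes and flips the voxel grid so axes run Right, Anterior, Superior.
#' Applying the function twice is a no-op, and the permutation is invertible.
#'
#' @param v A [volume3d()] or [mask3d()].
#' @return The reoriented object.
#' @export
reorient_to_ras <- function(v) {
  code <- vol_orientation(v)
  letters3 <- check_orientation_code(code)
  axis_of <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  flip_of <- c(R = FALSE, L = TRUE, A = FALSE, P = TRUE, S = FALSE, I = TRUE)
  src_axis <- axis_of[letters3]       # which anatomical axis each array axis holds
  perm <- match(1:3, src_axis)        # array axis to place at position 1,2,3
  vals <- unclass(v)
  attributes(vals) <- list(dim = dim(v))
  vals <- aperm(vals, perm)
  flips <- flip_of[letters3][perm]
  idx <- lapply(1:3, function(a) if (flips[a]) rev(seq_len(dim(vals)[a])) else
    seq_len(dim(vals)[a]))
  vals <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  rewrap(v, vals, spacing = vol_spacing(v)[perm], orientation = "RAS")
}

#' Resample a volume to a target voxel spacing
#'
#' Voxel centres are aligned in world coordinates (`world = (i + 0.5) *
#' spacing`), so the physical extent is preserved to within one voxel.
#' Masks must use `mode = "nearest"` so they stay binary.
#'
#' @param v A [volume3d()] or [mask3d()].
#' @param target_spacing Positive mm triple.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @return The resampled object.
#' @export
resample <- function(v, target_spacing,
                     mode = if (inherits(v, "mask3d")) "nearest" else "linear") {
  mode <- match.arg(mode, c("linear", "nearest"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target_spacing must be strictly positive")
  sp <- vol_spacing(v)
  if (isTRUE(all.equal(sp, target_spacing))) return(v)
  new_dim <- pmax(1L, as.integer(round(dim(v) * sp / target_spacing)))
  vals <- cpp_resample3d(array(as.numeric(v), dim(v)), sp, new_dim,
                         target_spacing, as.integer(mode == "nearest"))
  if (inherits(v, "mask3d")) vals <- vals != 0
  rewrap(v, vals, spacing = target_spacing)
}

#' Clip CT to an HU window and normalize to \[-1, 1\]
#'
#' @param v A CT [volume3d()] (`"CT-HU"`).
#' @param hu_window `c(lo, hi)` clipping window in HU.
#' @return A `"normalized-CT"` volume with values in \[-1, 1\].
#' @export
clip_normalize_ct <- function(v, hu_window = c(-1000, 1000)) {
  lo <- hu_window[1]; hi <- hu_window[2]
  if (!all(is.finite(hu_window)) || lo >= hi) stop("invalid HU window")
  vals <- pmin(pmax(array(as.numeric(v), dim(v)), lo), hi)
  vals <- 2 * (vals - lo) / (hi - lo) - 1
  rewrap(v, vals, modality = "normalized-CT")
}

#' Clip PET to a non-negative SUV range
#'
#' Values are clipped to `[0, suv_max]`; no rescaling is applied, since all
#' fidelity metrics are computed in SUV units.
#'
#' @param v A PET [volume3d()].
#' @param suv_max Upper SUV clip (> 0).
#' @return The clipped PET volume (still `"PET-SUV"`).
#' @export
clip_pet_suv <- function(v, suv_max = 30) {
  if (!is.finite(suv_max) || suv_max <= 0) stop("suv_max must be > 0")
  vals <- pmin(pmax(array(as.numeric(v), dim(v)), 0), suv_max)
  rewrap(v, vals)
}

#' Body (foreground) mask from CT
#'
#' Thresholds HU > -500, keeps the largest connected component and fills
#' internal holes, so the lungs remain inside the body mask.
#'
#' @param ct A `"CT-HU"` [volume3d()] (pre-normalization).
#' @param threshold HU threshold separating tissue from air.
#' @return A [mask3d()].
#' @export
body_mask <- function(ct, threshold = -500) {
  if (!identical(vol_modality(ct), "CT-HU"))
    stop("body_mask expects a CT-HU volume")
  fg <- array(as.numeric(ct), dim(ct)) > threshold
  if (!any(fg)) stop("body mask is empty: no voxels above ", threshold, " HU")
  lab <- cpp_label_components(fg, 26L)
  counts <- tabulate(lab[lab > 0])
  keep <- lab == which.max(counts)
  # fill internal holes: background components not touching the grid border
  bgl <- cpp_label_components(!keep, 6L)
  d <- dim(keep)
  border <- unique(c(bgl[c(1, d[1]), , ], bgl[, c(1, d[2]), ], bgl[, , c(1, d[3])]))
  border <- border[border > 0]
  hole <- !keep & !(bgl %in% border)
  keep[hole] <- TRUE
  mask3d(keep, vol_spacing(ct), vol_orientation(ct))
}

#' Threshold-based surrogate lung segmentation
#'
#' Selects voxels below -400 HU inside the body mask and keeps the two
#' largest connected components. This stands in for a trained lung
#' segmentation model: the downstream crop only needs the inferior lung
#' extent, which a threshold rule recovers on lung-like attenuation. A
#' precomputed lung mask can be supplied to [preprocess_case()] instead.
#'
#' @param ct A `"CT-HU"` [volume3d()].
#' @param threshold HU threshold below which voxels are lung candidates.
#' @param connectivity Component connectivity (6, 18 or 26).
#' @return A [mask3d()]; empty (with a warning) if no candidate voxels exist,
#'   single-component (with a warning) if only one is found.
#' @export
surrogate_lung_mask <- function(ct, threshold = -400, connectivity = 26L) {
  if (!identical(vol_modality(ct), "CT-HU"))
    stop("surrogate_lung_mask expects a CT-HU volume")
  body <- body_mask(ct)
  cand <- unclass(body) & (array(as.numeric(ct), dim(ct)) < threshold)
  if (!any(cand)) {
    warning("no lung candidate voxels found; returning an empty lung mask")
    return(mask3d(array(FALSE, dim(ct)), vol_spacing(ct), vol_orientation(ct)))
  }
  lab <- cpp_label_components(cand, as.integer(connectivity))
  counts <- tabulate(lab[lab > 0])
  if (length(counts) < 2L)
    warning("only one lung candidate component found; returning a single-component mask")
  keep_ids <- order(counts, decreasing = TRUE)[seq_len(min(2L, length(counts)))]
  mask3d(array(lab %in% keep_ids, dim(ct)), vol_spacing(ct), vol_orientation(ct))
}

#' Crop bounds from the lung base to the top of the volume
#'
#' The inferior-superior interval starts at the lowest superior-axis index
#' containing lung voxels and extends to the volume top; in-plane axes are
#' untouched. Indices are 0-based, half-open.
#'
#' @param lung_mask A non-empty [mask3d()] in RAS orientation.
#' @return A `crop_bounds` object: list of three `c(lo, hi)` intervals.
#' @export
lung_base_crop_bounds <- function(lung_mask) {
  if (!any(lung_mask))
    stop("empty lung mask: supply an external lung mask to define the crop")
  d <- dim(lung_mask)
  z_any <- apply(unclass(lung_mask), 3, any)
  z0 <- which(z_any)[1] - 1L
  structure(list(c(0L, d[1]), c(0L, d[2]), c(z0, d[3])), class = "crop_bounds")
}

#' Apply crop bounds to a volume or mask
#'
#' @param v A [volume3d()] or [mask3d()].
#' @param bounds A `crop_bounds` object (0-based, half-open).
#' @return The cropped object.
#' @export
apply_crop <- function(v, bounds) {
  stopifnot(inherits(bounds, "crop_bounds"))
  d <- dim(v)
  for (a in 1:3) {
    b <- bounds[[a]]
    if (b[1] < 0 || b[2] > d[a] || b[1] >= b[2]) stop("crop bounds out of range")
  }
  idx <- lapply(1:3, function(a) (bounds[[a]][1] + 1L):bounds[[a]][2])
  rewrap(v, unclass(v)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
}

#' Centre crop / symmetric pad to a fixed grid size
#'
#' Axes larger than the target are centre-cropped; smaller axes are padded
#' symmetrically with `pad_value` (odd remainders go to the far side).
#' Idempotent at fixed parameters.
#'
#' @param v A [volume3d()] or [mask3d()].
#' @param target_shape Integer triple, e.g. `c(96, 96, 64)`.
#' @param pad_value Fill value: -1000 HU for raw CT, -1 for normalized CT,
#'   0 for PET and masks.
#' @return The reshaped object.
#' @export
fixed_size_crop_pad <- function(v, target_shape = c(96L, 96L, 64L),
                                pad_value = 0) {
  target_shape <- as.integer(target_shape)
  if (any(target_shape < 1L)) stop("target_shape must be positive")
  vals <- unclass(v)
  attributes(vals) <- list(dim = dim(v))
  d <- dim(vals)
  # crop pass
  idx <- vector("list", 3)
  for (a in 1:3) {
    if (d[a] > target_shape[a]) {
      start <- (d[a] - target_shape[a]) %/% 2L
      idx[[a]] <- (start + 1L):(start + target_shape[a])
    } else idx[[a]] <- seq_len(d[a])
  }
  vals <- vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  d <- dim(vals)
  if (any(d < target_shape)) {
    out <- array(pad_value, target_shape)
    lo <- (target_shape - d) %/% 2L
    out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- vals
    vals <- out
  }
  if (inherits(v, "mask3d")) vals <- vals != 0
  rewrap(v, vals)
}

#' Full anatomy-guided preprocessing of one paired case
#'
#' Composes the standardization pipeline: RAS reorientation, resampling to a
#' common spacing, lung-base-to-head cropping (from a supplied or surrogate
#' lung mask), fixed-size crop/pad, CT clip + normalization, and PET SUV
#' clipping. The body evaluation mask is computed on the cropped CT before
#' normalization.
#'
#' @param ct CT [volume3d()] (`"CT-HU"`).
#' @param pet PET [volume3d()] (`"PET-SUV"`), aligned with `ct`.
#' @param lung_mask Optional precomputed lung [mask3d()]; if `NULL`, the
#'   surrogate segmenter is used.
#' @param lesion_mask Optional lesion [mask3d()] carried through the same
#'   geometry operations.
#' @param target_spacing Common voxel spacing in mm.
#' @param target_shape Fixed grid size after crop/pad.
#' @param hu_window CT clip window.
#' @param suv_max PET SUV clip.
#' @return List with `ct_hu`, `ct_norm`, `pet`, `body_mask`, `lung_mask`,
#'   and (if given) `lesion_mask`, all aligned on `target_shape`.
#' @export
preprocess_case <- function(ct, pet, lung_mask = NULL, lesion_mask = NULL,
                            target_spacing = c(2, 2, 3),
                            target_shape = c(96L, 96L, 64L),
                            hu_window = c(-1000, 1000), suv_max = 30) {
  ct <- reorient_to_ras(ct)
  pet <- reorient_to_ras(pet)
  ct <- resample(ct, target_spacing, "linear")
  pet <- resample(pet, target_spacing, "linear")
  if (!is.null(lung_mask))
    lung_mask <- resample(reorient_to_ras(lung_mask), target_spacing, "nearest")
  else
    lung_mask <- surrogate_lung_mask(ct)
  if (!is.null(lesion_mask))
    lesion_mask <- resample(reorient_to_ras(lesion_mask), target_spacing, "nearest")
  bounds <- lung_base_crop_bounds(lung_mask)
  ct <- apply_crop(ct, bounds)
  pet <- apply_crop(pet, bounds)
  lung_mask <- apply_crop(lung_mask, bounds)
  if (!is.null(lesion_mask)) lesion_mask <- apply_crop(lesion_mask, bounds)
  ct <- fixed_size_crop_pad(ct, target_shape, pad_value = -1000)
  pet <- fixed_size_crop_pad(pet, target_shape, pad_value = 0)
  lung_mask <- fixed_size_crop_pad(lung_mask, target_shape, pad_value = 0)
  if (!is.null(lesion_mask))
    lesion_mask <- fixed_size_crop_pad(lesion_mask, target_shape, pad_value = 0)
  B <- body_mask(ct)
  out <- list(ct_hu = ct,
              ct_norm = clip_normalize_ct(ct, hu_window),
              pet = clip_pet_suv(pet, suv_max),
              body_mask = B, lung_mask = lung_mask)
  if (!is.null(lesion_mask)) out$lesion_mask <- lesion_mask
  out
}
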