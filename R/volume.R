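#' 3D scalar volume with geometry metadata
#'
#' A `volume3d` is a plain 3D numeric array carrying voxel spacing (mm),
#' an axis-orientation code (e.g. `"RAS"`), and a modality tag that records
#' which intensity scale the voxels live on: Hounsfield units (`"CT-HU"`),
#' standardized uptake values (`"PET-SUV"`), or CT normalized to \[-1, 1\]
#' (`"normalized-CT"`).
#'
#' @param values 3D numeric array.
#' @param spacing Positive numeric triple, voxel edge lengths in mm.
#' @param orientation Three-letter axis code made of one of R/L, one of A/P,
#'   one of S/I per axis (e.g. `"RAS"`, `"LPS"`).
#' @param modality One of `"CT-HU"`, `"PET-SUV"`, `"normalized-CT"`.
#' @return A `volume3d` object.
#' @export
volume3d <- function(values, spacing, orientation = "RAS", modality = "CT-HU") {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be a strictly positive mm triple")
  modality <- match.arg(modality, c("CT-HU", "PET-SUV", "normalized-CT"))
  check_orientation_code(orientation)
  structure(values,
            spacing = spacing, orientation = orientation, modality = modality,
            class = "volume3d")
}

#' Binary 3D mask aligned to a volume
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @inheritParams volume3d
#' @return A `mask3d` object (logical array with geometry attributes).
#' @export
mask3d <- function(values, spacing, orientation = "RAS") {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  v <- array(as.logical(values), dim = dim(values))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  check_orientation_code(orientation)
  structure(v, spacing = spacing, orientation = orientation, class = "mask3d")
}

check_orientation_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 3L)
    stop("orientation code must be a 3-letter string, got: ", deparse(code))
  letters3 <- strsplit(toupper(code), "")[[1]]
  axes <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  if (any(!letters3 %in% names(axes)))
    stop("unknown orientation code: ", code)
  if (length(unique(axes[letters3])) != 3L)
    stop("degenerate orientation code: ", code)
  invisible(letters3)
}

#' Geometry and modality accessors
#'
#' @param v A [volume3d()] or [mask3d()].
#' @return Voxel spacing (mm triple), orientation code, or modality tag.
#' @export
vol_spacing <- function(v) attr(v, "spacing")

#' @rdname vol_spacing
#' @export
vol_orientation <- function(v) attr(v, "orientation")

#' @rdname vol_spacing
#' @export
vol_modality <- function(v) attr(v, "modality")

# Rebuild a volume3d/mask3d around new voxel data, keeping (or overriding)
# geometry attributes.
rewrap <- function(template, values, spacing = NULL, orientation = NULL,
                   modality = NULL) {
  spacing <- spacing %||% vol_spacing(template)
  orientation <- orientation %||% vol_orientation(template)
  if (inherits(template, "mask3d")) {
    mask3d(values, spacing, orientation)
  } else {
    volume3d(values, spacing, orientation,
             modality %||% vol_modality(template))
  }
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume3d %s> %dx%dx%d voxels, spacing %s mm, %s, range [%.3g, %.3g]\n",
              vol_modality(x), d[1], d[2], d[3],
              paste(signif(vol_spacing(x), 4), collapse = "x"),
              vol_orientation(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mask3d> %dx%dx%d voxels, spacing %s mm, %s, %d foreground\n",
              d[1], d[2], d[3], paste(signif(vol_spacing(x), 4), collapse = "x"),
              vol_orientation(x), sum(x)))
  invisible(x)
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are written with an RAS-positive diagonal affine built from the
#' voxel spacing. Masks are written as 0/1 integers.
#'
#' @param v A `volume3d` or `mask3d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  vals <- if (inherits(v, "mask3d")) array(as.integer(v), dim(v)) else
    array(as.numeric(v), dim(v))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol_spacing(v)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume or mask from NIfTI
#'
#' @param path NIfTI file path.
#' @param modality Modality tag to attach (`"CT-HU"`, `"PET-SUV"`,
#'   `"normalized-CT"`), or `"mask"` to read a binary mask.
#' @return A `volume3d` or `mask3d`.
#' @export
read_volume <- function(path, modality = "CT-HU") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  code <- tryCatch(RNifti::orientation(img), error = function(e) "RAS")
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  if (identical(modality, "mask")) {
    mask3d(vals != 0, sp, code)
  } else {
    volume3d(vals, sp, code, modality)
  }
}
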