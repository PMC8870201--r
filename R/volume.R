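#' @useDynLib radiopcr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate approx cor cov dist ecdf fivenum mad median
#'   pnorm prcomp predict quantile rbinom rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

MODALITIES <- c("T2", "DWI", "CECT")

#' Construct a 3D image volume
#'
#' An `image_volume` is a 3D scalar grid with anisotropic voxel spacing in
#' millimetres and a physical origin. Voxel indices are 0-based in the
#' physical mapping: position = origin + index * spacing.
#'
#' @param voxels 3D numeric array of intensities (all finite).
#' @param spacing numeric length-3, voxel size (dx, dy, dz) in mm, all > 0.
#' @param origin numeric length-3, physical coordinates of voxel (0,0,0).
#' @param modality one of `"T2"`, `"DWI"`, `"CECT"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         modality = "T2") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array, got ", length(dim(voxels)), " dimensions")
  if (any(dim(voxels) < 1L)) stop("grid must have >= 1 voxel in each axis")
  if (!all(is.finite(voxels))) stop("intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  modality <- match.arg(modality, MODALITIES)
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), modality = modality),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' Any nonzero voxel is treated as foreground.
#'
#' @param voxels 3D array; coerced to 0/1 integer.
#' @inheritParams image_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("mask voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("mask values must be finite")
  stor <- array(as.integer(voxels != 0), dim = dim(voxels))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(list(voxels = stor, spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm\n", x$modality,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d foreground voxels\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

.nifti_affine <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`) with 3D data.
#' @param modality modality label to attach.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = "T2") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stop("expected 3D NIfTI data in ", path,
                             ", got ", length(dm), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in ", path)
  orig <- as.numeric(RNifti::xform(img)[1:3, 4])
  image_volume(array(as.numeric(img), dim = dm), spacing = sp,
               origin = orig, modality = modality)
}

#' Read a NIfTI ROI mask
#'
#' @inheritParams read_volume
#' @return An [roi_mask()]; any nonzero voxel is foreground.
#' @export
read_mask <- function(path) {
  v <- read_volume(path, modality = "T2")
  roi_mask(v$voxels, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or mask to NIfTI-1
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  dat <- if (inherits(x, "roi_mask")) array(as.numeric(x$voxels), dim(x$voxels))
         else x$voxels
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::qform(img) <- structure(.nifti_affine(x$spacing, x$origin), code = 2L)
  RNifti::sform(img) <- structure(.nifti_affine(x$spacing, x$origin), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that a volume and mask share the same geometry
#'
#' Shapes must match exactly and spacing within 1e-6 mm.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @return invisibly `TRUE`; errors naming the mismatching field otherwise.
#' @export
validate_pair <- function(volume, mask) {
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("shape mismatch: volume ", paste(dim(volume$voxels), collapse = "x"),
         " vs mask ", paste(dim(mask$voxels), collapse = "x"))
  if (any(abs(volume$spacing - mask$spacing) > 1e-6))
    stop("spacing mismatch: volume (", paste(volume$spacing, collapse = ", "),
         ") vs mask (", paste(mask$spacing, collapse = ", "), ")")
  invisible(TRUE)
}

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks score 1 (perfect agreement of
#' nothing); empty vs non-empty scores 0.
#'
#' @param a,b [roi_mask()] objects on the same grid.
#' @return overlap ratio in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("shape mismatch between masks")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  inter <- sum(a$voxels & b$voxels)
  2 * inter / (na + nb)
}

#' Foreground intensities in deterministic raster order
#'
#' Order is x fastest, then y, then z (z-major raster scan).
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()] on the same grid with >= 1 foreground voxel.
#' @return list with `values` (numeric) and `coords` (n x 3 matrix of 1-based
#'   voxel indices).
#' @export
roi_intensities <- function(volume, mask) {
  validate_pair(volume, mask)
  keep <- which(mask$voxels != 0L)
  if (length(keep) == 0L) stop("empty mask: no foreground voxels")
  list(values = as.numeric(volume$voxels[keep]),
       coords = arrayInd(keep, dim(mask$voxels)))
}
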