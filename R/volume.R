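#' Construct a 3D image volume
#'
#' A minimal container for a 3D scalar grid of CT intensities in Hounsfield
#' units (HU), together with the physical voxel spacing in millimetres and
#' the physical position of voxel `(1,1,1)`.  Voxel indices are 1-based in R
#' and the axis order of the array is fixed as (x, y, z).
#'
#' @param voxels 3D numeric array of intensities (HU). Must be finite.
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm;
#'   all strictly positive.
#' @param origin numeric length-3, physical coordinates (mm) of the centre
#'   of voxel `(1,1,1)`.
#' @return An object of class `image_volume`: a list with elements
#'   `voxels`, `spacing`, `origin`.
#' @seealso [roi_mask()], [read_volume()], [write_volume()]
#' @export
#' @examples
#' v <- image_volume(array(rnorm(8 * 8 * 8, 50, 10), dim = c(8, 8, 8)))
#' v$spacing
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-dimensional array, got ",
         if (is.array(voxels)) paste0(length(dim(voxels)), " dimensions")
         else class(voxels)[1], call. = FALSE)
  }
  if (!all(is.finite(voxels))) {
    stop("image volume contains non-finite intensities", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel sizes in mm",
         call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin))) {
    stop("`origin` must be 3 finite physical coordinates in mm", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary region-of-interest mask
#'
#' A binary grid marking one lesion, aligned voxel-for-voxel with an
#' [image_volume()].  Any non-zero input value is treated as foreground.
#'
#' @param voxels 3D array; coerced to 0/1 (non-zero means inside the ROI).
#' @inheritParams image_volume
#' @return An object of class `roi_mask` with elements `voxels` (logical
#'   array), `spacing`, `origin`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-dimensional array", call. = FALSE)
  }
  if (anyNA(voxels)) stop("mask contains missing values", call. = FALSE)
  vox <- array(voxels != 0, dim = dim(voxels))
  if (!any(vox)) stop("empty mask: no foreground voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive voxel sizes in mm",
         call. = FALSE)
  }
  structure(list(voxels = vox, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  intensity range [", signif(min(x$voxels), 5), ", ",
      signif(max(x$voxels), 5), "] HU\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

check_same_grid <- function(a, b, what = "mask") {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop(what, " grid (", paste(dim(a$voxels), collapse = "x"),
         ") does not match reference grid (",
         paste(dim(b$voxels), collapse = "x"), ")", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6) {
    stop(what, " spacing does not match reference spacing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Voxel spacing is taken from the file header (`pixdim`); intensities are
#' returned unchanged.  Only 3D images are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D image, got ", length(dim(arr)),
         " dimensions in ", path, call. = FALSE)
  }
  if (!all(is.finite(arr))) {
    stop("non-finite voxel intensities in ", path, call. = FALSE)
  }
  sp <- RNifti::pixdim(img)[1:3]
  hdr <- RNifti::niftiHeader(img)
  org <- as.numeric(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  image_volume(array(as.numeric(arr), dim = dim(arr)), spacing = sp,
               origin = org)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' @param volume an [image_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, c("image_volume", "roi_mask"))) {
    stop("`volume` must be an image_volume or roi_mask", call. = FALSE)
  }
  arr <- volume$voxels
  if (is.logical(arr)) arr <- array(as.numeric(arr), dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI mask from a NIfTI-1 file
#'
#' Values are binarized (non-zero is foreground).  The grid must match the
#' reference volume exactly in shape and spacing; an empty mask is an error.
#'
#' @param path path to the mask file.
#' @param reference the [image_volume()] the mask belongs to.
#' @return An [roi_mask()] on the reference grid.
#' @export
read_mask <- function(path, reference) {
  if (!inherits(reference, "image_volume")) {
    stop("`reference` must be an image_volume", call. = FALSE)
  }
  raw <- read_volume(path)
  m <- roi_mask(raw$voxels != 0, spacing = raw$spacing, origin = raw$origin)
  check_same_grid(m, reference, what = "mask")
  m
}

#' Number of foreground voxels in a mask
#' @param mask an [roi_mask()].
#' @return integer count.
#' @export
mask_voxel_count <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  sum(mask$voxels)
}
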