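#' Voxel volume and ROI mask containers
#'
#' A `voxel_volume` is a plain 3D numeric array of attenuation values
#' (Hounsfield units) carrying the physical voxel spacing (mm) and scanner
#' origin as attributes. An `roi_mask` is a logical 3D array of the same
#' shape marking the region of interest. Both are deliberately lightweight:
#' all feature computations depend only on the masked voxel content and the
#' spacing.
#'
#' @param intensities 3D numeric array of attenuation values (HU).
#' @param spacing Positive length-3 numeric, voxel spacing in mm per axis.
#' @param origin Length-3 numeric, physical position of the first voxel.
#' @return `voxel_volume()` returns an object of class `voxel_volume`;
#'   `roi_mask()` an object of class `roi_mask`.
#' @examples
#' vol <- voxel_volume(array(rnorm(27), c(3, 3, 3)))
#' msk <- roi_mask(array(TRUE, c(3, 3, 3)))
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3) {
    stop("`intensities` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("`intensities` must be finite", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  }
  structure(intensities,
    spacing = spacing, origin = as.numeric(origin),
    class = c("voxel_volume", "array")
  )
}

#' @param mask 3D logical (or 0/1) array.
#' @rdname voxel_volume
#' @export
roi_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3) {
    stop("`mask` must be a 3D array", call. = FALSE)
  }
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask has no foreground voxel", call. = FALSE)
  structure(mask, class = c("roi_mask", "array"))
}

#' @rdname voxel_volume
#' @param x a `voxel_volume`.
#' @export
vol_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask))) {
    stop("volume and mask shapes differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over [RNifti] keeping the spacing attribute in step with
#' the NIfTI pixdim. Masks round-trip as 0/1 volumes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti()` returns a [voxel_volume()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_volume(array(as.numeric(img), dim(img)[1:3]),
    spacing = RNifti::pixdim(img)[1:3]
  )
}

#' @param volume a [voxel_volume()] (or 0/1 array for masks).
#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(unclass(volume) * 1.0)
  RNifti::pixdim(img) <- vol_spacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k / sum(k)
}

smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  out <- conv3d_sep(as.numeric(arr), dim(arr), gaussian_kernel_1d(sigma))
  array(out, dim(arr))
}
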