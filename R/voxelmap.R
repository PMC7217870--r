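#' Construct a voxel map
#'
#' A 3D scalar field on a fixed voxel grid: a numeric array with an optional
#' logical mask (values outside the mask are NA) and an isotropic voxel size
#' carried for NIfTI export.
#'
#' @param data 3D numeric array.
#' @param mask optional logical array of the same shape.
#' @param voxel_size voxel edge length in mm (default 3).
#' @return object of class \code{voxel_map}.
#' @export
as_voxel_map <- function(data, mask = NULL, voxel_size = 3) {
  data <- as.array(data)
  stop_if_not(length(dim(data)) == 3L, "voxel map must be a 3D array")
  if (!is.null(mask)) {
    stop_if_not(identical(dim(mask), dim(data)), "mask grid mismatch")
    data[!mask] <- NA_real_
  }
  structure(data, mask = mask, voxel_size = voxel_size, class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat("voxel map", paste(dim(x), collapse = " x "), "at",
      attr(x, "voxel_size"), "mm; ",
      sum(!is.na(x)), "defined voxels\n")
  invisible(x)
}

#' Write a voxel map (or 4D array) as NIfTI-1
#'
#' The grid descriptor is stored in the header affine as an isotropic scaling
#' by the voxel size.
#'
#' @param x a \code{voxel_map}, 3D, or 4D array.
#' @param file output path (.nii or .nii.gz).
#' @param voxel_size voxel edge length in mm (taken from the map when
#'   available).
#' @export
write_voxel_map <- function(x, file, voxel_size = NULL) {
  voxel_size <- voxel_size %||% attr(x, "voxel_size") %||% 3
  arr <- unclass(x)
  attributes(arr) <- list(dim = dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, min(3L, length(dim(arr))))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI volume as a voxel map
#'
#' @param file path to a NIfTI file.
#' @param mask optional logical array applied after reading.
#' @return a \code{voxel_map} (3D input) or plain array (4D input).
#' @export
read_voxel_map <- function(file, mask = NULL) {
  img <- RNifti::readNifti(file)
  vs <- RNifti::pixdim(img)[1]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 3L) as_voxel_map(arr, mask = mask, voxel_size = vs) else arr
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves each axis with a unit-sum truncated Gaussian kernel
#' (zero-padding at the edges). FWHM is given in voxels per axis.
#'
#' @param x 3D numeric array.
#' @param fwhm_vox FWHM in voxel units (scalar or length 3). 0 disables
#'   smoothing.
#' @return smoothed array.
#' @export
gaussian_smooth_3d <- function(x, fwhm_vox) {
  fwhm_vox <- rep_len(fwhm_vox, 3L)
  if (all(fwhm_vox <= 0)) return(x)
  for (ax in 1:3) {
    if (fwhm_vox[ax] <= 0) next
    K <- smoothing_kernel_matrix(dim(x)[ax], fwhm_vox[ax])
    x <- apply_along_axis(x, ax, K)
  }
  x
}

# per-voxel SD of unit-variance white noise after gaussian_smooth_3d:
# variance = separable convolution of ones with the squared kernels
smoothed_noise_sd <- function(dims, fwhm_vox) {
  fwhm_vox <- rep_len(fwhm_vox, 3L)
  v <- array(1, dims)
  for (ax in 1:3) {
    if (fwhm_vox[ax] <= 0) next
    K <- smoothing_kernel_matrix(dims[ax], fwhm_vox[ax])
    v <- apply_along_axis(v, ax, K^2)
  }
  sqrt(v)
}

smoothing_kernel_matrix <- function(n, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  r <- ceiling(3 * sigma)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- matrix(0, n, n)
  inside <- abs(d) <= r
  K[inside] <- w[d[inside] + r + 1]
  K
}

# multiply kernel matrix K along one axis of a 3D array
apply_along_axis <- function(x, axis, K) {
  dims <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- K %*% matrix(xp, nrow = dims[axis])
  dim(m) <- dims[perm]
  aperm(m, order(perm))
}
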