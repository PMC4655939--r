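#' Masked 4D image container
#'
#' An `image4d` stores one subject's voxel-by-time data restricted to an
#' in-brain mask, together with the grid geometry needed to reconstruct
#' volumes. The data matrix has one row per in-mask voxel (column-major
#' order of the mask) and one column per timepoint.
#'
#' @param data numeric matrix, voxels (rows) by timepoints (columns); rows
#'   must match the number of `TRUE` voxels in `mask`.
#' @param mask logical 3D array marking in-brain voxels.
#' @param tr repetition time in seconds (time between volumes).
#' @param voxel_mm numeric length-3, voxel size along each axis in mm.
#' @return An object of class `image4d`.
#' @export
image4d <- function(data, mask, tr, voxel_mm = c(3, 3, 3)) {
  stopifnot(is.matrix(data), is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim(mask))
  if (nrow(data) != sum(mask))
    stop("data rows (", nrow(data), ") must equal in-mask voxel count (",
         sum(mask), ")")
  if (ncol(data) < 2) stop("need at least 2 timepoints")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be positive")
  structure(
    list(data = data, mask = mask, dim = dim(mask), tr = tr,
         voxel_mm = as.numeric(voxel_mm)),
    class = "image4d")
}

#' @export
print.image4d <- function(x, ...) {
  cat("image4d: grid ", paste(x$dim, collapse = "x"),
      ", ", ncol(x$data), " volumes, TR ", x$tr, " s, ",
      nrow(x$data), " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Number of timepoints of an image4d
#' @param img an `image4d`.
#' @return integer number of volumes.
#' @export
n_timepoints <- function(img) ncol(img$data)

#' Embed a masked voxel vector (or matrix) into full 3D/4D arrays
#'
#' @param values numeric vector (one value per in-mask voxel) or matrix
#'   (voxels by frames).
#' @param mask logical 3D array.
#' @param fill value used outside the mask.
#' @return 3D array (vector input) or 4D array (matrix input).
#' @export
as_volume <- function(values, mask, fill = 0) {
  if (is.matrix(values)) {
    out <- array(fill, c(dim(mask), ncol(values)))
    for (j in seq_len(ncol(values))) {
      v <- array(fill, dim(mask)); v[mask] <- values[, j]
      out[, , , j] <- v
    }
    return(out)
  }
  v <- array(fill, dim(mask))
  v[mask] <- values
  v
}

#' Extract in-mask values from a full volume
#' @param vol 3D array on the same grid as `mask`.
#' @param mask logical 3D array.
#' @return numeric vector of in-mask values.
#' @export
mask_values <- function(vol, mask) {
  stopifnot(all(dim(vol) == dim(mask)))
  vol[mask]
}

# ---- NIfTI / text I/O ------------------------------------------------------

#' Write an image4d to a NIfTI-1 file
#' @param img an `image4d`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image4d <- function(img, path) {
  arr <- as_volume(img$data, img$mask)
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- c(img$voxel_mm, img$tr)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read an image4d from a NIfTI-1 file
#' @param path NIfTI file with 4 dimensions.
#' @param mask logical 3D array; if `NULL`, voxels with nonzero temporal
#'   variance or nonzero mean are taken as in-mask.
#' @return an `image4d`.
#' @export
read_image4d <- function(path, mask = NULL) {
  nim <- RNifti::readNifti(path)
  arr <- array(as.numeric(nim), dim(nim))
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI image")
  pd <- RNifti::pixdim(nim)
  if (is.null(mask)) {
    m <- apply(arr, 1:3, function(v) any(v != 0))
    mask <- array(m, dim(arr)[1:3])
  }
  # logical index recycles over frames; column-major order keeps frames contiguous
  dat <- matrix(arr[rep(mask, dim(arr)[4])], nrow = sum(mask))
  image4d(dat, mask, tr = pd[4], voxel_mm = pd[1:3])
}

#' Write a 3D map (or mask) as NIfTI
#' @param vol 3D numeric/logical array.
#' @param path output path.
#' @param voxel_mm voxel size, mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = c(3, 3, 3)) {
  nim <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(nim) <- voxel_mm
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Read a 3D map from NIfTI
#' @param path NIfTI file.
#' @return 3D numeric array.
#' @export
read_volume <- function(path) {
  nim <- RNifti::readNifti(path)
  array(as.numeric(nim), dim(nim)[1:3])
}

#' Write motion parameters as whitespace-delimited text
#' @param motion T-by-6 numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  stopifnot(ncol(motion) == 6)
  utils::write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motion parameters from text
#' @param path whitespace-delimited file with 6 columns.
#' @return T-by-6 matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) stop("motion file must have 6 columns, got ", ncol(m))
  dimnames(m) <- NULL
  m
}
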