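# Thin NIfTI-1 volume layer over RNifti. A "volume" in this package is a 3-D
# numeric array carrying its voxel dimensions (mm); RNifti's niftiImage
# satisfies that, and plain arrays are accepted with explicit voxel dims.

#' Read and write single-volume NIfTI files
#'
#' `readVolume` loads one 3-D NIfTI-1 file; `writeVolume` stores a 3-D array
#' with its voxel dimensions. These wrap RNifti and exist so the rest of the
#' engine has one place for file I/O.
#'
#' @param path File path (`.nii`).
#' @param data 3-D numeric array.
#' @param voxel_dims_mm Numeric length-3 voxel sizes in mm.
#' @return `readVolume`: a `niftiImage` (3-D array subclass).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a single 3-D volume: ", path)
  img
}

#' @rdname readVolume
#' @export
writeVolume <- function(data, path, voxel_dims_mm = voxelDims(data)) {
  img <- RNifti::asNifti(unclass(as.array(data)))
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel dimensions of a volume
#'
#' @param x A `niftiImage` or plain array (plain arrays default to 1 mm
#'   isotropic).
#' @return Numeric length-3 voxel sizes in mm.
#' @export
voxelDims <- function(x) {
  if (inherits(x, "niftiImage")) {
    pd <- RNifti::pixdim(x)
    return(as.numeric(pd[seq_len(3)]))
  }
  c(1, 1, 1)
}

# Read a boolean ROI mask on the functional grid.
readMask <- function(path, name = basename(path)) {
  img <- readVolume(path)
  mask <- as.array(img) > 0.5
  if (!any(mask)) stop("mask has no voxels: ", path)
  structure(list(name = name, mask = mask, voxel_dims_mm = voxelDims(img)),
            class = "roiMask")
}

#' Construct an ROI mask object
#'
#' @param mask Logical 3-D array (at least one `TRUE` voxel).
#' @param name Label for the ROI.
#' @param voxel_dims_mm Voxel sizes in mm.
#' @return A `roiMask` object.
#' @export
roiMask <- function(mask, name = "roi", voxel_dims_mm = c(1, 1, 1)) {
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask has no voxels")
  structure(list(name = name, mask = mask, voxel_dims_mm = voxel_dims_mm),
            class = "roiMask")
}

#' @export
print.roiMask <- function(x, ...) {
  cat(sprintf("roiMask '%s': %d voxels on %s grid\n", x$name, sum(x$mask),
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Mean intensity within an ROI
#'
#' @param volume 3-D array.
#' @param mask A `roiMask` or logical array on the same grid.
#' @return Scalar mean of the in-mask voxels.
#' @export
roiMean <- function(volume, mask) {
  m <- if (inherits(mask, "roiMask")) mask$mask else mask
  stopifnot(identical(dim(volume)[1:3], dim(m)[1:3]))
  mean(as.array(volume)[m])
}
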