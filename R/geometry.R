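#' Volume geometry of a 3D voxel grid
#'
#' Describes the sampling grid all masks live on: voxel counts per axis,
#' physical voxel spacing in millimetres, and the origin of the voxel-to-mm
#' mapping. Voxel centres sit at integer (1-based) indices mapped through
#' \code{origin + (index - 1) * spacing}; a voxel is the whole spacing-sized
#' box around its centre.
#'
#' @param dims Integer vector of length 3, voxels per axis (all positive).
#' @param spacing Numeric vector of length 3, mm per voxel per axis (all
#'   positive). The FLAIR protocol this pipeline was designed around uses
#'   0.86 x 0.86 x 3.00 mm; phantoms default to finer, less anisotropic grids.
#' @param origin Numeric vector of length 3, mm coordinate of the centre of
#'   voxel (1,1,1).
#' @return An object of class \code{vol_geom}.
#' @export
vol_geom <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || anyNA(dims) || any(dims < 1L))
    stop("dims must be 3 positive integers")
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0) ||
      any(!is.finite(spacing)))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || anyNA(origin))
    stop("origin must be 3 finite values (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "vol_geom")
}

#' @export
print.vol_geom <- function(x, ...) {
  cat(sprintf("<vol_geom> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

voxel_volume_mm3 <- function(geometry) prod(geometry$spacing)

#' Test two grids for compatible geometry
#'
#' Masks of one participant must share dims and spacing exactly (the pipeline
#' assumes pre-registered inputs); a small tolerance absorbs header rounding.
#'
#' @param a,b \code{vol_geom} objects.
#' @param tol Relative tolerance on spacing/origin.
#' @return Logical scalar.
#' @export
geom_compatible <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(a$spacing, b$spacing)) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin)))
}

stop_if_geom_mismatch <- function(a, b, what = "masks") {
  if (!geom_compatible(a, b))
    stop(sprintf("geometry mismatch: %s must share dims and spacing", what))
  invisible(TRUE)
}

#' Construct a binary mask
#'
#' @param data Logical (or coercible 0/1) 3D array matching the geometry.
#' @param geometry A \code{\link{vol_geom}}.
#' @return An object of class \code{binary_mask} with elements \code{data}
#'   (logical array) and \code{geometry}.
#' @export
binary_mask <- function(data, geometry) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  if (!identical(as.integer(dim(data)), geometry$dims))
    stop("mask dimensions do not match geometry dims")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask occupancy must be strictly binary (no NA)")
  structure(list(data = data, geometry = geometry), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d / %d voxels set (%.4g ml)\n",
              sum(x$data), prod(x$geometry$dims), mask_volume_ml(x)))
  print(x$geometry)
  invisible(x)
}

#' Number of true voxels in a mask
#' @param mask A \code{binary_mask}.
#' @return Integer count.
#' @export
n_voxels <- function(mask) sum(mask$data)

#' Mask volume in millilitres
#'
#' Volume is the true-voxel count times the physical voxel volume
#' (product of spacings, mm^3), divided by 1000.
#'
#' @param mask A \code{binary_mask}.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$data) * voxel_volume_mm3(mask$geometry) / 1000
}

#' Read a NIfTI volume as a binary mask
#'
#' Voxels with intensity strictly greater than \code{threshold} become true.
#' The default 0.5 both passes hard 0/1 masks through unchanged and binarizes
#' probabilistic lesion maps at even odds. Spacing is taken from the header
#' pixdim; the source image is retained so that derived masks can be written
#' with an identical header.
#'
#' @param path Path to a .nii or .nii.gz scalar 3D volume.
#' @param threshold Binarization threshold (value > threshold is lesion).
#' @return A \code{\link{binary_mask}} carrying a \code{nifti_ref} attribute.
#' @export
read_mask <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop(sprintf("expected a 3D volume, got %d dimensions (header field dim): %s",
                 length(d), path))
  } else {
    img2 <- as.array(img)
  }
  pd <- abs(RNifti::pixdim(img)[1:3])
  if (anyNA(pd) || any(pd <= 0))
    stop("non-positive voxel spacing in header field pixdim: ", path)
  geom <- vol_geom(d, pd)
  m <- binary_mask(array(img2 > threshold, dim = d), geom)
  attr(m, "nifti_ref") <- img
  m
}

#' Write a mask (or integer label volume) as NIfTI
#'
#' When the mask was loaded from disk (or \code{reference} is given), the
#' source header, including the affine, is copied verbatim; otherwise a
#' diagonal affine is built from the grid spacing and origin.
#'
#' @param x A \code{binary_mask}, or an integer array (e.g. lesion-type codes
#'   1 = periventricular, 2 = confluent, 3 = deep) plus \code{geometry}.
#' @param path Output path (.nii or .nii.gz).
#' @param geometry Required when \code{x} is a bare array.
#' @param reference Optional \code{niftiImage} (or mask with a
#'   \code{nifti_ref} attribute) whose header is copied.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(x, path, geometry = NULL, reference = NULL) {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$data), dim = x$geometry$dims)
    geometry <- x$geometry
    if (is.null(reference)) reference <- attr(x, "nifti_ref")
  } else {
    arr <- x
    if (is.null(geometry)) stop("geometry is required for a bare array")
    storage.mode(arr) <- "integer"
  }
  if (inherits(reference, "binary_mask")) reference <- attr(reference, "nifti_ref")
  if (!is.null(reference)) {
    img <- RNifti::asNifti(arr, reference = reference, datatype = "int16")
  } else {
    attr(arr, "pixdim") <- geometry$spacing
    img <- RNifti::asNifti(arr, datatype = "int16")
    aff <- diag(c(geometry$spacing, 1))
    aff[1:3, 4] <- geometry$origin
    RNifti::`sform<-`(img, structure(aff, code = 2L))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Connected components of a binary mask
#'
#' Deterministic labelling in column-major scan order: the component holding
#' the first true voxel in array order gets label 1. Connectivity 26 (the
#' default throughout the pipeline) joins voxels sharing a face, edge or
#' corner; 6 joins faces only.
#'
#' @param mask A \code{binary_mask}.
#' @param connectivity 6 or 26.
#' @return An object of class \code{labeled_components}: \code{labels}
#'   (integer array, 0 = background), \code{n} components, the geometry and
#'   connectivity used.
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  lab <- .cc_label(as.logical(mask$data), mask$geometry$dims,
                   as.integer(connectivity))
  n <- attr(lab, "n_components")
  labels <- array(as.integer(lab), dim = mask$geometry$dims)
  structure(list(labels = labels, n = n, connectivity = connectivity,
                 geometry = mask$geometry),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d components (connectivity %d)\n",
              x$n, x$connectivity))
  invisible(x)
}

#' Euclidean distance field of a mask
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest true
#' voxel centre of the reference mask, honouring anisotropic spacing via a
#' separable lower-envelope transform. Zero exactly on the mask.
#'
#' @param reference A nonempty \code{binary_mask}.
#' @return Object of class \code{distance_field}: \code{values} (mm array)
#'   and \code{geometry}.
#' @export
distance_field <- function(reference) {
  if (n_voxels(reference) == 0L)
    stop("distance field of an empty reference mask is undefined")
  d2 <- .edt_sq(as.logical(reference$data), reference$geometry$dims,
                reference$geometry$spacing)
  structure(list(values = array(sqrt(d2), dim = reference$geometry$dims),
                 geometry = reference$geometry),
            class = "distance_field")
}
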