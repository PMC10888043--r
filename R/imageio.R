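# Volume I/O and intensity preprocessing.
#
# Intensity normalization follows the two-sided winsorization reading of a
# "bandpass" outlier filter: voxel values below the lower-tail empirical
# quantile (default 0.1%) are raised to it, values above the (1 - upper_tail)
# quantile (default upper tail 10%) are clipped to it, and the clipped range is
# affinely mapped to [0, 1]. Clip bounds are order statistics (not interpolated
# quantiles) so that the operation is exactly idempotent.

#' Construct an image volume
#'
#' A light container for one modality's voxel grid: a 3-D array indexed
#' (z, y, x), the voxel spacing in millimetres, the modality tag and a subject
#' identifier.
#'
#' @param voxels 3-D numeric array, indexed (z, y, x).
#' @param spacing_mm positive numeric triple, spacing per axis in mm.
#' @param modality one of `"PET"`, `"CT"`.
#' @param subject_id character scalar.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1), modality = c("CT", "PET"),
                         subject_id = "anonymous") {
  modality <- match.arg(modality)
  if (length(dim(voxels)) != 3L)
    stop("non-3-D voxel array: image_volume requires a (z, y, x) array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive reals")
  structure(list(voxels = voxels, spacing_mm = spacing_mm, modality = modality,
                 subject_id = subject_id),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s %s  dims (z,y,x) = %s  spacing = %s mm\n",
              x$subject_id, x$modality,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = "x")))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI file into an [image_volume]. NIfTI stores data (x, y, z);
#' the array is permuted to the package's (z, y, x) convention.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag, `"CT"` or `"PET"`.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return an [image_volume].
#' @export
read_volume <- function(path, modality = c("CT", "PET"), subject_id = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("non-3-D image: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  sp <- RNifti::pixdim(img)
  # (x,y,z) -> (z,y,x)
  image_volume(aperm(arr, c(3, 2, 1)), spacing_mm = rev(sp[1:3]),
               modality = modality, subject_id = subject_id)
}

#' Write an image volume as NIfTI
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  arr <- aperm(vol$voxels, c(3, 2, 1))
  attr(arr, "pixdim") <- rev(vol$spacing_mm)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param lower_tail fraction of low-intensity voxels winsorized upward
#'   (default 0.001, i.e. 1 per mille).
#' @param upper_tail fraction of high-intensity voxels clipped downward
#'   (default 0.10).
#' @param input_side side length of the square model input (default 224).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(lower_tail = 0.001, upper_tail = 0.10,
                              input_side = 224L) {
  if (!(lower_tail >= 0 && lower_tail < 1 - upper_tail && 1 - upper_tail <= 1))
    stop("require 0 <= lower_tail < 1 - upper_tail <= 1")
  if (input_side < 1) stop("input_side must be positive")
  structure(list(lower_tail = lower_tail, upper_tail = upper_tail,
                 input_side = as.integer(input_side)),
            class = "preprocess_config")
}

# order-statistic clip bounds: lower bound is the (floor(n*lower)+1)-th order
# statistic, upper bound the ceiling(n*(1-upper))-th. Using data values as
# bounds (rather than interpolated quantiles) makes the normalization exactly
# idempotent: re-application finds its own bounds already at 0 and 1.
winsor_bounds <- function(x, lower_tail, upper_tail) {
  n <- length(x)
  xs <- sort(x)
  k_lo <- min(n, floor(n * lower_tail) + 1L)
  k_hi <- max(1L, ceiling(n * (1 - upper_tail)))
  c(xs[k_lo], xs[k_hi])
}

#' Winsorize intensity outliers and normalize to [0, 1]
#'
#' Implements the outlier "bandpass" rule: voxels below the lower-tail bound
#' are raised to it, voxels above the upper bound are clipped to it, and the
#' result is affinely rescaled so that min = 0 and max = 1. The operation is
#' idempotent and invariant to positive affine transforms of the input.
#'
#' @param vol an [image_volume] with at least two distinct finite values.
#' @param cfg a [preprocess_config].
#' @return an [image_volume] with voxels in [0, 1].
#' @export
bandpass_normalize <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "image_volume"))
  v <- vol$voxels
  if (anyNA(v) || any(!is.finite(v))) stop("NaN or non-finite voxels")
  b <- winsor_bounds(as.vector(v), cfg$lower_tail, cfg$upper_tail)
  if (b[2] <= b[1]) stop("constant image: zero dynamic range after clipping")
  v <- pmin(pmax(v, b[1]), b[2])
  v <- (v - b[1]) / (b[2] - b[1])
  vol$voxels <- v
  vol
}

# bilinear resample of a 2-D matrix to nr x nc, pixel-center aligned:
# output center u in [0,1] maps to input coordinate u*(n_in-1)+1 (1-based).
# Convex interpolation: output values never leave [min(x), max(x)].
resize_bilinear <- function(x, nr, nc) {
  nr_in <- nrow(x); nc_in <- ncol(x)
  map_idx <- function(n_out, n_in) {
    if (n_out == 1L) return(list(lo = 1L, hi = 1L, w = 0))
    pos <- (seq_len(n_out) - 1) / (n_out - 1) * (n_in - 1) + 1
    lo <- pmin(floor(pos), n_in - 1L)
    lo <- pmax(lo, 1L)
    list(lo = as.integer(lo), hi = as.integer(lo + 1L), w = pos - lo)
  }
  ri <- map_idx(nr, nr_in)
  ci <- map_idx(nc, nc_in)
  if (nr_in == 1L) { ri <- list(lo = rep(1L, nr), hi = rep(1L, nr), w = rep(0, nr)) }
  if (nc_in == 1L) { ci <- list(lo = rep(1L, nc), hi = rep(1L, nc), w = rep(0, nc)) }
  a <- x[ri$lo, ci$lo, drop = FALSE]
  b <- x[ri$hi, ci$lo, drop = FALSE]
  cc <- x[ri$lo, ci$hi, drop = FALSE]
  d <- x[ri$hi, ci$hi, drop = FALSE]
  wr <- matrix(ri$w, nr, nc)
  wc <- matrix(ci$w, nr, nc, byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b + (1 - wr) * wc * cc + wr * wc * d
}

# center-crop or zero-pad a matrix to a square of side s
center_square <- function(x, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  s <- max(nr, nc)
  out <- matrix(fill, s, s)
  r0 <- (s - nr) %/% 2
  c0 <- (s - nc) %/% 2
  out[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)] <- x
  out
}

#' Reduce a preprocessed volume to a fixed-size 2-D model input
#'
#' Selects the axial slice with the largest in-mask area (or the central slice
#' when no mask is given), pads to square, and resamples bilinearly to
#' `cfg$input_side` pixels a side, clamping to [0, 1].
#'
#' @param vol a preprocessed [image_volume] (values in [0, 1]).
#' @param mask optional [image_volume] on the same grid; nonzero = tumor.
#' @param cfg a [preprocess_config].
#' @return a list of class `model_input` with fields `plane` (matrix),
#'   `modality`, `subject_id`, `slice_index`.
#' @export
volume_to_input <- function(vol, mask = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "image_volume"))
  v <- vol$voxels
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "image_volume"))
    if (!all(dim(mask$voxels) == dim(v))) stop("mask grid differs from volume grid")
    area <- apply(mask$voxels != 0, 1L, sum)
    if (all(area == 0)) stop("empty mask")
    z <- which.max(area)
  } else {
    z <- (dim(v)[1] + 1L) %/% 2L
  }
  plane <- center_square(v[z, , ])
  plane <- resize_bilinear(plane, cfg$input_side, cfg$input_side)
  plane <- pmin(pmax(plane, 0), 1)
  structure(list(plane = plane, modality = vol$modality,
                 subject_id = vol$subject_id, slice_index = z),
            class = "model_input")
}
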