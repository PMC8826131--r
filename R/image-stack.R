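# Core containers: ImageStack (a z-ordered stack of equally shaped slices with
# voxel geometry) and AcquisitionMeta (stage position metadata for one scan).

#' Create an image stack
#'
#' An `ImageStack` is the unit every pipeline stage consumes and produces: an
#' ordered sequence of equally shaped 2D intensity slices plus voxel geometry.
#' Slice index 1 is the slice at the smallest physical z; the stack grows
#' upward along the vertical axis.
#'
#' @param data 3D numeric array with dimensions `c(ny, nx, nz)` (rows,
#'   columns, slices), or a single 2D matrix for a one-slice stack.
#' @param dtype Pixel type tag, `"float32"` (reconstruction output) or
#'   `"uint16"` (export format). For `"uint16"` the values must be integers in
#'   `[0, 65535]`.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param slice_axis_label Name of the slice axis, `"z"` by default.
#' @param mask Optional logical array of the same dimensions marking valid
#'   voxels; `NULL` means all voxels are valid. Used by the rigid-merge path
#'   to track voxels that fell outside the source volume during resampling.
#' @param check If `TRUE` (default), validate invariants (finite intensities,
#'   positive voxel size, matching mask dimensions).
#'
#' @return An object of class `ImageStack`.
#' @export
#' @examples
#' s <- image_stack(array(runif(4 * 4 * 3), c(4, 4, 3)), voxel_size_um = 100)
#' n_slices(s)
image_stack <- function(data, dtype = c("float32", "uint16"),
                        voxel_size_um = 1, slice_axis_label = "z",
                        mask = NULL, check = TRUE) {
  dtype <- match.arg(dtype)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (ny, nx, nz) or a single matrix")
  x <- structure(
    list(data = data, dtype = dtype,
         voxel_size_um = as.numeric(voxel_size_um),
         slice_axis_label = slice_axis_label, mask = mask),
    class = "ImageStack")
  if (check) validate_image_stack(x)
  x
}

validate_image_stack <- function(x) {
  stopifnot(inherits(x, "ImageStack"))
  d <- dim(x$data)
  if (length(d) != 3L || d[3] < 1L) stop("stack must hold at least one slice")
  if (!is.numeric(x$voxel_size_um) || length(x$voxel_size_um) != 1L ||
      !is.finite(x$voxel_size_um) || x$voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  if (anyNA(x$data) || any(!is.finite(x$data)))
    stop("stack intensities must be finite (no NA/NaN/Inf)")
  if (x$dtype == "uint16") {
    rng <- range(x$data)
    if (rng[1] < 0 || rng[2] > 65535 || any(x$data != trunc(x$data)))
      stop("uint16 stack must contain integers in [0, 65535]")
  }
  if (!is.null(x$mask)) {
    if (!is.logical(x$mask) || !identical(dim(x$mask), d))
      stop("mask must be a logical array with the same dimensions as the data")
  }
  invisible(x)
}

#' Number of slices in a stack
#' @param x An `ImageStack`.
#' @return Integer slice count.
#' @export
n_slices <- function(x) {
  stopifnot(inherits(x, "ImageStack"))
  dim(x$data)[3]
}

#' Extract one slice as a matrix
#' @param x An `ImageStack`.
#' @param i Slice index (1-based).
#' @return A `ny x nx` matrix.
#' @export
get_slice <- function(x, i) {
  stopifnot(inherits(x, "ImageStack"), i >= 1, i <= n_slices(x))
  x$data[, , i]
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d slice(s) of %d x %d, dtype %s, voxel %g um%s\n",
              d[3], d[1], d[2], x$dtype, x$voxel_size_um,
              if (!is.null(x$mask))
                sprintf(", %d masked voxel(s)", sum(!x$mask)) else ""))
  invisible(x)
}

#' Create acquisition metadata
#'
#' Records where one acquisition sits along the vertical (stage motor) axis.
#' `motor_z_mm` is the stage position of slice index 1; the physical span of
#' the acquisition is `(n_slices - 1) * slice_spacing_mm`.
#'
#' @param motor_z_mm Stage motor position (mm) of the first slice.
#' @param slice_spacing_mm Spacing between consecutive slices (mm), positive.
#' @param n_slices Number of slices, at least 1.
#' @param orientation `"down"` for the normal mounting, `"up"` for a series
#'   acquired with the specimen flipped.
#' @param label Free-text label used in reports and error messages.
#'
#' @return An object of class `AcquisitionMeta`.
#' @export
acquisition_meta <- function(motor_z_mm, slice_spacing_mm, n_slices,
                             orientation = c("down", "up"), label = "") {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(motor_z_mm), length(motor_z_mm) == 1L,
            is.finite(motor_z_mm))
  if (!is.numeric(slice_spacing_mm) || slice_spacing_mm <= 0)
    stop("slice_spacing_mm must be positive")
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) stop("n_slices must be >= 1")
  structure(
    list(motor_z_mm = as.numeric(motor_z_mm),
         slice_spacing_mm = as.numeric(slice_spacing_mm),
         n_slices = n_slices, orientation = orientation,
         label = as.character(label)),
    class = "AcquisitionMeta")
}

#' @export
print.AcquisitionMeta <- function(x, ...) {
  cat(sprintf(
    "AcquisitionMeta '%s': %d slices from z = %g mm, spacing %g mm, %s\n",
    x$label, x$n_slices, x$motor_z_mm, x$slice_spacing_mm, x$orientation))
  invisible(x)
}

# round half away from zero upward: round(0.5) -> 1, used everywhere a slice
# count or pixel value is quantised so results do not depend on R's
# round-half-to-even rule
round_half_up <- function(x) floor(x + 0.5)
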