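#' Define a 3D voxel grid in template space
#'
#' A `volume_grid` ties voxel indices to millimetre coordinates through an
#' axis-aligned affine: `mm = origin_mm + (index - 1) * voxel_size_mm`.
#' All spatial operations in the package (smoothing kernels in mm, peak
#' coordinates, smoothness estimates) are expressed through this mapping.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm positive numeric vector of length 3, voxel edge
#'   lengths in mm.
#' @param origin_mm numeric vector of length 3, the mm coordinate of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(20, 20, 12), voxel_size_mm = c(3, 3, 3))
#' voxel_to_mm(g, c(1, 1, 1))
#' @export
volume_grid <- function(shape, voxel_size_mm = c(3, 3, 3),
                        origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            length(origin_mm) == 3L, all(is.finite(origin_mm)))
  structure(list(shape = shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Convert voxel indices to template-space mm coordinates
#'
#' @param grid a [volume_grid()].
#' @param idx numeric vector of length 3 (1-based voxel index) or a matrix
#'   with 3 columns.
#' @return mm coordinates, same shape as `idx`.
#' @export
voxel_to_mm <- function(grid, idx) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.matrix(idx)) {
    sweep(sweep(idx - 1, 2, grid$voxel_size_mm, `*`), 2, grid$origin_mm, `+`)
  } else {
    grid$origin_mm + (idx - 1) * grid$voxel_size_mm
  }
}

#' Convert mm coordinates to (fractional) voxel indices
#'
#' @inheritParams voxel_to_mm
#' @param mm numeric vector of length 3 or matrix with 3 columns.
#' @return 1-based voxel indices (possibly fractional).
#' @export
mm_to_voxel <- function(grid, mm) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.matrix(mm)) {
    sweep(sweep(mm, 2, grid$origin_mm, `-`), 2, grid$voxel_size_mm, `/`) + 1
  } else {
    (mm - grid$origin_mm) / grid$voxel_size_mm + 1
  }
}

#' Construct a 4D BOLD series object
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param grid a [volume_grid()] matching the first three dimensions.
#' @param tr_s repetition time in seconds.
#' @return An object of class `bold4d` with fields `data`, `grid`,
#'   `n_volumes` and `tr_s`.
#' @export
bold4d <- function(data, grid, tr_s) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            inherits(grid, "volume_grid"),
            identical(dim(data)[1:3], as.integer(grid$shape)),
            is.numeric(tr_s), tr_s > 0)
  if (any(!is.finite(data)))
    stop("bold4d: data contains non-finite values")
  structure(list(data = data, grid = grid,
                 n_volumes = dim(data)[4L], tr_s = as.numeric(tr_s)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold4d: %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

nifti_affine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$voxel_size_mm)
  aff[1:3, 4] <- grid$origin_mm  # 0-based voxel (0,0,0) == 1-based (1,1,1)
  aff
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param x 3D array, 4D array, or a [bold4d()].
#' @param grid a [volume_grid()]; taken from `x` when `x` is a `bold4d`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param tr_s repetition time stored in the header for 4D images.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL, tr_s = 1) {
  if (inherits(x, "bold4d")) {
    grid <- x$grid; tr_s <- x$tr_s; x <- x$data
  }
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(grid$voxel_size_mm,
                           if (length(dim(x)) == 4L) tr_s)
  img <- RNifti::`sform<-`(img, structure(nifti_affine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume into an array plus grid
#'
#' @param path a NIfTI file.
#' @return list with `data` (array), `grid` ([volume_grid()]) and `tr_s`
#'   (NA for 3D images).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  vx <- abs(hdr$pixdim[2:4])
  aff <- RNifti::xform(img)
  origin <- aff[1:3, 4]  # mm of 0-based voxel (0,0,0), i.e. 1-based (1,1,1)
  grid <- volume_grid(dim(img)[1:3], voxel_size_mm = vx, origin_mm = origin)
  tr <- if (length(dim(img)) >= 4L) hdr$pixdim[5] else NA_real_
  list(data = array(as.numeric(img), dim = dim(img)), grid = grid, tr_s = tr)
}
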