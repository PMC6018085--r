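# In-scope preprocessing for resting-state BOLD: initial volume discard,
# motion-based subject exclusion, Gaussian spatial smoothing, linear
# detrending and band-pass filtering. Pipeline order is fixed:
# discard -> (exclusion) -> smooth -> detrend -> band-pass.

#' Preprocessing configuration
#'
#' @param n_discard initial volumes to drop (scanner stabilization).
#' @param motion_trans_limit_mm,motion_rot_limit_deg exclusion limits; a
#'   subject is excluded iff any entry strictly exceeds the limit.
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm.
#' @param band_hz band-pass edges in Hz, `0 < low < high < Nyquist`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 10,
                              motion_trans_limit_mm = 2.5,
                              motion_rot_limit_deg = 2.5,
                              fwhm_mm = 6,
                              band_hz = c(0.01, 0.08)) {
  stopifnot(n_discard >= 0, motion_trans_limit_mm > 0,
            motion_rot_limit_deg > 0, fwhm_mm >= 0,
            length(band_hz) == 2, band_hz[1] > 0, band_hz[1] < band_hz[2])
  structure(list(n_discard = n_discard,
                 motion_trans_limit_mm = motion_trans_limit_mm,
                 motion_rot_limit_deg = motion_rot_limit_deg,
                 fwhm_mm = fwhm_mm, band_hz = band_hz),
            class = "preprocess_config")
}

#' Discard initial volumes of a BOLD series
#'
#' @param x a [bold4d()].
#' @param n number of leading volumes to drop (`n < n_volumes`).
#' @return A [bold4d()] with `n_volumes - n` volumes; the retained volumes
#'   are bit-identical to the input.
#' @export
discard_initial_volumes <- function(x, n) {
  stopifnot(inherits(x, "bold4d"), n >= 0)
  if (n >= x$n_volumes)
    stop("cannot discard ", n, " of ", x$n_volumes, " volumes")
  if (n == 0) return(x)
  bold4d(x$data[, , , (n + 1):x$n_volumes, drop = FALSE], x$grid, x$tr_s)
}

#' Exclude subjects by head-motion limits
#'
#' A subject is excluded iff any translation entry strictly exceeds
#' `trans_limit_mm` in absolute value, or any rotation entry strictly
#' exceeds `rot_limit_deg` ("exceeded" is read as a strict inequality, so a
#' trace touching the limit exactly is kept).
#'
#' @param traces named list of motion data frames (6 columns: 3 translations
#'   in mm, 3 rotations in degrees).
#' @param trans_limit_mm,rot_limit_deg exclusion limits.
#' @param n_volumes if given, each trace's length is checked against it.
#' @return A data frame with one row per subject: `subject`, `max_trans_mm`,
#'   `max_rot_deg`, `excluded`, `rule` (which limit fired, or "").
#' @examples
#' tr <- list(ok = as.data.frame(matrix(0, 10, 6)),
#'            bad = as.data.frame(matrix(c(rep(0, 55), 2.6, rep(0, 4)), 10, 6)))
#' exclude_by_motion(tr)
#' @export
exclude_by_motion <- function(traces, trans_limit_mm = 2.5,
                              rot_limit_deg = 2.5, n_volumes = NULL) {
  stopifnot(length(traces) > 0)
  nm <- names(traces)
  if (is.null(nm)) nm <- sprintf("sub-%03d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    tr <- as.matrix(traces[[i]])
    if (ncol(tr) != 6)
      stop("motion trace ", nm[i], " must have 6 columns")
    if (!is.null(n_volumes) && nrow(tr) != n_volumes)
      stop("motion trace ", nm[i], " has ", nrow(tr),
           " rows but the series has ", n_volumes, " volumes")
    mt <- max(abs(tr[, 1:3]))
    mr <- max(abs(tr[, 4:6]))
    rule <- c(if (mt > trans_limit_mm) "translation",
              if (mr > rot_limit_deg) "rotation")
    data.frame(subject = nm[i], max_trans_mm = mt, max_rot_deg = mr,
               excluded = length(rule) > 0,
               rule = paste(rule, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spatially smooth each volume with a Gaussian kernel
#'
#' Separable 3D Gaussian convolution per volume with
#' `sigma_mm = fwhm / (2 * sqrt(2 * log 2))`, converted to voxel units per
#' axis (anisotropic voxels are handled). The boundary policy reflects at
#' the volume edges; masking, if any, is applied after smoothing.
#'
#' @param x a [bold4d()] or 3D array (with `grid` supplied).
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param grid required when `x` is a bare array.
#' @return Same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, grid = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (inherits(x, "bold4d")) {
    if (fwhm_mm == 0) return(x)
    sigma_vox <- fwhm_mm / FWHM_SIGMA / x$grid$voxel_size_mm
    out <- x$data
    for (t in seq_len(x$n_volumes))
      out[, , , t] <- smooth3d(x$data[, , , t], sigma_vox)
    return(bold4d(out, x$grid, x$tr_s))
  }
  stopifnot(is.array(x), length(dim(x)) == 3L, inherits(grid, "volume_grid"))
  if (fwhm_mm == 0) return(x)
  smooth3d(x, fwhm_mm / FWHM_SIGMA / grid$voxel_size_mm)
}

#' Remove linear drift and band-pass filter each voxel time course
#'
#' Per voxel: the least-squares linear trend (intercept + slope) is removed,
#' then the series is band-passed with a zero-phase forward-backward
#' Butterworth filter (order 4). Output voxel means are ~0.
#'
#' @param x a [bold4d()] with at least 20 volumes.
#' @param band_hz pass band in Hz; the upper edge must be below Nyquist
#'   (`1 / (2 * TR)`).
#' @param order Butterworth order (per direction).
#' @return A filtered [bold4d()].
#' @export
detrend_and_bandpass <- function(x, band_hz = c(0.01, 0.08), order = 4) {
  stopifnot(inherits(x, "bold4d"), x$n_volumes >= 20)
  nyq <- 1 / (2 * x$tr_s)
  if (band_hz[2] >= nyq)
    stop("band upper edge ", band_hz[2], " Hz is not below Nyquist (",
         signif(nyq, 4), " Hz)")
  if (band_hz[1] <= 0 || band_hz[1] >= band_hz[2])
    stop("invalid band: ", paste(band_hz, collapse = "-"), " Hz")
  n <- x$n_volumes
  tt <- seq_len(n)
  Xd <- cbind(1, tt - mean(tt))
  hat <- Xd %*% solve(crossprod(Xd), t(Xd))
  flat <- matrix(x$data, ncol = n)          # voxels x time
  flat <- flat - flat %*% t(hat)            # detrend (symmetric hat)
  bf <- signal::butter(order, band_hz / nyq, type = "pass")
  filt <- filtfilt_rows(bf$b, bf$a, flat)
  out <- array(filt, dim = dim(x$data))
  bold4d(out, x$grid, x$tr_s)
}

# Zero-phase forward-backward IIR filtering applied to every row of X at
# once. Edge transients are reduced by odd-mirror padding of length
# 3 * (filter order) at both ends before the forward pass.
filtfilt_rows <- function(b, a, X) {
  nf <- max(length(a), length(b))
  pad <- min(3L * (nf - 1L), ncol(X) - 1L)
  left <- 2 * X[, 1] - X[, (pad + 1):2, drop = FALSE]
  right <- 2 * X[, ncol(X)] - X[, (ncol(X) - 1):(ncol(X) - pad),
                                drop = FALSE]
  Xp <- cbind(left, X, right)
  Y <- iir_rows(b, a, Xp)
  Y <- iir_rows(b, a, Y[, ncol(Y):1, drop = FALSE])
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y[, pad + seq_len(ncol(X)), drop = FALSE]
}

iir_rows <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  n <- ncol(X)
  Y <- matrix(0, nrow(X), n)
  nb <- length(b); na <- length(a)
  for (t in seq_len(n)) {
    acc <- b[1] * X[, t]
    jmax <- min(nb - 1L, t - 1L)
    if (jmax >= 1) for (j in seq_len(jmax))
      acc <- acc + b[j + 1] * X[, t - j]
    kmax <- min(na - 1L, t - 1L)
    if (kmax >= 1) for (k in seq_len(kmax))
      acc <- acc - a[k + 1] * Y[, t - k]
    Y[, t] <- acc
  }
  Y
}

#' Run the full preprocessing chain on one subject
#'
#' Order: discard initial volumes, smooth, detrend + band-pass. Motion
#' exclusion is a cohort-level decision and is applied separately with
#' [exclude_by_motion()].
#'
#' @param x a [bold4d()].
#' @param config a [preprocess_config()].
#' @return A preprocessed [bold4d()].
#' @export
preprocess_subject <- function(x, config = preprocess_config()) {
  x <- discard_initial_volumes(x, config$n_discard)
  x <- smooth_gaussian(x, config$fwhm_mm)
  detrend_and_bandpass(x, config$band_hz)
}
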