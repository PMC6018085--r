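# Shared numeric helpers: separable Gaussian convolution with reflection
# padding, seed derivation, Fisher transform.

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # fwhm = FWHM_SIGMA * sigma

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along margin `axis` of a 3D array, reflecting at the edges.
conv3d_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1L) return(vol)
  d <- dim(vol)
  half <- (length(kernel) - 1L) %/% 2L
  n <- d[axis]
  # reflect indices: 1 2 3 ... n with mirror boundary (no repeated edge)
  idx <- c(rev(seq_len(min(half, n - 1L)) + 1L),
           seq_len(n),
           n - seq_len(min(half, n - 1L)))
  # if half exceeds n-1, clamp by recycling reflection (tiny grids)
  while (length(idx) < n + 2L * half) {
    idx <- c(idx[1], idx, idx[length(idx)])
  }
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = dv[1], ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[seq_len(dv[1]) + (j - 1L), , drop = FALSE]
  }
  res <- array(out, dim = dv)
  aperm(res, order(perm))
}

# Separable 3D Gaussian smoothing; sigma given per axis in voxels.
smooth3d <- function(vol, sigma_vox) {
  for (ax in 1:3) {
    vol <- conv3d_axis(vol, gaussian_kernel_1d(sigma_vox[ax]), ax)
  }
  vol
}

# Deterministic child seeds: keep within 32-bit signed range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629)
}

#' Fisher z-transform of a correlation
#'
#' Correlations are clipped to `1 - 1e-7` in absolute value before `atanh`
#' so that sample correlations of exactly +/-1 stay finite.
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return `atanh` of the clipped correlations.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

# Column-standardize a matrix (voxels in rows, ...); returns matrix.
standardize <- function(x) {
  (x - mean(x)) / stats::sd(x)
}
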