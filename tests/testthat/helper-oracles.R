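# Independent reference implementations used as oracles. These are written
# deliberately differently from the package code so that agreement is
# evidence of correctness, not of shared bugs.

# Flood-fill connected-component labelling by repeated frontier expansion
# over an explicit neighbour table (the package labeller is a keyed BFS).
flood_fill_labels <- function(mask, connectivity = 26) {
  sh <- dim(mask)
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    manh <- abs(dx) + abs(dy) + abs(dz)
    if (connectivity == 6 && manh != 1) next
    if (connectivity == 18 && manh > 2) next
    offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  lab <- array(0L, dim = sh)
  nxt <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    frontier <- s
    lab[s] <- nxt
    while (length(frontier)) {
      newf <- integer(0)
      for (v in frontier) {
        co <- arrayInd(v, sh)[1, ]
        for (o in offs) {
          p <- co + o
          if (any(p < 1) || any(p > sh)) next
          li <- p[1] + (p[2] - 1L) * sh[1] + (p[3] - 1L) * sh[1] * sh[2]
          if (mask[li] && lab[li] == 0L) {
            lab[li] <- nxt
            newf <- c(newf, li)
          }
        }
      }
      frontier <- newf
    }
  }
  lab
}

# Ideal band-pass by FFT bin masking (two-sided spectrum).
fft_ideal_bandpass <- function(x, tr_s, band_hz = c(0.01, 0.08)) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)
  keep <- f >= band_hz[1] & f <= band_hz[2]
  z <- stats::fft(x)
  z[!keep] <- 0
  Re(stats::fft(z, inverse = TRUE)) / n
}

# RMS amplitude ratio of a filtered sinusoid relative to the input, with
# the first/last few samples dropped to ignore edge transients.
amp_ratio <- function(y, x, trim = 10) {
  idx <- (trim + 1):(length(x) - trim)
  sqrt(mean(y[idx]^2) / mean(x[idx]^2))
}

dice_coefficient <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Run the pipeline without console noise.
quiet_pipeline <- function(...) {
  suppressWarnings(suppressMessages(run_pipeline(...)))
}

# Voxel indices of corrected (extent-surviving) clusters for one RSN of a
# pipeline result.
corrected_voxels <- function(rsn_entry, connectivity = 26) {
  if (is.null(rsn_entry$stat) || is.null(rsn_entry$clusters) ||
      nrow(rsn_entry$clusters) == 0) return(integer(0))
  supra <- array(FALSE, dim = dim(rsn_entry$t_volume))
  supra[rsn_entry$roi] <- is.finite(rsn_entry$stat$p) &
    rsn_entry$stat$p < 0.05
  lc <- label_clusters(supra, connectivity)
  keep <- which(lc$sizes >= rsn_entry$k_star)
  which(lc$labels %in% keep)
}
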