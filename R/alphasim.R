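# Monte-Carlo cluster-extent correction: smoothness estimation from
# residual maps, connected-component labelling, simulation of the null
# distribution of the maximum suprathreshold cluster size in smooth
# Gaussian noise, and cluster reporting.

#' Monte-Carlo cluster-correction configuration
#'
#' @param voxel_p voxel-level (uncorrected) p threshold.
#' @param corrected_alpha target corrected cluster-level alpha.
#' @param n_iterations Monte-Carlo iterations (>= 100).
#' @param connectivity 6, 18 or 26 (face / edge / corner neighbours).
#' @param two_sided if `TRUE`, voxel thresholding is on `|z|` at
#'   `voxel_p / 2` per tail (matching a two-sided group test).
#' @param seed integer seed for the noise simulations.
#' @return A list of class `alphasim_config`.
#' @export
alphasim_config <- function(voxel_p = 0.05, corrected_alpha = 0.05,
                            n_iterations = 1000, connectivity = 26,
                            two_sided = TRUE, seed = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1, corrected_alpha > 0,
            corrected_alpha < 1, n_iterations >= 100,
            connectivity %in% c(6, 18, 26))
  structure(list(voxel_p = voxel_p, corrected_alpha = corrected_alpha,
                 n_iterations = as.integer(n_iterations),
                 connectivity = connectivity, two_sided = two_sided,
                 seed = seed),
            class = "alphasim_config")
}

#' Estimate the spatial smoothness (FWHM) of residual maps
#'
#' Classical derivative-based estimator: residual maps are standardized
#' within the mask, and for each axis the variance of first differences
#' between in-mask neighbours gives the lag-1 autocorrelation
#' `rho = 1 - var(d) / 2`, hence the equivalent Gaussian-filter width
#' `FWHM = sqrt(-2 log(2) / log(rho)) * voxel_size`. Estimates are averaged
#' over maps
#' and floored at `voxel_size * 2 * sqrt(log(2) / pi)` (the white-noise
#' limit of the estimator).
#'
#' @param resid_maps list of 3D arrays, or a matrix with maps in rows and
#'   mask voxels in columns (then `mask` is required to re-embed).
#' @param grid a [volume_grid()].
#' @param mask logical 3D array restricting the estimate.
#' @return Numeric length-3 vector: per-axis FWHM in mm.
#' @export
estimate_smoothness <- function(resid_maps, grid, mask) {
  stopifnot(inherits(grid, "volume_grid"), is.logical(mask))
  if (is.matrix(resid_maps)) {
    stopifnot(ncol(resid_maps) == sum(mask))
    resid_maps <- lapply(seq_len(nrow(resid_maps)), function(i) {
      v <- array(NA_real_, dim = grid$shape)
      v[mask] <- resid_maps[i, ]
      v
    })
  }
  stopifnot(length(resid_maps) >= 2)
  if (any(grid$shape < 2)) stop("grid has an axis with fewer than 2 voxels")
  acc <- matrix(NA_real_, length(resid_maps), 3)
  for (m in seq_along(resid_maps)) {
    v <- resid_maps[[m]]
    vals <- v[mask]
    s <- stats::sd(vals)
    if (!is.finite(s) || s == 0)
      stop("constant residual map; smoothness undefined")
    v[mask] <- (vals - mean(vals)) / s
    v[!mask] <- NA_real_
    sh <- grid$shape
    for (ax in 1:3) {
      n <- sh[ax]
      idx1 <- switch(ax,
                     v[-n, , , drop = FALSE],
                     v[, -n, , drop = FALSE],
                     v[, , -n, drop = FALSE])
      idx2 <- switch(ax,
                     v[-1, , , drop = FALSE],
                     v[, -1, , drop = FALSE],
                     v[, , -1, drop = FALSE])
      d <- (idx2 - idx1)[!is.na(idx2 - idx1)]
      if (length(d) < 2) next
      rho <- 1 - stats::var(d) / 2
      # rho = exp(-1 / (4 sigma^2)) for white noise passed through a
      # Gaussian filter of width sigma (voxels): FWHM = sqrt(-2 ln2 / ln rho)
      acc[m, ax] <- if (rho <= 0) 0 else sqrt(-2 * log(2) / log(rho))
    }
  }
  fwhm_vox <- colMeans(acc, na.rm = TRUE)
  fwhm_vox[!is.finite(fwhm_vox)] <- 0
  floor_vox <- 2 * sqrt(log(2) / pi)
  pmax(fwhm_vox, floor_vox) * grid$voxel_size_mm
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off)) <= 2,
                 "26" = rep(TRUE, nrow(off)))
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Breadth-first connected-component labelling under 6-, 18- or
#' 26-connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return A list of class `cluster_labels`: `labels` (integer 3D array, 0
#'   for background) and `sizes` (voxels per cluster, in label order).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  sh <- dim(mask)
  labels <- array(0L, dim = sh)
  idx <- which(mask)
  if (length(idx) == 0)
    return(structure(list(labels = labels, sizes = integer(0)),
                     class = "cluster_labels"))
  off <- neighbour_offsets(connectivity)
  coord <- arrayInd(idx, sh)
  key <- function(cm) (cm[, 3] - 1L) * sh[1] * sh[2] +
    (cm[, 2] - 1L) * sh[1] + cm[, 1]
  in_mask <- logical(prod(sh)); in_mask[idx] <- TRUE
  lab_vec <- integer(prod(sh))
  cur <- 0L
  sizes <- integer(0)
  for (start in idx) {
    if (lab_vec[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab_vec[start] <- cur
    count <- 0L
    while (length(queue) > 0) {
      count <- count + length(queue)
      cm <- arrayInd(queue, sh)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        sweep(cm, 2, off[k, ], `+`)))
      ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] &
        nb[, 2] >= 1 & nb[, 2] <= sh[2] &
        nb[, 3] >= 1 & nb[, 3] <= sh[3]
      nbk <- unique(key(nb[ok, , drop = FALSE]))
      nbk <- nbk[in_mask[nbk] & lab_vec[nbk] == 0L]
      lab_vec[nbk] <- cur
      queue <- nbk
    }
    sizes <- c(sizes, count)
  }
  labels <- array(lab_vec, dim = sh)
  structure(list(labels = labels, sizes = sizes), class = "cluster_labels")
}

# Simulate one standardized smooth Gaussian noise volume within the mask.
smooth_noise_volume <- function(sh, sigma_vox, mask) {
  v <- array(stats::rnorm(prod(sh)), dim = sh)
  if (any(sigma_vox > 0)) v <- smooth3d(v, sigma_vox)
  vals <- v[mask]
  v[mask] <- (vals - mean(vals)) / stats::sd(vals)
  v
}

#' Monte-Carlo minimum cluster extent for corrected significance
#'
#' Simulates `n_iterations` Gaussian noise volumes at the given smoothness,
#' standardizes them within the mask, thresholds at the voxel-level p, and
#' records the maximum suprathreshold cluster size. The returned `k_star`
#' is the smallest extent `k` with empirical
#' `P(max cluster >= k) <= corrected_alpha`.
#'
#' @param cfg an [alphasim_config()].
#' @param mask logical 3D array (nonempty).
#' @param smoothness_fwhm_mm per-axis FWHM in mm (e.g. from
#'   [estimate_smoothness()]).
#' @param grid a [volume_grid()].
#' @return A list of class `alphasim_result`: `k_star`, `max_sizes`
#'   (simulated maxima), `cfg`, `smoothness_fwhm_mm`.
#' @export
cluster_threshold_mc <- function(cfg, mask, smoothness_fwhm_mm, grid) {
  stopifnot(inherits(cfg, "alphasim_config"), is.logical(mask), any(mask),
            inherits(grid, "volume_grid"),
            length(smoothness_fwhm_mm) %in% c(1, 3))
  if (cfg$corrected_alpha < 1 / cfg$n_iterations)
    stop("corrected_alpha below Monte-Carlo resolution 1/n_iterations")
  sigma_vox <- rep(smoothness_fwhm_mm, length.out = 3) / FWHM_SIGMA /
    grid$voxel_size_mm
  zcrit <- if (cfg$two_sided) stats::qnorm(1 - cfg$voxel_p / 2) else
    stats::qnorm(1 - cfg$voxel_p)
  sh <- grid$shape
  set.seed(derive_seed(cfg$seed, 77L))
  max_sizes <- integer(cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    v <- smooth_noise_volume(sh, sigma_vox, mask)
    supra <- if (cfg$two_sided) abs(v) > zcrit else v > zcrit
    supra[!mask] <- FALSE
    lc <- label_clusters(supra, cfg$connectivity)
    max_sizes[i] <- if (length(lc$sizes) == 0) 0L else max(lc$sizes)
  }
  ks <- 1:max(1L, max(max_sizes) + 1L)
  tail_p <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  k_star <- ks[which(tail_p <= cfg$corrected_alpha)[1]]
  structure(list(k_star = as.integer(k_star), max_sizes = max_sizes,
                 cfg = cfg,
                 smoothness_fwhm_mm = rep(smoothness_fwhm_mm,
                                          length.out = 3)),
            class = "alphasim_result")
}

#' Monte-Carlo cluster extent from the empirical residual covariance
#'
#' A covariance-calibrated variant of the smooth-noise Monte Carlo: instead
#' of assuming a stationary Gaussian field at a single smoothness, null
#' subject maps are drawn as Gaussian fields with the *empirical* spatial
#' covariance of the supplied residual maps (`X = G R / sqrt(n - 2)` with
#' `G` iid standard normal), a two-sample t map is computed with the real
#' group sizes, and the maximum suprathreshold cluster size — maximized
#' across all supplied ROIs — is recorded per iteration. This captures
#' long-range and low-rank spatial dependence (e.g. network regions whose
#' connectivity moves coherently across subjects) that a stationary
#' smoothness summary misses, and controls the corrected alpha jointly over
#' all ROIs.
#'
#' @param cfg an [alphasim_config()].
#' @param resid named list of residual matrices (subjects x ROI voxels,
#'   demeaned within group), one per ROI.
#' @param rois named list of logical 3D arrays matching `resid`.
#' @param grid a [volume_grid()].
#' @param n_a,n_b group sizes used for the simulated t maps.
#' @return A list of class `alphasim_result`: `k_star`, `max_sizes`, `cfg`,
#'   `method = "covariance"`.
#' @export
cluster_threshold_boot <- function(cfg, resid, rois, grid, n_a, n_b) {
  stopifnot(inherits(cfg, "alphasim_config"), length(resid) >= 1,
            length(resid) == length(rois), n_a >= 2, n_b >= 2)
  if (cfg$corrected_alpha < 1 / cfg$n_iterations)
    stop("corrected_alpha below Monte-Carlo resolution 1/n_iterations")
  n <- n_a + n_b
  sh <- grid$shape
  for (i in seq_along(resid))
    stopifnot(ncol(resid[[i]]) == sum(rois[[i]]))
  scale_df <- sqrt(n - 2)
  set.seed(derive_seed(cfg$seed, 177L))
  tcrit <- stats::qt(1 - cfg$voxel_p / 2, df = n - 2)
  max_sizes <- integer(cfg$n_iterations)
  for (it in seq_len(cfg$n_iterations)) {
    m <- 0L
    for (i in seq_along(resid)) {
      R <- resid[[i]]
      G <- matrix(stats::rnorm(n * nrow(R)), n, nrow(R))
      X <- G %*% R / scale_df
      Xa <- X[seq_len(n_a), , drop = FALSE]
      Xb <- X[n_a + seq_len(n_b), , drop = FALSE]
      ma <- colMeans(Xa); mb <- colMeans(Xb)
      # fast pooled t; the Gaussian draws never produce constant columns,
      # so the degenerate-voxel handling of two_sample_tmap is not needed
      sp2 <- (colSums(Xa^2) - n_a * ma^2 + colSums(Xb^2) - n_b * mb^2) /
        (n - 2)
      t_v <- (mb - ma) / sqrt(pmax(sp2, 1e-300) * (1 / n_a + 1 / n_b))
      hit <- abs(t_v) > tcrit
      # a ROI with <= m suprathreshold voxels cannot raise the running max
      if (sum(hit) <= m) next
      supra <- array(FALSE, sh)
      supra[rois[[i]]] <- hit
      lc <- label_clusters(supra, cfg$connectivity)
      if (length(lc$sizes)) m <- max(m, max(lc$sizes))
    }
    max_sizes[it] <- m
  }
  ks <- 1:max(1L, max(max_sizes) + 1L)
  tail_p <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  k_star <- ks[which(tail_p <= cfg$corrected_alpha)[1]]
  structure(list(k_star = as.integer(k_star), max_sizes = max_sizes,
                 cfg = cfg, method = "covariance"),
            class = "alphasim_result")
}

#' Report suprathreshold clusters surviving the extent threshold
#'
#' Labels the suprathreshold mask, drops clusters smaller than `k_star`,
#' and tabulates per cluster: size, peak |t| and its template-space mm
#' coordinate, and optional region labels from a label volume. Rows are
#' sorted by size, descending.
#'
#' @param t_map numeric 3D array of t values (non-suprathreshold voxels may
#'   be anything).
#' @param supra logical 3D array of suprathreshold voxels.
#' @param k_star minimum cluster extent in voxels.
#' @param grid a [volume_grid()].
#' @param connectivity 6, 18 or 26.
#' @param label_volume optional integer 3D array of region codes.
#' @param label_names optional named translation of region codes.
#' @return A data frame of class `cluster_table` with columns `cluster_id`,
#'   `n_voxels`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_t`, `labels`;
#'   attribute `k_star` records the threshold.
#' @export
report_clusters <- function(t_map, supra, k_star, grid, connectivity = 26,
                            label_volume = NULL, label_names = NULL) {
  stopifnot(is.array(t_map), identical(dim(t_map), dim(supra)),
            inherits(grid, "volume_grid"))
  if (!is.null(label_volume) &&
      !identical(dim(label_volume), dim(t_map)))
    stop("label volume grid mismatch")
  lc <- label_clusters(supra, connectivity)
  rows <- list()
  keep <- which(lc$sizes >= k_star)
  for (ci in keep) {
    vox <- which(lc$labels == ci)
    peak <- vox[which.max(abs(t_map[vox]))]
    pc <- arrayInd(peak, dim(t_map))[1, ]
    mm <- voxel_to_mm(grid, pc)
    labs <- ""
    if (!is.null(label_volume)) {
      codes <- sort(unique(label_volume[vox]))
      codes <- codes[codes != 0]
      labs <- if (!is.null(label_names))
        paste(label_names[as.character(codes)], collapse = " ") else
          paste(codes, collapse = " ")
    }
    rows[[length(rows) + 1]] <- data.frame(
      cluster_id = ci, n_voxels = lc$sizes[ci],
      peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
      peak_t = t_map[peak], labels = labs, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0)
    data.frame(cluster_id = integer(0), n_voxels = integer(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), peak_t = numeric(0),
               labels = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  out <- out[order(-out$n_voxels), , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "k_star") <- k_star
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Write a cluster table as TSV
#'
#' The minimum extent `k_star` is recorded in a header comment line.
#'
#' @param x a [report_clusters()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# minimum cluster extent k_star = %d",
                     attr(x, "k_star")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
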