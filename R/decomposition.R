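# Model-order estimation (MDL), PCA reduction/whitening, per-channel rank
# gaussianization (the post-nonlinear inversion stage), fixed-point fastICA
# with symmetric decorrelation, and the group ICA driver with dual-regression
# back-reconstruction.

#' Estimate the number of components by the MDL criterion
#'
#' Computes the classical eigenvalue form of the minimum-description-length
#' criterion from the temporal covariance of a voxels-by-time data matrix:
#' for candidate order `k`,
#' `MDL(k) = -N (p - k) log(g_k / a_k) + k (2p - k) log(N) / 2`,
#' where `g_k` and `a_k` are the geometric and arithmetic means of the
#' trailing `p - k` eigenvalues, `p` the number of channels and `N` the
#' number of samples. The returned order is the argmin, floored at 1.
#'
#' @param data numeric matrix, samples (voxels) in rows, channels (time
#'   points) in columns.
#' @param max_order largest candidate order (`< ncol(data)`).
#' @param effective_n optional override for the sample count `N` (e.g. an
#'   i.i.d.-corrected effective sample size); defaults to `nrow(data)`.
#' @return A list of class `model_order`: `n_components`, `curve` (MDL value
#'   per candidate), `candidates`, `eigenvalues`.
#' @export
estimate_order_mdl <- function(data, max_order = ncol(data) - 1L,
                               effective_n = NULL) {
  stopifnot(is.matrix(data), max_order >= 1, max_order < ncol(data))
  p <- ncol(data)
  N <- if (is.null(effective_n)) nrow(data) else effective_n
  cc <- stats::cov(data)
  lam <- sort(eigen(cc, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  if (any(lam <= 0))
    stop("non-positive covariance eigenvalues; data is rank deficient ",
         "below the candidate orders")
  ks <- 0:max_order
  curve <- vapply(ks, function(k) {
    tail_l <- lam[(k + 1):p]
    g <- exp(mean(log(tail_l)))
    a <- mean(tail_l)
    -N * (p - k) * log(g / a) + 0.5 * k * (2 * p - k) * log(N)
  }, numeric(1))
  k_hat <- ks[which.min(curve)]
  structure(list(n_components = max(1L, as.integer(k_hat)),
                 curve = curve, candidates = ks, eigenvalues = lam),
            class = "model_order")
}

#' PCA reduction with whitening / dewhitening transforms
#'
#' Reduces the channel dimension of a channels-by-samples matrix to the top
#' `n_components` principal directions and whitens them. The dewhitening
#' matrix reverses the whitening on the retained subspace to machine
#' precision; the squared reconstruction error equals the discarded
#' eigenvalue mass.
#'
#' @param x numeric matrix, channels in rows, samples in columns.
#' @param n_components retained dimension (`<= rank`).
#' @return A list of class `pca_reduction`: `reduced` (whitened
#'   `n_components x samples`), `whitening`, `dewhitening`, `eigenvalues`
#'   (all of them), `center` (row means).
#' @export
reduce_pca <- function(x, n_components) {
  stopifnot(is.matrix(x), n_components >= 1,
            n_components <= min(dim(x)))
  ctr <- rowMeans(x)
  xc <- x - ctr
  cc <- tcrossprod(xc) / (ncol(x) - 1)
  eg <- eigen(cc, symmetric = TRUE)
  lam <- eg$values
  if (lam[n_components] <= .Machine$double.eps * max(lam) * nrow(x))
    stop("n_components exceeds the numerical rank of the data")
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  d <- lam[seq_len(n_components)]
  K <- diag(1 / sqrt(d), n_components) %*% t(E)       # whitening
  Kinv <- E %*% diag(sqrt(d), n_components)           # dewhitening
  structure(list(reduced = K %*% xc, whitening = K, dewhitening = Kinv,
                 eigenvalues = lam, center = ctr),
            class = "pca_reduction")
}

#' Reconstruct data from a PCA reduction
#'
#' @param p a [reduce_pca()] result.
#' @param reduced optionally, a replacement for `p$reduced`.
#' @return The reconstructed channels-by-samples matrix.
#' @export
pca_reconstruct <- function(p, reduced = p$reduced) {
  p$dewhitening %*% reduced + p$center
}

#' Gaussianize each channel by a rank-based monotone map
#'
#' Maps every channel's empirical distribution to standard-normal quantiles
#' (midpoint plotting positions), optionally blended with the standardized
#' identity. This is the post-nonlinear inversion stage: any strictly
#' monotone channel-wise distortion leaves the ranks, and hence the fully
#' gaussianized output, unchanged.
#'
#' @param x numeric matrix, channels in rows, samples in columns (>= 50
#'   samples recommended for a stable map).
#' @param blend weight of the gaussianized values vs the standardized input
#'   (1 = full gaussianization, 0 = identity up to standardization).
#' @return A list of class `gaussianized`: `data` (transformed matrix) and
#'   `maps` (per channel, a data frame of knots `x` -> `g` sampled at up to
#'   65 quantiles, the fitted inverse nonlinearity).
#' @export
gaussianize_channels <- function(x, blend = 1) {
  stopifnot(is.matrix(x), blend >= 0, blend <= 1)
  n <- ncol(x)
  out <- x
  maps <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("channel ", i, " is constant; cannot gaussianize")
    g <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
    out[i, ] <- blend * g + (1 - blend) * (v - mean(v)) / s
    qs <- seq(0, 1, length.out = min(65L, n))
    maps[[i]] <- data.frame(x = as.numeric(stats::quantile(v, qs)),
                            g = as.numeric(stats::quantile(out[i, ], qs)))
  }
  structure(list(data = out, maps = maps), class = "gaussianized")
}

#' Fixed-point fastICA with symmetric decorrelation
#'
#' Log-cosh contrast, symmetric orthogonalization each sweep. Convergence is
#' declared when every row of the new unmixing matrix is collinear with its
#' predecessor: `max_i |1 - |diag(W W_prev')_i|| < tol`.
#'
#' @param xw whitened data, components-by-samples.
#' @param n_components number of sources (`<= nrow(xw)`).
#' @param seed integer seed for the random orthogonal initialization.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap; on hitting it the best estimate is
#'   returned with `converged = FALSE` and a warning.
#' @param alpha log-cosh slope parameter.
#' @return A list of class `fastica_fit`: `W` (unmixing, orthonormal rows),
#'   `sources` (`W %*% xw`), `iterations`, `converged`, `tol`.
#' @export
fastica_symmetric <- function(xw, n_components = nrow(xw), seed = 1,
                              tol = 1e-4, max_iter = 1000, alpha = 1) {
  stopifnot(is.matrix(xw), n_components >= 1, n_components <= nrow(xw))
  m <- ncol(xw)
  set.seed(derive_seed(seed, 7L))
  W <- matrix(stats::rnorm(n_components * nrow(xw)), n_components)
  sym_decorr <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorr(W)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    wx <- W %*% xw
    gwx <- tanh(alpha * wx)
    gp <- alpha * rowMeans(1 - gwx^2)
    W1 <- gwx %*% t(xw) / m - gp * W
    W1 <- sym_decorr(W1)
    delta <- max(abs(1 - abs(diag(W1 %*% t(W)))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fastICA did not converge in ", max_iter, " iterations")
  structure(list(W = W, sources = W %*% xw, iterations = it,
                 converged = converged, tol = tol),
            class = "fastica_fit")
}

#' Amari index between a true and an estimated mixing
#'
#' Permutation- and scale-invariant distance in [0, 1]; 0 means perfect
#' unmixing up to permutation and scaling.
#'
#' @param A true mixing matrix (sources in columns).
#' @param W estimated unmixing matrix.
#' @return The normalized Amari index of `P = W %*% A`.
#' @export
amari_index <- function(A, W) {
  P <- abs(W %*% A)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * n * (n - 1))
}

#' Z-score a spatial map over mask voxels
#'
#' @param map numeric vector (mask voxels) or 3D array.
#' @param mask logical 3D array, required when `map` is an array; voxels
#'   outside the mask are zero-filled.
#' @return Z-scored map of the same shape (mean 0, sd 1 over mask voxels).
#' @export
zscore_map <- function(map, mask = NULL) {
  if (is.array(map) && length(dim(map)) == 3L) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(map)))
    v <- map[mask]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance map; cannot z-score")
    out <- array(0, dim = dim(map))
    out[mask] <- (v - mean(v)) / s
    return(out)
  }
  s <- stats::sd(map)
  if (!is.finite(s) || s == 0) stop("zero-variance map; cannot z-score")
  (map - mean(map)) / s
}

subject_matrix <- function(bold, mask) {
  # volumes x mask voxels
  t(matrix(bold$data, ncol = bold$n_volumes)[which(mask), , drop = FALSE])
}

#' Post-nonlinear group ICA with dual-regression back-reconstruction
#'
#' Runs, for one cohort: per-volume rank gaussianization over mask voxels
#' (inverting the channel-wise post-nonlinearity; disabled in linear mode),
#' subject-level temporal PCA, temporal concatenation, group-level PCA with
#' whitening, and symmetric fastICA on the whitened data. Subject-specific
#' maps are recovered by dual regression against each subject's (non
#' gaussianized) preprocessed data, and all maps are z-scored over the mask.
#' Component signs are fixed so each z-map has positive skewness.
#'
#' @param bolds list of preprocessed [bold4d()] objects (>= 2 subjects).
#' @param mask logical 3D brain mask on the shared grid.
#' @param order number of components; `NULL` estimates it with
#'   [estimate_order_mdl()] on the concatenated data.
#' @param seed integer seed (initialization of fastICA).
#' @param pnl logical; `FALSE` switches gaussianization off (linear group
#'   ICA, for comparison).
#' @param subject_order per-subject retained temporal dimension; default
#'   `ceiling(1.5 * order)` capped by the data.
#' @param blend gaussianization blend, see [gaussianize_channels()].
#' @param tol,max_iter fastICA settings.
#' @param max_order cap for MDL order estimation when `order` is `NULL`.
#' @return A list of class `pnl_ica`: `group_maps` (components x voxels,
#'   z-scored), `group_maps_raw`, `group_timecourses` (components x time,
#'   averaged over subjects), `subject_maps` (subjects x components x
#'   voxels), `subject_timecourses` (list), `inverse_nonlinearities` (per
#'   subject, fitted monotone channel maps, PNL mode only), `order`,
#'   `convergence`, `mask`, `grid`.
#' @export
pnl_group_ica <- function(bolds, mask, order = NULL, seed = 1,
                          pnl = TRUE, subject_order = NULL, blend = 1,
                          tol = 1e-4, max_iter = 1000, max_order = 20L) {
  stopifnot(is.list(bolds), length(bolds) >= 2,
            all(vapply(bolds, inherits, TRUE, "bold4d")),
            is.logical(mask))
  grid <- bolds[[1]]$grid
  for (b in bolds)
    if (!identical(b$grid$shape, grid$shape))
      stop("subjects are on inconsistent grids")
  xs <- lapply(bolds, subject_matrix, mask = mask)  # volumes x voxels

  inv_nl <- NULL
  if (pnl) {
    gz <- lapply(xs, gaussianize_channels, blend = blend)
    xs <- lapply(gz, `[[`, "data")
    inv_nl <- lapply(gz, `[[`, "maps")
  }

  if (is.null(order)) {
    cat_data <- do.call(rbind, xs)                  # channels x voxels
    mo <- estimate_order_mdl(t(cat_data),
                             max_order = min(max_order, nrow(cat_data) - 1L))
    order <- mo$n_components
  }
  k1 <- if (is.null(subject_order)) ceiling(1.5 * order) else subject_order
  k1 <- min(k1, min(vapply(xs, nrow, 1L)) - 1L)
  if (k1 < order)
    stop("subject-level order ", k1, " below group order ", order)

  red_sub <- lapply(xs, reduce_pca, n_components = k1)
  ycat <- do.call(rbind, lapply(red_sub, `[[`, "reduced"))
  if (order > nrow(ycat))
    stop("order ", order, " exceeds concatenated rank ", nrow(ycat))
  red_grp <- reduce_pca(ycat, n_components = order)
  fit <- fastica_symmetric(red_grp$reduced, n_components = order,
                           seed = seed, tol = tol, max_iter = max_iter)
  maps_raw <- fit$sources                            # comp x voxels

  # dual regression against the preprocessed (non-gaussianized) data
  orig <- lapply(bolds, subject_matrix, mask = mask)
  n_sub <- length(orig)
  nv <- ncol(maps_raw)
  Mt <- t(maps_raw)
  proj <- Mt %*% solve(crossprod(Mt))                # voxels x comp
  subj_tc <- vector("list", n_sub)
  subj_maps <- array(NA_real_, dim = c(n_sub, order, nv))
  for (i in seq_len(n_sub)) {
    Ti <- orig[[i]] %*% proj                         # time x comp
    Bi <- solve(crossprod(Ti), t(Ti) %*% orig[[i]])  # comp x voxels
    subj_tc[[i]] <- Ti
    subj_maps[i, , ] <- Bi
  }

  zmaps <- t(apply(maps_raw, 1, zscore_map))
  sk <- apply(zmaps, 1, function(v) mean(v^3))
  flip <- ifelse(sk < 0, -1, 1)
  zmaps <- zmaps * flip
  maps_raw <- maps_raw * flip
  for (i in seq_len(n_sub)) {
    subj_tc[[i]] <- sweep(subj_tc[[i]], 2, flip, `*`)
    subj_maps[i, , ] <- subj_maps[i, , ] * flip
  }
  subj_zmaps <- subj_maps
  for (i in seq_len(n_sub))
    for (k in seq_len(order))
      subj_zmaps[i, k, ] <- zscore_map(subj_maps[i, k, ])

  tmin <- min(vapply(subj_tc, nrow, 1L))
  gtc <- Reduce(`+`, lapply(subj_tc, function(m) m[seq_len(tmin), ])) / n_sub

  structure(list(group_maps = zmaps, group_maps_raw = maps_raw,
                 group_timecourses = t(gtc),
                 subject_maps = subj_zmaps, subject_maps_raw = subj_maps,
                 subject_timecourses = subj_tc,
                 inverse_nonlinearities = inv_nl,
                 order = order, pnl = pnl,
                 convergence = list(iterations = fit$iterations,
                                    converged = fit$converged,
                                    tol = tol, seed = seed),
                 mask = mask, grid = grid),
            class = "pnl_ica")
}

#' @export
print.pnl_ica <- function(x, ...) {
  cat(sprintf("pnl_ica: %d components, %d subjects, %s mode, %s (%d iter)\n",
              x$order, dim(x$subject_maps)[1],
              if (x$pnl) "post-nonlinear" else "linear",
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  invisible(x)
}
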