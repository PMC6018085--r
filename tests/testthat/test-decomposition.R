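# Simulated spectra with q strong orthogonal components + isotropic noise.
make_low_rank <- function(n = 800, p = 20, q = 5, noise = 0.05, seed = 1) {
  set.seed(seed)
  U <- qr.Q(qr(matrix(rnorm(p * q), p, q)))
  scores <- matrix(rnorm(n * q), n, q) %*% diag(seq(3, 2, length.out = q))
  scores %*% t(U) + matrix(rnorm(n * p, sd = noise), n, p)
}

test_that("MDL recovers the true order on low-rank spectra", {
  for (q in c(3, 5, 8)) {
    mo <- estimate_order_mdl(make_low_rank(q = q, seed = q), max_order = 15)
    expect_equal(mo$n_components, q)
  }
})

test_that("MDL floors at one on white noise and is deterministic", {
  set.seed(4)
  x <- matrix(rnorm(600 * 12), 600, 12)
  mo <- estimate_order_mdl(x, max_order = 8)
  expect_lte(mo$n_components, 1)
  mo2 <- estimate_order_mdl(x, max_order = 8)
  expect_identical(mo$curve, mo2$curve)
  expect_error(estimate_order_mdl(matrix(rnorm(5 * 12), 5, 12),
                                  max_order = 8),
               "non-positive")
})

test_that("reduce_pca round-trips losslessly at full rank", {
  set.seed(5)
  x <- matrix(rnorm(8 * 300), 8, 300)
  p <- reduce_pca(x, 8)
  expect_lt(max(abs(pca_reconstruct(p) - x)), 1e-8)
  # whitened output has identity covariance
  expect_equal(tcrossprod(p$reduced) / (300 - 1), diag(8),
               tolerance = 1e-8)
})

test_that("reduce_pca handles rank-1 data and over-requests", {
  u <- rnorm(6); v <- rnorm(100)
  x <- outer(u, v)
  p <- reduce_pca(x, 1)
  expect_lt(max(abs(pca_reconstruct(p) - x)), 1e-8)
  expect_error(reduce_pca(x, 3), "rank")
})

test_that("PCA reconstruction error equals the discarded eigenvalue mass", {
  set.seed(6)
  x <- matrix(rnorm(50 * 200), 50, 200)
  p <- reduce_pca(x, 10)
  err <- sum((pca_reconstruct(p) - x)^2) / (200 - 1)
  lam <- eigen(tcrossprod(sweep(x, 1, rowMeans(x))) / (200 - 1),
               symmetric = TRUE, only.values = TRUE)$values
  expect_equal(err, sum(lam[11:50]), tolerance = 1e-8)
})

test_that("gaussianize_channels is near-identity on Gaussian input", {
  set.seed(7)
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  g <- gaussianize_channels(x)
  expect_gt(cor(g$data[1, ], x[1, ]), 0.99)
  expect_identical(rank(g$data[1, ]), rank(x[1, ]))
})

test_that("gaussianize_channels symmetrizes a tanh-distorted channel", {
  set.seed(8)
  z <- rnorm(5000)
  x <- rbind(tanh(z) + 0.05 * z)
  g <- gaussianize_channels(x)$data[1, ]
  skew <- mean((g - mean(g))^3) / sd(g)^3
  kurt <- mean((g - mean(g))^4) / sd(g)^4 - 3
  expect_lt(abs(skew), 0.1)
  expect_lt(abs(kurt), 0.3)
})

test_that("gaussianization is exactly invariant to monotone distortion", {
  set.seed(9)
  x <- matrix(rnorm(300), 1, 300)
  f <- function(v) v + 0.3 * v^3
  expect_identical(gaussianize_channels(x)$data,
                   gaussianize_channels(f(x))$data)
  expect_error(gaussianize_channels(matrix(1, 1, 100)), "constant")
})

test_that("gaussianize blend 0 reduces to standardization", {
  set.seed(10)
  x <- matrix(rexp(200), 1, 200)
  g0 <- gaussianize_channels(x, blend = 0)$data[1, ]
  expect_equal(g0, as.numeric(scale(x[1, ])), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fastICA separates independent uniform sources", {
  set.seed(11)
  S <- matrix(runif(2 * 4000, -sqrt(3), sqrt(3)), 2)
  th <- 0.7
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fit <- fastica_symmetric(A %*% S, 2, seed = 3)
  expect_true(fit$converged)
  cm <- abs(cor(t(fit$sources), t(S)))
  expect_gt(max(cm[1, ]), 0.95)
  expect_gt(max(cm[2, ]), 0.95)
  # permutation structure: each source claimed once
  expect_equal(sort(apply(cm, 1, which.max)), 1:2)
})

test_that("fastICA is deterministic given a seed and handles one component", {
  set.seed(12)
  x <- matrix(runif(3 * 1000, -1, 1), 3)
  xw <- reduce_pca(x, 3)$reduced
  f1 <- fastica_symmetric(xw, 3, seed = 5)
  f2 <- fastica_symmetric(xw, 3, seed = 5)
  expect_identical(f1$W, f2$W)

  s <- matrix(runif(1500, -1, 1), 1)
  sw <- reduce_pca(rbind(s), 1)$reduced
  f3 <- fastica_symmetric(sw, 1, seed = 1)
  expect_gt(abs(cor(f3$sources[1, ], s[1, ])), 0.999)
})

test_that("fastICA warns when it cannot converge", {
  set.seed(13)
  xw <- reduce_pca(matrix(rnorm(2 * 500), 2), 2)$reduced
  expect_warning(fastica_symmetric(xw, 2, seed = 1, max_iter = 2),
                 "did not converge")
})

test_that("amari_index is zero for scaled permutations and positive otherwise", {
  A <- diag(3)
  W <- rbind(c(0, 2, 0), c(0, 0, -1), c(0.5, 0, 0))  # scaled permutation
  expect_equal(amari_index(A, W), 0)
  expect_gt(amari_index(A, matrix(1, 3, 3) + diag(3)), 0.1)
})

test_that("zscore_map standardizes, is idempotent, and rejects constants", {
  v <- c(3, 5, 7, 9)
  z <- zscore_map(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore_map((v - 5) / 2), z, tolerance = 1e-12)
  expect_equal(zscore_map(z), z, tolerance = 1e-12)
  expect_error(zscore_map(rep(2, 10)), "zero-variance")

  mask <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                dim = c(2, 2, 2))
  m3 <- array(0, dim = c(2, 2, 2)); m3[mask] <- v
  z3 <- zscore_map(m3, mask)
  expect_equal(z3[mask], z, tolerance = 1e-12)
  expect_true(all(z3[!mask] == 0))
})

test_that("group ICA recovers sources from a clean linear study", {
  g <- volume_grid(c(14, 14, 10))
  tm <- make_templates(g, 4, seed = 31)
  mx <- pnl_mixing_spec(4, noise_sd = 0.05)
  bolds <- lapply(1:3, function(i)
    simulate_subject(tm, mx, n_volumes = 100, seed = 40 + i)$bold)
  fit <- suppressWarnings(pnl_group_ica(bolds, tm$mask, order = 4, seed = 1,
                                        pnl = FALSE))
  expect_s3_class(fit, "pnl_ica")
  expect_equal(dim(fit$group_maps), c(4, sum(tm$mask)))
  expect_equal(dim(fit$subject_maps), c(3, 4, sum(tm$mask)))
  # each z-map standardized over the mask
  expect_equal(unname(rowMeans(fit$group_maps)), rep(0, 4),
               tolerance = 1e-8)
  truth <- vapply(tm$templates, function(w) w[tm$mask],
                  numeric(sum(tm$mask)))
  cm <- abs(cor(t(fit$group_maps), truth))
  matched <- apply(cm, 2, max)
  expect_gt(mean(matched), 0.8)
})

test_that("group ICA validates order against the concatenated rank", {
  g <- volume_grid(c(10, 10, 6))
  tm <- make_templates(g, 2, seed = 3)
  mx <- pnl_mixing_spec(2, noise_sd = 0.2)
  bolds <- lapply(1:2, function(i)
    simulate_subject(tm, mx, n_volumes = 30, seed = i)$bold)
  expect_error(
    suppressWarnings(pnl_group_ica(bolds, tm$mask, order = 40, seed = 1)))
})
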