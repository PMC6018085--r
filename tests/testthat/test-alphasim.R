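test_that("alphasim_config validates its fields", {
  expect_s3_class(alphasim_config(), "alphasim_config")
  expect_error(alphasim_config(voxel_p = 0))
  expect_error(alphasim_config(n_iterations = 10))
  expect_error(alphasim_config(connectivity = 10))
})

test_that("smoothness estimate recovers a known kernel within 20 percent", {
  g <- volume_grid(c(20, 20, 14))
  mask <- array(TRUE, dim = g$shape)
  set.seed(1)
  ests <- replicate(20, {
    maps <- lapply(1:2, function(i) {
      v <- array(rnorm(prod(g$shape)), dim = g$shape)
      smooth_gaussian(v, 6, grid = g)
    })
    mean(estimate_smoothness(maps, g, mask))
  })
  expect_lt(abs(median(ests) - 6) / 6, 0.2)
})

test_that("smoothness of white noise hits the estimator floor", {
  g <- volume_grid(c(16, 16, 12))
  mask <- array(TRUE, dim = g$shape)
  set.seed(2)
  maps <- lapply(1:4, function(i) array(rnorm(prod(g$shape)),
                                        dim = g$shape))
  est <- estimate_smoothness(maps, g, mask)
  floor_mm <- 3 * 2 * sqrt(log(2) / pi)
  expect_true(all(est >= floor_mm - 1e-9))
  expect_true(all(est < 6))
  expect_error(
    estimate_smoothness(lapply(1:2, function(i)
      array(1, dim = g$shape)), g, mask),
    "constant")
})

test_that("label_clusters handles canonical connectivity cases", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  lc <- label_clusters(m)
  expect_equal(lc$sizes, 1L)

  # two voxels sharing only a corner
  m2 <- array(FALSE, dim = c(5, 5, 5))
  m2[2, 2, 2] <- TRUE; m2[3, 3, 3] <- TRUE
  expect_length(label_clusters(m2, 26)$sizes, 1)
  expect_length(label_clusters(m2, 6)$sizes, 2)
  # edge neighbours differ between 6 and 18
  m3 <- array(FALSE, dim = c(5, 5, 5))
  m3[2, 2, 2] <- TRUE; m3[3, 3, 2] <- TRUE
  expect_length(label_clusters(m3, 18)$sizes, 1)
  expect_length(label_clusters(m3, 6)$sizes, 2)

  empty <- label_clusters(array(FALSE, dim = c(3, 3, 3)))
  expect_length(empty$sizes, 0)
})

test_that("label_clusters agrees with the flood-fill oracle", {
  set.seed(3)
  for (i in 1:6) {
    conn <- c(6, 18, 26)[(i %% 3) + 1]
    m <- array(runif(10 * 10 * 8) < 0.3, dim = c(10, 10, 8))
    lc <- label_clusters(m, conn)
    oracle <- flood_fill_labels(m, conn)
    expect_equal(length(lc$sizes), max(oracle))
    expect_equal(sort(lc$sizes), sort(as.integer(table(oracle[oracle > 0]))))
  }
})

test_that("cluster_threshold_mc boundary behaviour", {
  g <- volume_grid(c(10, 10, 6))
  mask <- array(TRUE, dim = g$shape)
  # near-1 corrected alpha with a sparse voxel threshold: everything passes
  cfg <- alphasim_config(n_iterations = 100, seed = 1,
                         corrected_alpha = 0.999, voxel_p = 0.001,
                         two_sided = FALSE)
  mc <- cluster_threshold_mc(cfg, mask, c(0, 0, 0), g)
  expect_equal(mc$k_star, 1L)

  cfg2 <- alphasim_config(n_iterations = 100, seed = 1,
                          voxel_p = 0.001, two_sided = FALSE)
  mc2 <- cluster_threshold_mc(cfg2, mask, c(0, 0, 0), g)
  expect_lte(mc2$k_star, 2L)

  expect_error(
    cluster_threshold_mc(alphasim_config(n_iterations = 100, seed = 1,
                                         corrected_alpha = 0.005),
                         mask, c(0, 0, 0), g),
    "resolution")
})

test_that("cluster extent threshold grows with smoothness", {
  g <- volume_grid(c(14, 14, 10))
  mask <- array(TRUE, dim = g$shape)
  ks <- vapply(c(0, 6, 12), function(fw) {
    cfg <- alphasim_config(n_iterations = 150, seed = 7)
    cluster_threshold_mc(cfg, mask, rep(fw, 3), g)$k_star
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_gt(ks[3], ks[1])
})

test_that("covariance bootstrap is calibrated on independent-voxel residuals", {
  g <- volume_grid(c(12, 12, 8))
  roi <- array(FALSE, dim = g$shape)
  roi[3:9, 3:9, 3:5] <- TRUE
  set.seed(8)
  resid <- matrix(rnorm(10 * sum(roi)), 10)
  resid <- sweep(resid, 2, colMeans(resid))
  cfg <- alphasim_config(n_iterations = 200, seed = 2)
  bt <- cluster_threshold_boot(cfg, list(a = resid), list(a = roi), g,
                               n_a = 5, n_b = 5)
  expect_s3_class(bt, "alphasim_result")
  expect_equal(bt$method, "covariance")
  expect_gte(bt$k_star, 1L)
  # determinism
  bt2 <- cluster_threshold_boot(cfg, list(a = resid), list(a = roi), g,
                                n_a = 5, n_b = 5)
  expect_identical(bt$max_sizes, bt2$max_sizes)
  # on iid residuals the bootstrap cannot exceed the familywise truth by much:
  # compare against direct simulation of iid-noise two-sample t maps
  set.seed(9)
  ref <- replicate(200, {
    X <- matrix(rnorm(10 * sum(roi)), 10)
    tt <- two_sample_tmap(X[1:5, ], X[6:10, ])
    supra <- array(FALSE, dim = g$shape)
    supra[roi] <- tt$p < cfg$voxel_p
    lc <- label_clusters(supra, 26)
    if (length(lc$sizes)) max(lc$sizes) else 0L
  })
  k_ref <- quantile(ref, 0.95, type = 1)
  expect_lt(abs(bt$k_star - k_ref), max(5, k_ref))
})

test_that("bootstrap widens the extent threshold under spatial dependence", {
  # smooth residual maps carry spatially correlated nulls, so the extent
  # threshold must exceed the one obtained from independent-voxel residuals
  g <- volume_grid(c(12, 12, 8))
  roi <- array(FALSE, dim = g$shape)
  roi[3:10, 3:10, 3:6] <- TRUE
  nv <- sum(roi)
  set.seed(10)
  resid <- t(vapply(1:12, function(i) {
    v <- array(rnorm(prod(g$shape)), dim = g$shape)
    smooth_gaussian(v, 9, grid = g)[roi]
  }, numeric(nv)))
  resid <- sweep(resid, 2, colMeans(resid))
  cfg <- alphasim_config(n_iterations = 150, seed = 3)
  bt <- cluster_threshold_boot(cfg, list(a = resid), list(a = roi), g,
                               n_a = 6, n_b = 6)
  iid_resid <- matrix(rnorm(12 * nv), 12)
  iid_resid <- sweep(iid_resid, 2, colMeans(iid_resid))
  iid <- cluster_threshold_boot(cfg, list(a = iid_resid), list(a = roi), g,
                                n_a = 6, n_b = 6)
  expect_gt(bt$k_star, iid$k_star)
})

test_that("report_clusters filters, sorts, labels and records k_star", {
  g <- volume_grid(c(10, 10, 6))
  tmap <- array(0, dim = g$shape)
  supra <- array(FALSE, dim = g$shape)
  supra[2:4, 2:4, 2:3] <- TRUE      # 18 voxels
  tmap[2:4, 2:4, 2:3] <- 3
  tmap[3, 3, 2] <- 5                 # peak
  supra[8, 8, 5] <- TRUE             # singleton, below k*
  tmap[8, 8, 5] <- 4
  labels <- array(0L, dim = g$shape); labels[2:4, 2:4, 2:3] <- 2L
  ct <- report_clusters(tmap, supra, k_star = 5, g,
                        label_volume = labels,
                        label_names = c("1" = "DMN", "2" = "CEN"))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$n_voxels, 18)
  expect_equal(ct$peak_t, 5)
  expect_equal(c(ct$peak_x_mm, ct$peak_y_mm, ct$peak_z_mm),
               voxel_to_mm(g, c(3, 3, 2)))
  expect_equal(ct$labels, "CEN")
  expect_equal(attr(ct, "k_star"), 5)

  none <- report_clusters(tmap, array(FALSE, dim = g$shape), 5, g)
  expect_equal(nrow(none), 0)
  expect_error(report_clusters(tmap, supra, 5, g,
                               label_volume = array(0L, dim = c(2, 2, 2))),
               "mismatch")
})

test_that("cluster tables round-trip through TSV with the k_star header", {
  g <- volume_grid(c(6, 6, 4))
  tmap <- array(0, dim = g$shape)
  supra <- array(FALSE, dim = g$shape)
  supra[2:3, 2:3, 2] <- TRUE; tmap[2:3, 2:3, 2] <- 2.5
  ct <- report_clusters(tmap, supra, 2, g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(ct, path)
  lines <- readLines(path)
  expect_match(lines[1], "k_star = 2")
  rd <- read.delim(path, comment.char = "#")
  expect_equal(rd$n_voxels, ct$n_voxels)
})
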