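test_that("make_templates produces distinct named templates and a mask", {
  g <- volume_grid(c(20, 20, 12))
  tm <- make_templates(g, n_networks = 8, seed = 1)
  expect_s3_class(tm, "rsn_templates")
  expect_length(tm$templates, 8)
  expect_named(tm$templates,
               c("DMN", "CEN", "VN", "AN", "SRN", "SMN", "DAN", "CN"))
  expect_true(all(vapply(tm$templates, max, 1) == 1))
  expect_true(any(tm$mask))
  # largely non-overlapping: pairwise spatial correlation below 0.3
  vs <- vapply(tm$templates, function(w) w[tm$mask], numeric(sum(tm$mask)))
  cm <- cor(vs)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.3)
})

test_that("make_templates single-network and determinism cases", {
  g <- volume_grid(c(20, 20, 12))
  tm1 <- make_templates(g, 1, seed = 4)
  expect_length(tm1$templates, 1)
  expect_equal(spatial_correlation(tm1$templates[[1]], tm1$templates[[1]],
                                   tm1$mask), 1)
  a <- make_templates(g, 8, seed = 9)
  b <- make_templates(g, 8, seed = 9)
  expect_identical(a$templates, b$templates)
  expect_identical(a$mask, b$mask)
})

test_that("make_templates refuses a grid too small for the request", {
  expect_error(make_templates(volume_grid(c(4, 4, 3)), 8, seed = 1),
               "too small")
})

test_that("nonlinearity family is validated and monotone-checked", {
  f <- pnl_nonlinearity("cubic", a = 1, b = 0.5)
  expect_equal(f$fun(2), 1 * 2 + 0.5 * 8)
  expect_error(pnl_nonlinearity("cubic", a = -1, b = 0.5), "a > 0")
  expect_error(pnl_nonlinearity("tanhlin", c = 1, d = 0), "d > 0")
  expect_error(pnl_mixing_spec(3, matrix(1, 3, 3)), "full row rank")
})

test_that("identity nonlinearity and zero noise give the exact linear mixture", {
  g <- volume_grid(c(12, 12, 8))
  tm <- make_templates(g, 3, seed = 2)
  mx <- pnl_mixing_spec(3, noise_sd = 0)
  s <- simulate_subject(tm, mx, n_volumes = 30, seed = 5)
  Y <- matrix(s$bold$data, ncol = 30)[s$truth$mask_idx, ]
  expect_equal(Y, s$truth$loadings %*% s$truth$timecourses,
               tolerance = 1e-12)
})

test_that("simulate_subject honours acquisition parameters", {
  g <- volume_grid(c(10, 10, 6))
  tm <- make_templates(g, 2, seed = 3)
  mx <- pnl_mixing_spec(2)
  s <- simulate_subject(tm, mx, n_volumes = 130, tr_s = 3.0, seed = 1)
  expect_equal(s$bold$n_volumes, 130)
  expect_equal(s$bold$tr_s, 3.0)
  expect_equal(nrow(s$motion), 130)
  expect_equal(ncol(s$motion), 6)
  expect_true(all(is.finite(s$bold$data)))
})

test_that("zero effect size leaves the groups exchangeable in the target region", {
  g <- volume_grid(c(12, 12, 8))
  tm <- make_templates(g, 3, seed = 7)
  mx <- pnl_mixing_spec(3, noise_sd = 0.3)
  core <- network_core_region(tm, 1)
  ts <- vapply(seq_len(50), function(i) {
    s <- 5000L + 2L * i
    a <- simulate_subject(tm, mx, effect = NULL, n_volumes = 40, seed = s)
    b <- simulate_subject(tm, mx,
                          effect = group_effect_spec(1, core, "decrease",
                                                     effect_size = 0),
                          n_volumes = 40, seed = s + 1L)
    fa <- mean(cor(t(matrix(a$bold$data, ncol = 40)[which(core), ]),
                   a$truth$timecourses[1, ]))
    fb <- mean(cor(t(matrix(b$bold$data, ncol = 40)[which(core), ]),
                   b$truth$timecourses[1, ]))
    fb - fa
  }, numeric(1))
  tt <- t.test(ts)
  expect_lt(abs(tt$statistic), 2.5)
})

test_that("effect regions are validated against the network support", {
  g <- volume_grid(c(12, 12, 8))
  tm <- make_templates(g, 2, seed = 3)
  mx <- pnl_mixing_spec(2)
  outside <- array(FALSE, dim = g$shape)
  outside[which(tm$templates[[1]] == 0 & tm$mask)[1]] <- TRUE
  expect_error(
    simulate_subject(tm, mx, n_volumes = 30, seed = 1,
                     effect = group_effect_spec(1, outside, "increase", 0.3)),
    "support")
  expect_error(
    simulate_subject(tm, mx, n_volumes = 30, seed = 1,
                     effect = group_effect_spec(9, network_core_region(tm, 1),
                                                "increase", 0.3)),
    "unknown network")
})

test_that("planted effects shift correlations toward the recorded targets", {
  g <- volume_grid(c(14, 14, 10))
  tm <- make_templates(g, 3, seed = 11)
  mx <- pnl_mixing_spec(3, noise_sd = 0)
  core <- network_core_region(tm, 2)
  s <- simulate_subject(tm, mx, n_volumes = 60, seed = 2,
                        effect = group_effect_spec(2, core, "decrease", 0.4))
  pl <- s$truth$planted[[1]]
  Y <- matrix(s$bold$data, ncol = 60)
  got <- vapply(seq_along(pl$voxels), function(j)
    cor(Y[pl$voxels[j], ], s$truth$timecourses[2, ]), numeric(1))
  expect_equal(got, pl$target_r, tolerance = 1e-6)
})

test_that("simulate_group_study builds study-sized cohorts deterministically", {
  g <- volume_grid(c(10, 10, 6))
  st <- simulate_group_study(32, 38, grid = g, n_networks = 2,
                             n_volumes = 24, seed = 1)
  expect_equal(nrow(st$manifest), 70)
  expect_equal(as.integer(table(st$group)), c(32, 38))

  st2 <- simulate_group_study(2, 2, grid = g, n_networks = 2,
                              n_volumes = 24, seed = 5)
  expect_length(st2$subjects, 4)
  st3 <- simulate_group_study(2, 2, grid = g, n_networks = 2,
                              n_volumes = 24, seed = 5)
  expect_identical(st2$manifest, st3$manifest)
  expect_identical(st2$subjects[[1]]$bold$data, st3$subjects[[1]]$bold$data)
})

test_that("planted FC shift grows monotonically with effect size", {
  g <- volume_grid(c(12, 12, 8))
  shifts <- vapply(c(0, 0.2, 0.4), function(es) {
    tm <- make_templates(g, 3, seed = 33)  # study below shares this seed
    mx <- pnl_mixing_spec(3, noise_sd = 0.3)
    core <- network_core_region(tm, 1)
    eff <- if (es > 0)
      list(group_effect_spec(1, core, "decrease", es)) else list()
    st <- simulate_group_study(3, 3, grid = g, n_networks = 3,
                               effects = eff, mixing = mx,
                               n_volumes = 50, seed = 33)
    fc <- vapply(st$subjects, function(s) {
      Y <- matrix(s$bold$data, ncol = 50)
      mean(cor(t(Y[which(core), ]), s$truth$timecourses[1, ]))
    }, numeric(1))
    mean(fc[st$group == "B"]) - mean(fc[st$group == "A"])
  }, numeric(1))
  expect_true(all(diff(shifts) < 0))  # "decrease" effects push B below A
  expect_gt(abs(shifts[3]), abs(shifts[2]))
})

test_that("motion traces can be generated to violate the exclusion limit", {
  g <- volume_grid(c(10, 10, 6))
  tm <- make_templates(g, 2, seed = 3)
  mx <- pnl_mixing_spec(2)
  ok <- simulate_subject(tm, mx, n_volumes = 30, seed = 1)
  bad <- simulate_subject(tm, mx, n_volumes = 30, seed = 1,
                          motion_violate = TRUE)
  expect_lte(max(abs(as.matrix(ok$motion[, 1:3]))), 2.5)
  expect_gt(max(abs(as.matrix(bad$motion[, 1:3]))), 2.5)
})

test_that("written studies read back with identical content", {
  g <- volume_grid(c(10, 10, 6))
  st <- simulate_group_study(2, 2, grid = g, n_networks = 2,
                             n_volumes = 24, seed = 8)
  dir <- withr::local_tempdir()
  write_group_study(st, dir)
  rd <- read_group_study(dir)
  expect_equal(rd$group, st$group)
  expect_equal(rd$templates$mask, st$templates$mask)
  expect_equal(rd$templates$templates$DMN, st$templates$templates$DMN,
               tolerance = 1e-6)
  expect_equal(rd$subjects[[1]]$bold$data, st$subjects[[1]]$bold$data,
               tolerance = 1e-6)
  expect_equal(rd$subjects[[1]]$bold$tr_s, 3.0)
  expect_equal(as.matrix(rd$subjects[[3]]$motion),
               as.matrix(st$subjects[[3]]$motion),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("least-squares unmixing of a clean linear study recovers the maps", {
  g <- volume_grid(c(14, 14, 10))
  tm <- make_templates(g, 4, seed = 13)
  mx <- pnl_mixing_spec(4, noise_sd = 0)
  s <- simulate_subject(tm, mx, n_volumes = 80, seed = 3)
  Y <- matrix(s$bold$data, ncol = 80)[s$truth$mask_idx, ]
  U <- s$truth$timecourses
  M_hat <- Y %*% t(U) %*% solve(U %*% t(U))
  for (k in 1:4)
    expect_gt(cor(M_hat[, k], s$truth$loadings[, k]), 0.99)
})
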