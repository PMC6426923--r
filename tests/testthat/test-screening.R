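test_that("null voxelwise GLM t statistics match the Student-t oracle", {
  set.seed(1)
  n <- 24
  maps <- array(rnorm(10 * 10 * 10 * n), c(10, 10, 10, n))
  outc <- rnorm(n)
  covs <- cbind(age = rnorm(n), grp = rbinom(n, 1, 0.5))
  tmap <- massunivariate_glm(maps, outc, covs)
  df <- attr(tmap, "df")
  expect_equal(df, n - 4L)
  # analytic E|t| for the central t distribution
  e_abs_t <- sqrt(df / pi) * gamma((df - 1) / 2) / gamma(df / 2)
  mc_se <- sd(abs(tmap)) / sqrt(length(tmap))
  expect_lt(abs(mean(abs(tmap)) - e_abs_t), 4 * mc_se)
  # roughly 5% exceedances at the 5% two-sided quantile
  exc <- mean(abs(tmap) > qt(0.975, df))
  expect_lt(abs(exc - 0.05), 0.02)
})

test_that("degenerate designs behave as documented", {
  set.seed(2)
  n <- 12
  outc <- rnorm(n)
  maps <- array(rnorm(4 * 4 * 4 * n), c(4, 4, 4, n))
  # a voxel that carries the outcome exactly: capped t
  maps[1, 1, 1, ] <- outc
  tmap <- massunivariate_glm(maps, outc)
  expect_gte(abs(tmap[1, 1, 1]), 1e5)
  # zero-variance voxel: t = 0
  maps[2, 2, 2, ] <- 3
  expect_equal(massunivariate_glm(maps, outc)[2, 2, 2], 0)
  # covariate equal to the outcome: all t zero, with a warning
  expect_warning(t0 <- massunivariate_glm(maps, outc,
                                          covariates = cbind(o = outc)),
                 "collinear")
  expect_true(all(t0 == 0))
  # collinearity inside the covariate block errors, naming columns
  expect_error(massunivariate_glm(maps, outc,
                                  covariates = cbind(a = 1:n, b = 2 * (1:n))),
               "collinear column")
})

test_that("TFCE matches the closed-form single-voxel sum and is monotone", {
  z <- array(0, c(5, 5, 5))
  expect_true(all(tfce_enhance(z) == 0))
  h0 <- 3.7
  z[3, 3, 3] <- h0
  dh <- 0.1
  enh <- tfce_enhance(z, E = 0.5, H = 2, dh = dh)
  expect_equal(enh[3, 3, 3], tfce_single_voxel(h0, 0.5, 2, dh),
               tolerance = 1e-10)
  expect_true(all(enh[-63] == 0))
  expect_error(tfce_enhance(z, E = -1), "nonnegative")
  # monotonicity: raising one voxel never lowers any enhanced value
  set.seed(5)
  for (i in 1:5) {
    m <- array(abs(rnorm(6^3)), c(6, 6, 6))
    e1 <- tfce_enhance(m, dh = 0.05)
    m2 <- m
    idx <- sample(6^3, 1)
    m2[idx] <- m2[idx] + 0.8
    e2 <- tfce_enhance(m2, dh = 0.05)
    expect_true(all(e2 >= e1 - 1e-10))
  }
})

test_that("TFCE with E = 0 ranks isolated voxels like their heights (maxT limit)", {
  z <- array(0, c(6, 6, 6))
  z[1, 1, 1] <- 2.1
  z[3, 3, 3] <- 3.4
  z[5, 5, 5] <- 1.2
  enh <- tfce_enhance(z, E = 0, H = 6, dh = 0.05)
  vals <- c(enh[1, 1, 1], enh[3, 3, 3], enh[5, 5, 5])
  expect_equal(order(vals), order(c(2.1, 3.4, 1.2)))
})

test_that("connected components respect the chosen connectivity", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1:2, 1] <- TRUE             # 4-voxel block
  m[5:6, 5:6, 6] <- TRUE             # far block
  lab <- label_clusters(m)
  expect_equal(sort(attr(lab, "sizes")), c(4L, 4L))
  # diagonal touch: one cluster at 26-connectivity, two at 6
  d <- array(FALSE, c(4, 4, 4))
  d[1, 1, 1] <- TRUE
  d[2, 2, 2] <- TRUE
  expect_length(attr(label_clusters(d, 26), "sizes"), 1L)
  expect_length(attr(label_clusters(d, 6), "sizes"), 2L)
})

test_that("identity permutation reproduces the observed max statistic", {
  set.seed(3)
  n <- 16
  maps <- array(rnorm(8^3 * n), c(8, 8, 8, n))
  outc <- rnorm(n)
  res <- suppressWarnings(permutation_fwe(maps, outc, n_perm = 60,
                                          method = "maxT", seed = 4))
  expect_equal(res$null_max[1], max(abs(res$tmap)))
  res2 <- suppressWarnings(permutation_fwe(maps, outc, n_perm = 60,
                                           method = "maxT", seed = 4))
  expect_identical(res$pmap_fwe, res2$pmap_fwe)
  expect_warning(permutation_fwe(maps, outc, n_perm = 50, seed = 1),
                 "n_perm")
  expect_error(permutation_fwe(maps, outc, n_perm = 100, method = "bogus"),
               "arg")
})

test_that("an embedded strong cluster is detected by all three corrections", {
  set.seed(6)
  n <- 30
  outc <- rnorm(n)
  sim <- generate_stat_maps(
    c(12, 12, 12),
    list(list(center = c(6, 6, 6), radius = 2.5, amplitude = 1.6)),
    outc, noise_sd = 1, seed = 7)
  for (m in c("maxT", "tfce", "cluster")) {
    res <- permutation_fwe(sim$maps, outc, n_perm = 100, method = m,
                           seed = 8)
    expect_gt(sum(res$mask & sim$truth) / sum(sim$truth), 0.5)
    expect_lt(mean(res$mask & !sim$truth), 0.01)
  }
})

test_that("cluster thresholding labels disjoint suprathreshold regions", {
  set.seed(9)
  n <- 30
  outc <- rnorm(n)
  sim <- generate_stat_maps(
    c(14, 14, 14),
    list(list(center = c(4, 4, 4), radius = 2, amplitude = 1.8),
         list(center = c(11, 11, 11), radius = 2, amplitude = 1.8)),
    outc, noise_sd = 1, seed = 10)
  res <- cluster_threshold(sim$maps, outc, n_perm = 100, seed = 11)
  expect_gte(nrow(res$clusters), 2L)
  sig <- res$clusters$p_fwe <= 0.05
  expect_gte(sum(sig), 2L)
  # no voxel passes the height threshold -> empty mask
  null_maps <- array(rnorm(6^3 * n, sd = 1e-3), c(6, 6, 6, n))
  res0 <- cluster_threshold(null_maps, outc, height_p = 1e-6, n_perm = 100,
                            seed = 12)
  expect_false(any(res0$mask))
})

test_that("ROI means extract per-subject averages over masks", {
  maps <- array(2.5, c(3, 3, 3, 4))
  maps[1, 1, 1, ] <- c(1, 2, 3, 4)
  m_all <- array(TRUE, c(3, 3, 3))
  m_one <- array(FALSE, c(3, 3, 3))
  m_one[1, 1, 1] <- TRUE
  out <- extract_roi_means(maps, list(all = m_all, vox = m_one))
  expect_equal(out$vox, c(1, 2, 3, 4))
  expect_equal(out$all, (2.5 * 26 + c(1, 2, 3, 4)) / 27)
  expect_warning(e <- extract_roi_means(maps, array(FALSE, c(3, 3, 3))),
                 "empty")
  expect_true(all(is.nan(e$roi)))
})

test_that("fisher transform is atanh", {
  expect_equal(fisher_r_to_z(c(-0.5, 0, 0.5)), atanh(c(-0.5, 0, 0.5)))
})
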