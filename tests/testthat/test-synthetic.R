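test_that("default cohort reproduces the published group structure", {
  co <- generate_cohort(seed = 3)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 151L)
  expect_equal(as.vector(table(co$group)[c("HC", "aMCI", "AD")]),
               c(51L, 54L, 46L))
  expect_true(all(co$severity[co$group == "HC"] == 0))
  expect_true(all(co$severity[co$group == "aMCI"] < 4))
  expect_true(all(co$severity[co$group == "AD"] >= 4))
  expect_false(anyDuplicated(co$id) > 0)
  expect_identical(co, generate_cohort(seed = 3))
})

test_that("severity draws respect diagnostic bounds and CDR-SB granularity", {
  specs <- default_group_specs()
  amci <- sample_severity(specs[[2]], n = 1e4, seed = 11)
  ad <- sample_severity(specs[[3]], n = 1e4, seed = 13)
  expect_true(max(amci) < 4)
  expect_true(min(ad) >= 4)
  expect_true(max(ad) <= 18)
  expect_true(all(amci * 2 == round(amci * 2)))  # 0.5 steps
  expect_true(all(ad * 2 == round(ad * 2)))
})

test_that("group severity means match the exact generator mean at 10x n", {
  for (sp in default_group_specs()[2:3]) {
    x <- sample_severity(sp, n = 10L * sp$n, seed = 5)
    mu <- severity_generator_mean(sp)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 2 * se + 1e-12)
  }
})

test_that("generating trajectories encode the published peak effects", {
  scen <- paper_trajectory_scenario()
  expect_length(scen, 10L)
  tg <- seq(0, 18, by = 0.1)
  fw <- eval_trajectory(scen$FW, tg)
  expect_equal(min(fw), -0.9)
  expect_lt(tg[which.min(fw)], 4)             # early aMCI trough
  expect_equal(max(eval_trajectory(scen$FA_T_fornix, tg)), 4.5)
  expect_equal(max(eval_trajectory(scen$GMV_mPFC, tg)), 4.5)
  expect_equal(max(eval_trajectory(scen$GMV_PCC, tg)), 1.4)
  hip <- eval_trajectory(scen$GMV_HIP, tg)
  expect_equal(max(hip), 2.4)
  expect_true(tg[which.max(hip)] >= 4 && tg[which.max(hip)] <= 5)
  for (nm in c("age", "gender", "handedness", "ethnicity")) {
    expect_true(all(eval_trajectory(scen[[nm]], tg) == 0))
  }
  expect_true(all(eval_trajectory(scen$FC_DMN, tg) ==
                    eval_trajectory(scen$FC_DMN, 0)))
})

test_that("trajectory specs validate their control points", {
  expect_error(trajectory_spec("x", cbind(c(1, 1), c(0, 1))), "increasing")
  expect_error(trajectory_spec("x", cbind(c(-1, 2), c(0, 1))), "\\[0, 18\\]")
  const <- trajectory_spec("x", cbind(3, 2))
  expect_equal(eval_trajectory(const, c(0, 9, 18)), rep(2, 3))
})

test_that("predictor generation is deterministic and severity-linked", {
  co <- generate_cohort(default_group_specs(1000), seed = 2)
  p0 <- generate_predictors(co, noise_sd = 0, seed = 4)
  expect_identical(p0, generate_predictors(co, noise_sd = 0, seed = 99))
  p1 <- generate_predictors(co, seed = 4)
  expect_identical(p1, generate_predictors(co, seed = 4))
  expect_gt(cor(p1$FW, co$severity), 0)
  expect_lt(cor(p1$GMV_HIP, co$severity), 0)
  expect_error(generate_predictors(co, noise_sd = -1), "noise_sd")
})

test_that("memory generation follows the varying-coefficient model", {
  co <- generate_cohort(seed = 1)
  pred <- generate_predictors(co, seed = 2)
  # null scenario: all trajectories zero, no noise -> y identically 0
  null_scen <- lapply(paper_trajectory_scenario(), function(s)
    trajectory_spec(s$predictor_name, cbind(0, 0)))
  y0 <- generate_memory(co, pred, null_scen, eps_sd = 0)
  expect_equal(y0, rep(0, nrow(co)))
  # constant beta = 2 on a single already-standardized predictor
  x <- rep(c(-1, 1), length.out = nrow(co))
  one <- data.frame(FW = x)
  scen1 <- list(FW = trajectory_spec("FW", cbind(0, 2)))
  y2 <- generate_memory(co, one, scen1, eps_sd = 0)
  expect_equal(y2, 2 * as.vector(scale(x)), tolerance = 1e-12)
  expect_error(generate_memory(co[1:10, ], pred), "different numbers")
})

test_that("outcome variance matches an independent Monte-Carlo oracle", {
  v1 <- var(simulate_svc_dataset(5000, seed = 21)$memory_z)
  v2 <- var(simulate_svc_dataset(5000, seed = 99)$memory_z)
  expect_lt(abs(v1 - v2) / v2, 0.05)
})

test_that("regressing y on the known generating signal recovers slope 1", {
  dat <- simulate_svc_dataset(1000, seed = 6)
  Xs <- standardize_predictors(dat$obs$X)$x
  signal <- rowSums(sapply(colnames(Xs), function(nm) {
    eval_trajectory(dat$scenario[[nm]], dat$obs$t) * Xs[, nm]
  }))
  fit <- lm(dat$memory_z ~ signal)
  est <- summary(fit)$coefficients["signal", ]
  expect_lt(abs(est["Estimate"] - 1), 2 * est["Std. Error"])
})

test_that("simulated diffusion voxels follow the bi-tensor forward model", {
  gt <- default_gradient_table()
  expect_length(gt$bvals, 68L)          # 61 DW + 7 b0
  expect_equal(sum(gt$b0), 7L)
  s <- generate_dwi_voxel(1, diag(3) * 1e-3, gt, S0 = 500)
  expect_equal(unique(round(s[!gt$b0] / 500, 10)),
               round(exp(-1150 * 3e-3), 10))
  d <- 1.2e-3
  s0 <- generate_dwi_voxel(0, diag(3) * d, gt, S0 = 200)
  expect_equal(s0[!gt$b0] / 200, rep(exp(-1150 * d), 61), tolerance = 1e-12)
  expect_error(generate_dwi_voxel(1.2, diag(3) * 1e-3, gt), "\\[0, 1\\]")
  expect_identical(generate_dwi_voxel(0.4, diag(3) * 1e-3, gt,
                                      noise_sd = 5, seed = 8),
                   generate_dwi_voxel(0.4, diag(3) * 1e-3, gt,
                                      noise_sd = 5, seed = 8))
})

test_that("stat-map stacks embed outcome-locked effects where stated", {
  set.seed(2)
  outc <- rnorm(15)
  null_sim <- generate_stat_maps(c(8, 8, 8), list(), outc, seed = 1)
  expect_false(any(null_sim$truth))
  sim <- generate_stat_maps(
    c(10, 10, 10),
    list(list(center = c(5, 5, 5), radius = 2.5, amplitude = 2)),
    outc, noise_sd = 1e-8, seed = 1)
  tmap <- massunivariate_glm(sim$maps, outc)
  expect_equal(abs(tmap) > 100, sim$truth)
  expect_error(generate_stat_maps(c(-4, 8, 8), list(), outc), "positive")
  expect_error(generate_stat_maps(
    c(8, 8, 8), list(list(center = c(20, 4, 4), radius = 1, amplitude = 1)),
    outc), "outside")
})

test_that("subject tables round-trip through TSV", {
  co <- generate_cohort(seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_subject_table(co, f)
  back <- read_subject_table(f)
  expect_equal(back$severity, co$severity)
  expect_equal(back$group, co$group)
})
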