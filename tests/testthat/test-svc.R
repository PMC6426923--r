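test_that("standardization gives exact zero mean / unit variance and round-trips", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  st <- standardize_predictors(X)
  expect_lt(max(abs(colMeans(st$x))), 1e-12)
  expect_lt(max(abs(apply(st$x, 2, var) - 1)), 1e-12)
  # idempotence
  st2 <- standardize_predictors(st$x)
  expect_equal(st2$x, st$x, tolerance = 1e-12)
  # back-transform reproduces raw-scale values
  back <- sweep(sweep(st$x, 2, st$scale, "*"), 2, st$center, "+")
  expect_equal(back, X, tolerance = 1e-12)
  X[, 2] <- 3
  expect_error(standardize_predictors(X), "v2")
  expect_equal(unname(standardize_predictors(X, allow_constant = TRUE)$x[, 2]),
               rep(0, 50))
})

test_that("design expansion realizes the varying-coefficient regression", {
  obs <- make_obs(n = 40, p = 3, seed = 2)
  obs <- standardize_predictors(obs)
  basis <- bspline_basis(obs$t, L = 4)
  Z <- expand_design(obs, basis)
  expect_equal(dim(Z), c(40L, 12L))
  set.seed(3)
  gamma <- matrix(rnorm(12), 3, 4, byrow = FALSE)
  direct <- rowSums(sapply(1:3, function(j) {
    (eval_basis(basis, obs$t) %*% gamma[j, ]) * obs$X[, j]
  }))
  expect_equal(as.vector(Z %*% as.vector(t(gamma))), direct,
               tolerance = 1e-12)
  # unit predictor: rows are the basis evaluations (sum to 1)
  one <- observation_set(rnorm(10), seq(0, 9), matrix(1, 10, 1))
  Z1 <- expand_design(one, bspline_basis(one$t, L = 4))
  expect_equal(rowSums(Z1), rep(1, 10), tolerance = 1e-12)
  # zero predictor column -> L zero columns
  zo <- observation_set(rnorm(10), seq(0, 9), cbind(rnorm(10), 0))
  Zz <- expand_design(zo, bspline_basis(zo$t, L = 4))
  expect_true(all(Zz[, 5:8] == 0))
})

test_that("full-shrinkage bound and unpenalized limit hold", {
  obs <- standardize_predictors(make_obs(n = 50, p = 3, seed = 4,
                                         beta_fun = function(j, t) j))
  basis <- bspline_basis(obs$t, L = 4)
  gram <- penalty_gram(basis)
  Z <- expand_design(obs, basis)
  yc <- obs$y - mean(obs$y)
  Zt <- adcontinuum:::.transform_design(Z, gram$R, 3, 4)
  lmax <- lambda_max_bound(Zt, yc, 3, 4)
  fit <- fit_group_lasso(Z, yc, gram, lmax * 1.0001)
  expect_true(all(fit$gamma == 0))
  fit_just_below <- fit_group_lasso(Z, yc, gram, lmax * 0.99)
  expect_gt(sum(fit_just_below$gamma^2), 0)
  # lambda = 0 with p*L < n reproduces least squares
  ls <- fit_group_lasso(Z, yc, gram, 0)
  expect_equal(as.vector(t(ls$gamma[, , 1])),
               unname(lm.fit(Z, yc)$coefficients), tolerance = 1e-6)
})

test_that("solver matches a brute-force grid-search oracle on a toy problem", {
  set.seed(5)
  n <- 30
  p <- 2
  L <- 2
  t <- runif(n, 0, 10)
  X <- scale(matrix(rnorm(n * p), n, p))
  obs <- observation_set(X[, 1] * 0.8 + rnorm(n, 0, 0.3), t, X)
  basis <- bspline_basis(t, L = L, degree = 1L)
  gram <- penalty_gram(basis)
  Z <- expand_design(obs, basis)
  yc <- obs$y - mean(obs$y)
  Zt <- adcontinuum:::.transform_design(Z, gram$R, p, L)
  for (lam in c(0.02, 0.1)) {
    fit <- fit_group_lasso(Z, yc, gram, lam, control = list(tol = 1e-10))
    oracle <- gl_grid_search(Zt, yc, lam, p, L)
    expect_lte(fit$objective[1], oracle$value + 1e-4)
    expect_lt(abs(fit$objective[1] - oracle$value), 1e-4)
  }
})

test_that("objective decreases monotonically across BCD sweeps", {
  obs <- standardize_predictors(make_obs(n = 60, p = 4, seed = 6,
                                         beta_fun = function(j, t) j / 2))
  basis <- bspline_basis(obs$t, L = 4)
  gram <- penalty_gram(basis)
  Z <- expand_design(obs, basis)
  yc <- obs$y - mean(obs$y)
  fit <- fit_group_lasso(Z, yc, gram, c(0.3, 0.1, 0.02),
                         control = list(trace_objective = TRUE))
  for (tr in fit$objective_trace) {
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("KKT conditions certify the returned solutions", {
  set.seed(7)
  for (i in 1:10) {
    n <- 40 + i
    p <- sample(2:5, 1)
    obs <- standardize_predictors(
      make_obs(n = n, p = p, seed = 100 + i,
               beta_fun = function(j, t) (j %% 2) * sin(t / 3)))
    basis <- bspline_basis(obs$t, L = 4)
    gram <- penalty_gram(basis)
    Z <- expand_design(obs, basis)
    yc <- obs$y - mean(obs$y)
    Zt <- adcontinuum:::.transform_design(Z, gram$R, p, 4)
    lmax <- lambda_max_bound(Zt, yc, p, 4)
    fit <- fit_group_lasso(Z, yc, gram, lmax * c(0.5, 0.1, 0.02),
                           control = list(tol = 1e-9))
    expect_lt(max(fit$kkt_residual), 1e-6)
  }
})

test_that("penalty equals lambda times the root-integrated squared trajectory", {
  obs <- standardize_predictors(make_obs(n = 50, p = 3, seed = 8,
                                         beta_fun = function(j, t) j - 2))
  basis <- bspline_basis(obs$t, L = 4)
  gram <- penalty_gram(basis)
  Z <- expand_design(obs, basis)
  yc <- obs$y - mean(obs$y)
  lam <- 0.05
  fit <- fit_group_lasso(Z, yc, gram, lam, control = list(tol = 1e-10))
  gamma <- fit$gamma[, , 1]
  pen_solver <- lam * sum(sqrt(sapply(1:3, function(j) {
    sum((gram$R %*% gamma[j, ])^2)
  })))
  pen_quad <- lam * sum(sqrt(sapply(1:3, function(j) {
    integrate(function(t) as.vector((eval_basis(basis, t) %*% gamma[j, ])^2),
              basis$domain[1], basis$domain[2], rel.tol = 1e-12)$value
  })))
  expect_lt(abs(pen_solver - pen_quad), 1e-8)
})

test_that("cross-validation is seeded, tie-broken sparse, and validates folds", {
  obs <- standardize_predictors(
    make_obs(n = 60, p = 3, seed = 9,
             beta_fun = function(j, t) if (j == 1) 2 else 0))
  basis <- bspline_basis(obs$t, L = 4)
  gram <- penalty_gram(basis)
  Z <- expand_design(obs, basis)
  cv1 <- cross_validate_lambda(Z, obs$y, gram, 3, 4, seed = 11)
  cv2 <- cross_validate_lambda(Z, obs$y, gram, 3, 4, seed = 11)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_error(cross_validate_lambda(Z[1:8, ], obs$y[1:8], gram, 3, 4),
               "fewer than 2")
})

test_that("a strong single predictor is selected; permuted order is irrelevant", {
  dat <- simulate_svc_dataset(151, seed = 10)
  fit <- fit_svc(dat$obs, svc_config(seed = 2))
  expect_true(fit$selected[["FA_T_fornix"]])
  expect_lt(fit$kkt_residual, 1e-6)
  # reorder predictors: per-name trajectories unchanged
  perm <- c(4, 1, 7, 10, 2, 3, 9, 5, 8, 6)
  obs_p <- observation_set(dat$obs$y, dat$obs$t, dat$obs$X[, perm])
  fit_p <- fit_svc(obs_p, svc_config(seed = 2))
  tr <- evaluate_trajectories(fit)
  tr_p <- evaluate_trajectories(fit_p)
  expect_equal(tr_p[, colnames(tr)], tr, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("pure-noise outcomes stay sparse and are never consistently selected", {
  # CV-min LASSO does select noise predictors in individual fits; what must
  # hold is that lambda* stays in the sparse part of the grid, the model
  # stays far from saturated, and no predictor survives across seeds
  sel <- matrix(FALSE, 12, 5)
  lam_ratio <- numeric(12)
  for (i in 1:12) {
    obs <- make_obs(n = 60, p = 5, seed = 300 + i, eps_sd = 1)
    fit <- fit_svc(obs, svc_config(seed = i))
    sel[i, ] <- fit$selected
    lam_ratio[i] <- fit$lambda / max(fit$cv$lambda)
  }
  expect_gt(median(lam_ratio), 0.03)      # grid spans down to 1e-3
  expect_lt(mean(rowSums(sel)), 4)        # of 5 predictors
  expect_true(all(colMeans(sel) < 0.9))   # nothing survives consistently
})

test_that("stability bands summarize replicate trajectories coherently", {
  dat <- simulate_svc_dataset(151, seed = 12)
  bands <- stability_replicates(dat$obs, svc_config(), n_rep = 8, seed = 13)
  expect_equal(bands$n_rep, 8L)
  expect_true(all(bands$selection_count >= 0 & bands$selection_count <= 8))
  expect_equal(dim(bands$mean), c(length(bands$t_grid), 10L))
  # replicate mean equals the mean of stored trajectories by construction
  expect_equal(bands$mean[, "FW"],
               rowMeans(bands$trajectories[, 1, ]), tolerance = 1e-12)
  # strong generating signals are selected in every replicate
  expect_equal(unname(bands$selection_count[["FA_T_fornix"]]), 8L)
  expect_identical(bands$stable,
                   stability_replicates(dat$obs, svc_config(), n_rep = 8,
                                        seed = 13)$stable)
})

test_that("bootstrap standard errors shrink roughly as 1/sqrt(n)", {
  b_small <- stability_replicates(simulate_svc_dataset(151, seed = 14)$obs,
                                  svc_config(), n_rep = 8, seed = 15)
  b_big <- stability_replicates(simulate_svc_dataset(604, seed = 14)$obs,
                                svc_config(), n_rep = 8, seed = 15)
  mid <- b_small$t_grid <= 8   # compare over well-supported severities
  ratio <- median(b_small$se[mid, 1:6]) / median(b_big$se[mid, 1:6])
  expect_gt(ratio, 1.2)        # expect about 2, allow wide Monte-Carlo slack
  expect_lt(ratio, 3.5)
})
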