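`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observation set for varying-coefficient modelling
#'
#' Bundles the outcome, the severity index and the predictor matrix.  The
#' design is cross-sectional: one severity value per subject (the model's
#' double sum over subjects and visits collapses to K = 1), but repeated
#' severities across subjects are expected — CDR-SB lives on a 0.5 grid.
#'
#' @param y memory z-scores.
#' @param t severities (CDR-SB units), one per subject.
#' @param X numeric matrix, subjects x predictors.
#' @param predictor_names optional column names for `X`.
#' @return list of class `observation_set` with `y`, `t`, `X`,
#'   `predictor_names`, `n`, `p`, `standardized` flag.
#' @export
observation_set <- function(y, t, X, predictor_names = colnames(X)) {
  X <- as.matrix(X)
  if (length(y) != nrow(X) || length(t) != nrow(X)) {
    stop("y, t and X disagree on the number of subjects")
  }
  if (!all(is.finite(y)) || !all(is.finite(t)) || !all(is.finite(X))) {
    stop("observation set contains non-finite values")
  }
  if (is.null(predictor_names)) predictor_names <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- predictor_names
  structure(list(y = as.numeric(y), t = as.numeric(t), X = X,
                 predictor_names = predictor_names,
                 n = nrow(X), p = ncol(X), standardized = FALSE),
            class = "observation_set")
}

#' Standardize predictor columns
#'
#' Centres every column to mean zero and scales to unit (sample) variance,
#' recording the transform so fitted coefficient functions can be mapped
#' back to the raw predictor scale.
#'
#' @param X numeric matrix (or `observation_set`).
#' @param allow_constant if `TRUE`, a zero-variance column is centred to
#'   all-zeros (scale recorded as 1) instead of erroring — used by the
#'   resampling loops, where a bootstrap draw can make a rare binary
#'   covariate constant; such a column can never be selected.
#' @return for a matrix: list with `x`, `center`, `scale`; for an
#'   observation set: the set with `X` standardized and the record attached.
#' @export
standardize_predictors <- function(X, allow_constant = FALSE) {
  if (inherits(X, "observation_set")) {
    rec <- standardize_predictors(X$X, allow_constant)
    X$X <- rec$x
    X$standardized <- TRUE
    X$scaling <- rec[c("center", "scale")]
    return(X)
  }
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- scl < 1e-12
  if (any(zero)) {
    if (!allow_constant) {
      stop("zero-variance predictor column(s): ",
           paste(colnames(X)[zero], collapse = ", "))
    }
    scl[zero] <- 1
  }
  x <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(x = x, center = ctr, scale = scl)
}

#' Basis-expanded design matrix
#'
#' Column (j, l) holds \eqn{x_{ij} B_l(t_i)}: the regression of y on this
#' design with coefficients \eqn{\gamma_{jl}} reproduces
#' \eqn{\sum_j \beta_j(t_i) x_{ij}} with
#' \eqn{\beta_j = \sum_l \gamma_{jl} B_l}.  Columns are ordered predictor-
#' major: all L basis columns of predictor 1, then predictor 2, ...
#'
#' @param obs an [observation_set()] (standardized for model fitting).
#' @param basis a [bspline_basis()].
#' @return n x (p*L) matrix with names `<predictor>.B<l>`.
#' @export
expand_design <- function(obs, basis) {
  stopifnot(inherits(obs, "observation_set"))
  B <- eval_basis(basis, obs$t)
  L <- basis$L
  Z <- matrix(0, obs$n, obs$p * L)
  cn <- character(obs$p * L)
  for (j in seq_len(obs$p)) {
    cols <- (j - 1L) * L + seq_len(L)
    Z[, cols] <- obs$X[, j] * B
    cn[cols] <- paste0(obs$predictor_names[j], ".B", seq_len(L))
  }
  colnames(Z) <- cn
  Z
}

# Apply the change of variables gamma_tilde = R gamma blockwise:
# Ztilde_j = Z_j %*% solve(R), so the block penalty becomes ||gamma_tilde_j||.
.transform_design <- function(Z, R, p, L) {
  Rinv <- backsolve(R, diag(L))
  Zt <- Z
  for (j in seq_len(p)) {
    cols <- (j - 1L) * L + seq_len(L)
    Zt[, cols] <- Z[, cols, drop = FALSE] %*% Rinv
  }
  Zt
}

#' Smallest penalty that zeroes every block
#'
#' \eqn{\lambda_{max} = \max_j \| \tilde Z_j^\top y / n \|}: at or above this
#' value the group-LASSO solution is identically zero.
#'
#' @param Zt transformed design (see [fit_group_lasso()]).
#' @param y centred outcome.
#' @param p,L block structure.
#' @return numeric.
#' @export
lambda_max_bound <- function(Zt, y, p, L) {
  n <- length(y)
  m <- 0
  for (j in seq_len(p)) {
    cols <- (j - 1L) * L + seq_len(L)
    m <- max(m, sqrt(sum((crossprod(Zt[, cols, drop = FALSE], y) / n)^2)))
  }
  m
}

#' Functional group-LASSO solver
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\|y - Z\gamma\|^2 +
#'       \lambda \sum_j \sqrt{\gamma_j^\top \Omega \gamma_j}}
#' by exact block coordinate descent after the change of variables
#' \eqn{\tilde\gamma_j = R\gamma_j} (\eqn{\Omega = R^\top R}), which turns
#' each block penalty into a Euclidean norm.  Whole blocks are set exactly
#' to zero when the block KKT bound \eqn{\|\tilde Z_j^\top r / n\| \le
#' \lambda} holds.
#'
#' @param design n x (p*L) basis-expanded matrix (see [expand_design()]).
#' @param y centred outcome vector.
#' @param gram a [penalty_gram()] shared by all blocks.
#' @param lambda penalty value(s); a decreasing vector is solved as a
#'   warm-started path.
#' @param p,L block structure (defaults inferred from `gram` and `design`).
#' @param control list: `tol` (max block coefficient change, default 1e-7),
#'   `maxit` (sweeps, default 1e4), `trace_objective` (return the per-sweep
#'   objective values).
#' @return list of class `group_lasso_path`: `gamma` (array p x L x
#'   n_lambda, original parameterization), `gamma_tilde`, `lambda`,
#'   `sweeps`, `objective`, `kkt_residual` per lambda, and traces if asked.
#' @export
fit_group_lasso <- function(design, y, gram, lambda, p = NULL,
                            L = NULL, control = list()) {
  ctl <- modifyList(list(tol = 1e-7, maxit = 10000L, trace_objective = FALSE,
                         diagnostics = TRUE),
                    control)
  if (is.null(L)) L <- ncol(gram$omega)
  if (is.null(p)) p <- ncol(design) / L
  if (p != round(p)) stop("design columns are not a multiple of L")
  p <- as.integer(p)
  if (!all(is.finite(design))) stop("design contains non-finite values")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  ev <- eigen(gram$omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("penalty Gram matrix is not positive definite")
  lambda <- as.numeric(lambda)
  Zt <- .transform_design(design, gram$R, p, L)
  res <- .gl_path_cpp(Zt, y, p, L, lambda, ctl$tol, as.integer(ctl$maxit),
                      isTRUE(ctl$trace_objective))
  n_lam <- length(lambda)
  gt <- array(res$gamma, c(L, p, n_lam))
  Rinv <- backsolve(gram$R, diag(L))
  gamma <- array(0, c(p, L, n_lam))
  gamma_tilde <- array(0, c(p, L, n_lam))
  obj <- numeric(n_lam)
  kkt <- numeric(n_lam)
  n <- length(y)
  for (k in seq_len(n_lam)) {
    gtk <- gt[, , k, drop = FALSE][, , 1]           # L x p
    if (p == 1L) gtk <- matrix(gtk, ncol = 1L)
    gamma_tilde[, , k] <- t(gtk)
    gamma[, , k] <- t(Rinv %*% gtk)
    if (isTRUE(ctl$diagnostics)) {
      r <- y - Zt %*% as.vector(gtk)
      obj[k] <- sum(r^2) / (2 * n) +
        lambda[k] * sum(sqrt(colSums(gtk^2)))
      kkt[k] <- .kkt_residual(Zt, y, gtk, lambda[k], p, L)
    }
  }
  warn <- res$sweeps >= ctl$maxit
  if (any(warn)) {
    warning("group-LASSO hit the sweep cap for ", sum(warn),
            " lambda value(s); returning best iterate")
  }
  dimnames(gamma) <- list(NULL, NULL, NULL)
  structure(list(gamma = gamma, gamma_tilde = gamma_tilde, lambda = lambda,
                 sweeps = res$sweeps, objective = obj, kkt_residual = kkt,
                 objective_trace = if (isTRUE(ctl$trace_objective))
                   res$objective_trace else NULL,
                 p = p, L = L, converged = !warn),
            class = "group_lasso_path")
}

# KKT residual of the transformed group LASSO at gamma_tilde (L x p).
.kkt_residual <- function(Zt, y, gtk, lambda, p, L) {
  n <- length(y)
  r <- y - Zt %*% as.vector(gtk)
  worst <- 0
  for (j in seq_len(p)) {
    cols <- (j - 1L) * L + seq_len(L)
    g <- as.vector(crossprod(Zt[, cols, drop = FALSE], r)) / n
    gj <- gtk[, j]
    nj <- sqrt(sum(gj^2))
    v <- if (nj < 1e-300) max(0, sqrt(sum(g^2)) - lambda)
         else sqrt(sum((g - lambda * gj / nj)^2))
    worst <- max(worst, v)
  }
  worst
}

#' Default log-spaced penalty grid
#'
#' @param lambda_max upper end (full-shrinkage bound).
#' @param nlambda grid size.
#' @param min_ratio smallest lambda as a fraction of `lambda_max`.
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(lambda_max, nlambda = 50L, min_ratio = 1e-3) {
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = nlambda))
}

#' Five-fold cross-validation for the penalty weight
#'
#' Subjects are partitioned into folds at random; for each fold the
#' warm-started penalty path is fit on the training part and scored by
#' held-out mean squared error.  Ties in CV error resolve to the larger
#' (sparser) lambda.
#'
#' @param design,y,gram,p,L as in [fit_group_lasso()].
#' @param lambda_grid decreasing penalty grid (default built from the data).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param control solver control list.
#' @return list: `lambda_min`, `cv_curve` (data.frame lambda / cv_error /
#'   cv_se), `folds`.
#' @export
cross_validate_lambda <- function(design, y, gram, p = NULL, L = NULL,
                                  lambda_grid = NULL, n_folds = 5L,
                                  seed = 1L, control = list()) {
  if (is.null(L)) L <- ncol(gram$omega)
  if (is.null(p)) p <- as.integer(ncol(design) / L)
  n <- length(y)
  n_folds <- as.integer(n_folds)
  if (n < 2L * n_folds) stop("a fold would contain fewer than 2 subjects")
  set.seed(as.integer(seed))
  folds <- sample(rep_len(seq_len(n_folds), n))
  if (is.null(lambda_grid)) {
    Zt <- .transform_design(design, gram$R, p, L)
    lam_max <- lambda_max_bound(Zt, y - mean(y), p, L)
    lambda_grid <- lambda_grid(max(lam_max, 1e-8))
  }
  errs <- matrix(NA_real_, n_folds, length(lambda_grid))
  # held-out MSE is insensitive to the last digits of the coefficients: run
  # the fold paths at a looser tolerance than the final fit
  cv_control <- control
  cv_control$tol <- max(control$tol %||% 1e-7, 1e-5)
  cv_control$diagnostics <- FALSE
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    ybar <- mean(y[tr])
    fit <- suppressWarnings(
      fit_group_lasso(design[tr, , drop = FALSE], y[tr] - ybar, gram,
                      lambda_grid, p, L, cv_control))
    # gamma_tilde columns live in the transformed design's coordinates:
    # predict all lambdas in one multiply
    coefs <- vapply(seq_along(lambda_grid), function(k) {
      gam <- fit$gamma[, , k]
      if (p == 1L) gam <- matrix(gam, nrow = 1L)
      as.vector(t(gam))
    }, numeric(p * L))
    pred <- ybar + design[te, , drop = FALSE] %*% coefs
    errs[f, ] <- colMeans((y[te] - pred)^2)
  }
  cv <- colMeans(errs)
  cv_se <- apply(errs, 2, sd) / sqrt(n_folds)
  best <- which(cv <= min(cv) + 1e-12)[1]  # grid is decreasing: first = sparser
  list(lambda_min = lambda_grid[best],
       cv_curve = data.frame(lambda = lambda_grid, cv_error = cv,
                             cv_se = cv_se),
       folds = folds)
}

#' Default SVC configuration
#'
#' @param L,degree basis size and degree (4 cubic = the published setup).
#' @param n_folds CV folds.
#' @param nlambda,lambda_min_ratio penalty grid shape.
#' @param tol,maxit solver control.
#' @param seed integer seed (CV folds).
#' @param domain optional fixed basis domain; default is the observed
#'   severity range.
#' @param t_grid_step evaluation grid step for trajectories.
#' @param low_support_above severities above this are flagged low-support.
#' @param allow_constant tolerate zero-variance predictor columns by
#'   treating them as all-zero (see [standardize_predictors()]); enabled
#'   automatically inside resampling loops.
#' @return list of class `svc_config`.
#' @export
svc_config <- function(L = 4L, degree = 3L, n_folds = 5L, nlambda = 50L,
                       lambda_min_ratio = 1e-3, tol = 1e-7, maxit = 10000L,
                       seed = 1L, domain = NULL, t_grid_step = 0.1,
                       low_support_above = 10, allow_constant = FALSE) {
  structure(list(L = as.integer(L), degree = as.integer(degree),
                 n_folds = as.integer(n_folds), nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 maxit = as.integer(maxit), seed = as.integer(seed),
                 domain = domain, t_grid_step = t_grid_step,
                 low_support_above = low_support_above,
                 allow_constant = isTRUE(allow_constant)),
            class = "svc_config")
}

#' Fit the sparse varying coefficient model
#'
#' Full pipeline for one dataset: standardize predictors, centre the
#' outcome, build the B-spline basis over the severity range, expand the
#' design, choose lambda by cross-validation, and refit on all data.  The
#' selected set is every predictor whose coefficient block is nonzero at the
#' chosen lambda.
#'
#' @param obs an [observation_set()].
#' @param config an [svc_config()].
#' @return object of class `svc_fit`: `gamma` (p x L), `basis`, `gram`,
#'   `lambda`, `cv`, `selected` (logical per predictor), `residuals`,
#'   `objective`, `kkt_residual`, `y_center`, `scaling`, `predictor_names`.
#' @export
fit_svc <- function(obs, config = svc_config()) {
  stopifnot(inherits(obs, "observation_set"))
  if (!obs$standardized) {
    obs <- standardize_predictors(obs, isTRUE(config$allow_constant))
  }
  basis <- bspline_basis(obs$t, L = config$L, degree = config$degree,
                         domain = config$domain)
  gram <- penalty_gram(basis)
  Z <- expand_design(obs, basis)
  y_center <- mean(obs$y)
  yc <- obs$y - y_center
  ctl <- list(tol = config$tol, maxit = config$maxit)
  Zt <- .transform_design(Z, gram$R, obs$p, basis$L)
  lam_max <- lambda_max_bound(Zt, yc, obs$p, basis$L)
  grid <- lambda_grid(max(lam_max, 1e-8), config$nlambda,
                      config$lambda_min_ratio)
  cv <- cross_validate_lambda(Z, obs$y, gram, obs$p, basis$L,
                              lambda_grid = grid, n_folds = config$n_folds,
                              seed = config$seed, control = ctl)
  # warm-started path down to lambda*; keep the last solution
  path_lams <- grid[grid >= cv$lambda_min - 1e-15]
  fit <- fit_group_lasso(Z, yc, gram, path_lams, obs$p, basis$L, ctl)
  k <- length(path_lams)
  gamma <- fit$gamma[, , k]
  if (obs$p == 1L) gamma <- matrix(gamma, nrow = 1L)
  rownames(gamma) <- obs$predictor_names
  selected <- rowSums(gamma^2) > 0
  fitted <- y_center + Z %*% as.vector(t(gamma))
  structure(list(gamma = gamma, basis = basis, gram = gram,
                 lambda = cv$lambda_min, cv = cv$cv_curve,
                 selected = selected, residuals = obs$y - as.vector(fitted),
                 fitted = as.vector(fitted),
                 objective = fit$objective[k],
                 kkt_residual = fit$kkt_residual[k],
                 y_center = y_center, scaling = obs$scaling,
                 predictor_names = obs$predictor_names,
                 n = obs$n, p = obs$p, config = config),
            class = "svc_fit")
}

#' @export
print.svc_fit <- function(x, ...) {
  cat("Sparse varying coefficient fit\n")
  cat("  subjects:", x$n, " predictors:", x$p,
      " basis L:", x$basis$L, "\n")
  cat("  lambda (5-fold CV):", format(x$lambda, digits = 4), "\n")
  cat("  selected:", if (any(x$selected))
    paste(x$predictor_names[x$selected], collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Evaluate fitted coefficient trajectories
#'
#' \eqn{\hat\beta_j(t) = \sum_l \gamma_{jl} B_l(t)} on a severity grid, plus
#' a signed-extremum (peak) table per predictor.
#'
#' @param fit an [fit_svc()] result (or any list with `gamma` and `basis`).
#' @param t_grid severities inside the basis domain; default a
#'   `config$t_grid_step` grid over the domain.
#' @return matrix grid x predictors with attributes `t_grid` and `peaks`
#'   (data.frame: predictor, peak_beta, peak_t).
#' @export
evaluate_trajectories <- function(fit, t_grid = NULL) {
  basis <- fit$basis
  if (is.null(t_grid)) {
    step <- if (!is.null(fit$config)) fit$config$t_grid_step else 0.1
    t_grid <- seq(basis$domain[1], basis$domain[2], by = step)
  }
  B <- eval_basis(basis, t_grid)
  beta <- B %*% t(fit$gamma)
  colnames(beta) <- rownames(fit$gamma)
  peaks <- data.frame(
    predictor = colnames(beta),
    peak_beta = apply(beta, 2, function(v) v[which.max(abs(v))]),
    peak_t = t_grid[apply(beta, 2, function(v) which.max(abs(v)))],
    row.names = NULL
  )
  attr(beta, "t_grid") <- t_grid
  attr(beta, "peaks") <- peaks
  beta
}
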