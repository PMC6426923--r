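#' Free-water compartment diffusivity (mm^2/s)
#'
#' Diffusion coefficient of free water at body temperature; the isotropic
#' compartment of the bi-tensor model is fixed at this value.
#' @export
D_FREE_WATER <- 3e-3

#' Diffusion gradient table
#'
#' @param bvals numeric b-values (s/mm^2), one per volume; values below
#'   `b0_threshold` are treated as b = 0 volumes.
#' @param bvecs matrix of gradient directions, either volumes x 3 or the
#'   FSL 3 x volumes layout; DW directions must have unit norm.
#' @param b0_threshold b-values at or below this count as b0.
#' @return list of class `gradient_table` with `bvals`, `bvecs`
#'   (volumes x 3), and logical `b0`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != length(bvals)) {
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") describe different numbers of volumes")
  }
  b0 <- bvals <= b0_threshold
  norms <- sqrt(rowSums(bvecs^2))
  if (any(abs(norms[!b0] - 1) > 1e-6)) {
    stop("diffusion-weighted directions must have unit norm (tol 1e-6)")
  }
  if (sum(!b0) > 0) {
    uniq <- unique(round(bvecs[!b0, , drop = FALSE], 6))
    if (nrow(uniq) < 6L) stop("need >= 6 unique DW directions for a tensor fit")
  }
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0),
            class = "gradient_table")
}

#' Read / write FSL-dialect bval and bvec files
#'
#' Plain whitespace-separated text: one row of b-values; three rows of
#' gradient components (3 x N).
#'
#' @param bval_path,bvec_path file paths.
#' @return a [gradient_table()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  gradient_table(bvals, bvecs)
}

#' @rdname read_bval_bvec
#' @param gtab a [gradient_table()].
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  cat(paste(gtab$bvals, collapse = " "), "\n", file = bval_path)
  write.table(format(t(gtab$bvecs), digits = 8), bvec_path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

check_tensor <- function(tensor, tol = 1e-8) {
  tensor <- as.matrix(tensor)
  if (!all(dim(tensor) == c(3L, 3L))) stop("tensor must be 3 x 3")
  if (max(abs(tensor - t(tensor))) > tol * max(1, max(abs(tensor)))) {
    stop("tensor must be symmetric")
  }
  tensor
}

#' Predict the bi-tensor diffusion signal
#'
#' Forward model of the two-compartment fit:
#' \eqn{S(g, b) = S_0 [ fw\, e^{-b d_{free}} + (1 - fw)\, e^{-b g^\top D g} ]}.
#'
#' @param fit list with elements `fw` and `tensor` (e.g. a [fit_bitensor()]
#'   result).
#' @param gradient_table a [gradient_table()].
#' @param S0 reference b = 0 signal (default taken from `fit$S0`, else 1).
#' @return numeric signal per volume.
#' @export
predict_signal <- function(fit, gradient_table, S0 = NULL) {
  if (is.null(S0)) S0 <- if (!is.null(fit$S0)) fit$S0 else 1
  D <- check_tensor(fit$tensor)
  g <- gradient_table$bvecs
  b <- gradient_table$bvals
  q <- rowSums((g %*% D) * g)          # g' D g per volume
  S0 * (fit$fw * exp(-b * D_FREE_WATER) + (1 - fit$fw) * exp(-b * q))
}

#' Fractional anisotropy of a tensor
#'
#' Standard eigenvalue formula
#' \eqn{FA = \sqrt{3/2}\;\|\lambda - \bar\lambda\| / \|\lambda\|}; the zero
#' tensor returns 0 by convention.
#'
#' @param tensor 3 x 3 symmetric matrix.
#' @return FA in \[0, 1\].
#' @export
fa_from_tensor <- function(tensor) {
  tensor <- check_tensor(tensor)
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  ss <- sum(ev^2)
  if (ss <= 0) return(0)
  fa <- sqrt(1.5 * sum((ev - mean(ev))^2) / ss)
  min(max(fa, 0), 1)
}

# Inner tensor fit at a fixed free-water fraction: subtract the free
# compartment, log-linearize, solve ordinary LS for the 6 tensor elements,
# then project to the PSD cone and the mean-diffusivity box.
.tissue_fit_at_fw <- function(fw, A, cfree, Xd, b_dw, opt) {
  At <- (A - fw * cfree) / (1 - fw)
  At <- pmin(pmax(At, 1e-4), 1)
  theta <- opt$qrX %*% (-log(At) / b_dw)
  D <- matrix(c(theta[1], theta[4], theta[5],
                theta[4], theta[2], theta[6],
                theta[5], theta[6], theta[3]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  md <- mean(ev)
  if (md < opt$md_bounds[1]) {
    ev <- if (md > 0) ev * opt$md_bounds[1] / md else rep(opt$md_bounds[1], 3)
  } else if (md > opt$md_bounds[2]) {
    ev <- ev * opt$md_bounds[2] / md
  }
  D <- e$vectors %*% (ev * t(e$vectors))
  D <- (D + t(D)) / 2
  q <- rowSums((opt$g_dw %*% D) * opt$g_dw)
  model <- fw * cfree + (1 - fw) * exp(-b_dw * q)
  rss <- sum((A - model)^2)
  pen <- opt$md_prior_weight * ((mean(ev) - opt$md_prior) * 1e3)^2
  list(D = D, rss = rss, objective = rss + pen)
}

#' Fit the two-compartment free-water model to one voxel
#'
#' Constrained nonlinear least squares for the bi-tensor model by variable
#' projection: the residual is profiled over the free-water fraction on a
#' grid (then refined by golden-section search), with an inner log-linear
#' tissue-tensor fit at each candidate fraction.  The tissue tensor is
#' projected to be positive semidefinite with mean diffusivity in
#' `md_bounds`; a tiny quadratic penalty toward `md_prior` breaks the
#' single-shell degeneracy on isotropic ridges (where fw is otherwise not
#' identifiable from one b-value).
#'
#' @param signal nonnegative signal per volume (same order as the table).
#' @param gradient_table a [gradient_table()].
#' @param options list overriding defaults: `fw_grid_step` (0.02),
#'   `md_bounds` (`c(0.1e-3, 2.0e-3)` mm^2/s), `md_prior` (`0.7e-3`),
#'   `md_prior_weight` (1e-5), `refine` (TRUE), `fw_range` (`c(0, 1)`;
#'   set `c(0, 0)` for a single-tensor fit with no free-water compartment).
#' @return list of class `bitensor_fit`: `fw`, `tensor`, `fa_t`, `S0`,
#'   `converged`, `residual_norm` (RSS square root in normalized signal
#'   units).
#' @export
fit_bitensor <- function(signal, gradient_table, options = list()) {
  opt <- modifyList(list(fw_grid_step = 0.02,
                         md_bounds = c(0.1e-3, 2.0e-3),
                         md_prior = 0.7e-3,
                         md_prior_weight = 1e-5,
                         refine = TRUE,
                         fw_range = c(0, 1)), options)
  gtab <- gradient_table
  signal <- as.numeric(signal)
  if (length(signal) != length(gtab$bvals)) {
    stop("signal length does not match the gradient table")
  }
  if (all(signal == 0)) stop("all-zero signal: voxel cannot be fit")
  S0 <- mean(signal[gtab$b0])
  if (!is.finite(S0) || S0 <= 0) stop("nonpositive S0; check b0 volumes")
  dw <- !gtab$b0
  A <- pmin(pmax(signal[dw] / S0, 1e-6), 2)
  b_dw <- gtab$bvals[dw]
  g_dw <- gtab$bvecs[dw, , drop = FALSE]
  cfree <- exp(-b_dw * D_FREE_WATER)
  Xd <- cbind(g_dw[, 1]^2, g_dw[, 2]^2, g_dw[, 3]^2,
              2 * g_dw[, 1] * g_dw[, 2],
              2 * g_dw[, 1] * g_dw[, 3],
              2 * g_dw[, 2] * g_dw[, 3])
  opt$qrX <- solve(crossprod(Xd), t(Xd))
  opt$g_dw <- g_dw

  iso_prior <- diag(opt$md_prior, 3)
  pure_free <- function(fw) {
    model <- fw * cfree + (1 - fw) * exp(-b_dw * opt$md_prior)
    sum((A - model)^2)
  }
  rng <- pmin(pmax(opt$fw_range, 0), 1)
  fw_grid <- seq(rng[1], min(rng[2], 1 - opt$fw_grid_step),
                 by = opt$fw_grid_step)
  if (!length(fw_grid)) fw_grid <- rng[1]
  objective <- function(fw) .tissue_fit_at_fw(fw, A, cfree, Xd, b_dw, opt)$objective
  obj_grid <- vapply(fw_grid, objective, numeric(1))
  # fw -> 1 leaves no tissue signal: evaluate the pure-free limit separately
  obj_one <- if (rng[2] >= 1) pure_free(1) else Inf
  if (obj_one < min(obj_grid)) {
    best_fw <- 1
    fitD <- iso_prior
    rss <- obj_one
    converged <- TRUE
  } else {
    i <- which.min(obj_grid)
    lo <- max(rng[1], fw_grid[i] - opt$fw_grid_step)
    hi <- min(rng[2], 1 - 1e-6, fw_grid[i] + opt$fw_grid_step)
    if (isTRUE(opt$refine) && hi > lo) {
      o <- optimize(objective, c(lo, hi), tol = 1e-6)
      best_fw <- if (o$objective <= obj_grid[i]) o$minimum else fw_grid[i]
    } else {
      best_fw <- fw_grid[i]
    }
    res <- .tissue_fit_at_fw(best_fw, A, cfree, Xd, b_dw, opt)
    fitD <- res$D
    rss <- res$rss
    converged <- TRUE
  }
  structure(list(fw = best_fw, tensor = fitD, fa_t = fa_from_tensor(fitD),
                 S0 = S0, converged = converged,
                 residual_norm = sqrt(rss)),
            class = "bitensor_fit")
}

#' Voxelwise free-water fitting of a 4D volume
#'
#' Applies [fit_bitensor()] within a mask and assembles FW and FA_T maps;
#' out-of-mask voxels carry `fill`.
#'
#' @param dwi_4d 4D array (x, y, z, volume).
#' @param mask logical 3D array on the same grid (NULL = all voxels).
#' @param gradient_table a [gradient_table()].
#' @param options passed to [fit_bitensor()].
#' @param fill value outside the mask (default `NA`).
#' @param verbose print slice progress.
#' @return list with 3D arrays `fw`, `fa_t`, and logical `converged`.
#' @export
fit_freewater_volume <- function(dwi_4d, mask = NULL, gradient_table,
                                 options = list(), fill = NA_real_,
                                 verbose = FALSE) {
  dims <- dim(dwi_4d)
  if (length(dims) != 4L) stop("dwi_4d must be a 4D array")
  if (dims[4] != length(gradient_table$bvals)) {
    stop("4D volume count does not match the gradient table")
  }
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!all(dim(mask) == dims[1:3])) stop("mask grid does not match the volume")
  fw <- array(fill, dims[1:3])
  fa <- array(fill, dims[1:3])
  conv <- array(FALSE, dims[1:3])
  idx <- which(mask)
  if (length(idx)) {
    coords <- arrayInd(idx, dims[1:3])
    for (v in seq_along(idx)) {
      i <- coords[v, 1]; j <- coords[v, 2]; k <- coords[v, 3]
      fit <- fit_bitensor(dwi_4d[i, j, k, ], gradient_table, options)
      fw[i, j, k] <- fit$fw
      fa[i, j, k] <- fit$fa_t
      conv[i, j, k] <- fit$converged
    }
    if (verbose) message("fit ", length(idx), " voxels")
  }
  list(fw = fw, fa_t = fa, converged = conv)
}
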