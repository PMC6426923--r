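# Flatten a 4D map stack (x, y, z, subject) to a subjects x voxels matrix
# restricted to `mask`; returns the matrix plus bookkeeping to fold results
# back into 3D arrays.
.flatten_maps <- function(maps, mask = NULL) {
  dims <- dim(maps)
  if (length(dims) != 4L) stop("maps must be a 4D array (x, y, z, subject)")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!all(dim(mask) == dims[1:3])) stop("analysis mask grid does not match maps")
  if (!any(mask)) stop("analysis mask is empty")
  n <- dims[4]
  flat <- matrix(aperm(maps, c(4, 1, 2, 3)), nrow = n)
  list(Y = flat[, as.vector(mask), drop = FALSE], mask = mask, dims = dims[1:3])
}

.unflatten <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}

# Residualize columns of M on the nuisance design [1, covariates].
.residualize <- function(M, covariates) {
  Z <- cbind(`(Intercept)` = rep(1, nrow(M)), covariates)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(res = M - qr.fitted(qz, M), rank = qz$rank)
}

.t_cap <- 1e6

# Voxelwise t statistics for a single regressor of interest after
# Frisch-Waugh residualization on the nuisance block.  `scale0` carries the
# raw column norms: voxels whose residual variation is negligible relative
# to their raw magnitude (constant maps, maps collinear with the
# covariates) get t = 0.
.t_stats <- function(res_out, res_Y, df, scale0 = NULL) {
  so <- sqrt(sum(res_out^2))
  if (so < 1e-12) return(rep(0, ncol(res_Y)))
  sy <- sqrt(colSums(res_Y^2))
  if (is.null(scale0)) scale0 <- sy
  degenerate <- sy <= 1e-8 * scale0 + 1e-300
  num <- as.vector(crossprod(res_Y, res_out))
  r <- ifelse(degenerate, 0, num / (so * pmax(sy, 1e-300)))
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(df / pmax(1 - r^2, 0))
  t[!is.finite(t)] <- sign(r[!is.finite(t)]) * .t_cap
  pmin(pmax(t, -.t_cap), .t_cap)
}

#' Mass-univariate voxelwise GLM
#'
#' Per-voxel ordinary least squares of each map on the outcome of interest
#' plus nuisance covariates; returns the t statistic of the outcome
#' coefficient.  Computed by Frisch-Waugh residualization, so an outcome that
#' is collinear with the covariates yields t = 0 everywhere (with a warning)
#' rather than an error; collinearity *within* the covariate block errors,
#' naming the columns.  Voxels with zero residual variance get t = 0 (or the
#' cap `1e6` when the fit is perfect with nonzero slope).
#'
#' @param maps 4D array (x, y, z, subject).
#' @param outcome numeric outcome per subject (e.g. memory z-score).
#' @param covariates optional numeric matrix/data.frame of nuisance columns.
#' @param analysis_mask optional logical 3D array.
#' @return 3D array of t statistics (0 outside the mask), with attributes
#'   `df` and `mask`.
#' @export
massunivariate_glm <- function(maps, outcome, covariates = NULL,
                               analysis_mask = NULL) {
  fl <- .flatten_maps(maps, analysis_mask)
  n <- nrow(fl$Y)
  covariates <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < n_cov + 3L) stop("need at least covariates + 3 subjects")
  rz <- .residualize(cbind(outcome, fl$Y), covariates)
  res_out <- rz$res[, 1]
  res_Y <- rz$res[, -1, drop = FALSE]
  if (sqrt(sum(res_out^2)) < 1e-10 * max(1, sqrt(sum(outcome^2)))) {
    warning("outcome is collinear with the covariates; all t set to 0")
  }
  df <- n - rz$rank - 1L
  t <- .t_stats(res_out, res_Y, df, scale0 = sqrt(colSums(fl$Y^2)))
  tmap <- .unflatten(t, fl$mask)
  attr(tmap, "df") <- df
  attr(tmap, "mask") <- fl$mask
  tmap
}

#' Threshold-free cluster enhancement
#'
#' Discretized TFCE integral: each voxel accumulates
#' \eqn{e(h)^E h^H \, dh} over height steps \eqn{h \le} its value, where
#' \eqn{e(h)} is the extent of its supporting cluster at height h.
#' Negative input values contribute nothing (enhance `abs(t)` or each sign
#' separately for two-sided use).
#'
#' @param statmap 3D numeric array (nonnegative part is enhanced).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh step size; default `max(statmap)/100`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D array of enhanced values.
#' @export
tfce_enhance <- function(statmap, E = 0.5, H = 2, dh = NULL,
                         connectivity = 26) {
  if (E < 0 || H < 0) stop("TFCE exponents E and H must be nonnegative")
  dims <- dim(statmap)
  if (length(dims) != 3L) stop("statmap must be a 3D array")
  v <- pmax(as.vector(statmap), 0)
  if (is.null(dh)) dh <- max(v) / 100
  if (max(v) == 0) return(array(0, dims))
  if (dh <= 0) stop("dh must be > 0")
  out <- .tfce_cpp(v, as.integer(dims), E, H, dh, as.integer(connectivity))
  array(out, dims)
}

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array of cluster labels (0 = background) with
#'   attribute `sizes` (voxels per cluster).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  if (length(dims) != 3L) stop("mask must be a 3D array")
  lab <- .cc_label_cpp(as.logical(mask), as.integer(dims),
                       as.integer(connectivity))
  out <- array(lab, dims)
  nc <- attr(lab, "n_clusters")
  attr(out, "sizes") <- if (nc > 0) tabulate(lab[lab > 0], nc) else integer(0)
  out
}

# Cluster masses (sum of |t| excess over the height threshold) of the
# suprathreshold components; mass rather than extent keeps the null
# distribution continuous, so the permutation test is not made conservative
# by ties among small cluster sizes.
.cluster_masses <- function(t3, mask, height_t, connectivity) {
  supra <- abs(t3) >= height_t & mask
  lab <- label_clusters(supra, connectivity)
  nc <- length(attr(lab, "sizes"))
  if (!nc) return(list(lab = lab, mass = numeric(0),
                       size = integer(0)))
  excess <- abs(t3) - height_t
  mass <- vapply(seq_len(nc), function(ci) sum(excess[lab == ci]),
                 numeric(1))
  list(lab = lab, mass = mass, size = attr(lab, "sizes"))
}

# Per-permutation max statistic for one of the three correction methods.
.perm_statistic <- function(tmap_vec, mask, method, df, height_t, E, H,
                            connectivity, dh_ref) {
  if (method == "maxT") return(max(abs(tmap_vec)))
  t3 <- .unflatten(tmap_vec, mask)
  if (method == "tfce") {
    enh <- tfce_enhance(abs(t3), E = E, H = H, dh = dh_ref,
                        connectivity = connectivity)
    return(max(enh[mask]))
  }
  cm <- .cluster_masses(t3, mask, height_t, connectivity)
  if (length(cm$mass)) max(cm$mass) else 0
}

#' Permutation-based familywise-error-corrected screening
#'
#' Fits the voxelwise GLM, then builds the null distribution of the maximum
#' statistic by sign-free permutation of the covariate-residualized outcome
#' (Freedman-Lane style), giving FWE-corrected p-values at the voxel level
#' (`maxT`, `tfce`) or cluster level (`cluster`).  The identity permutation
#' is always included in the null, so corrected p-values are bounded below
#' by `1/n_perm`.
#'
#' @param maps 4D array (x, y, z, subject).
#' @param outcome numeric outcome of interest.
#' @param covariates optional nuisance matrix.
#' @param n_perm number of permutations (identity included); below 100
#'   triggers a warning.
#' @param method `"maxT"`, `"tfce"` or `"cluster"`.
#' @param alpha familywise error level for the significance mask.
#' @param seed integer seed for the permutation stream.
#' @param analysis_mask optional logical 3D array.
#' @param height_p cluster-forming height threshold (two-sided p), used by
#'   `method = "cluster"` only.
#' @param E,H,connectivity TFCE/clustering parameters.
#' @return list of class `statmap_result`: `tmap`, `pmap_fwe`, `mask`
#'   (significant voxels), `method`, `null_max` (permutation distribution),
#'   `alpha`, plus cluster tables for the cluster method.
#' @export
permutation_fwe <- function(maps, outcome, covariates = NULL, n_perm = 1000L,
                            method = c("maxT", "tfce", "cluster"),
                            alpha = 0.05, seed = 1L, analysis_mask = NULL,
                            height_p = 0.01, E = 0.5, H = 2,
                            connectivity = 26) {
  method <- match.arg(method)
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse FWE estimate")
  fl <- .flatten_maps(maps, analysis_mask)
  n <- nrow(fl$Y)
  covariates <- if (is.null(covariates)) NULL else as.matrix(covariates)
  rz <- .residualize(cbind(outcome, fl$Y), covariates)
  res_out <- rz$res[, 1]
  res_Y <- rz$res[, -1, drop = FALSE]
  df <- n - rz$rank - 1L
  height_t <- qt(1 - height_p / 2, df)

  t_obs <- .t_stats(res_out, res_Y, df)
  dh_ref <- if (method == "tfce") max(abs(t_obs)) / 100 else NULL
  if (!is.null(dh_ref) && dh_ref <= 0) dh_ref <- 1e-3

  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  null_max[1] <- .perm_statistic(t_obs, fl$mask, method, df, height_t,
                                 E, H, connectivity, dh_ref)
  for (b in seq_len(n_perm - 1L)) {
    perm <- sample.int(n)
    t_b <- .t_stats(res_out[perm], res_Y, df)
    null_max[b + 1L] <- .perm_statistic(t_b, fl$mask, method, df, height_t,
                                        E, H, connectivity, dh_ref)
  }

  tmap <- .unflatten(t_obs, fl$mask)
  if (method == "cluster") {
    cm <- .cluster_masses(tmap, fl$mask, height_t, connectivity)
    pmap <- array(1, dim(fl$mask))
    sig <- array(FALSE, dim(fl$mask))
    clus_p <- vapply(cm$mass, function(s) mean(null_max >= s), numeric(1))
    for (ci in seq_along(cm$mass)) {
      inside <- cm$lab == ci
      pmap[inside] <- clus_p[ci]
      if (clus_p[ci] <= alpha) sig[inside] <- TRUE
    }
    clusters <- data.frame(cluster = seq_along(cm$mass), size = cm$size,
                           mass = cm$mass, p_fwe = clus_p)
  } else {
    stat_obs <- if (method == "maxT") {
      abs(t_obs)
    } else {
      enh <- tfce_enhance(abs(tmap), E = E, H = H, dh = dh_ref,
                          connectivity = connectivity)
      enh[fl$mask]
    }
    p <- vapply(stat_obs, function(s) mean(null_max >= s), numeric(1))
    pmap <- .unflatten(p, fl$mask, fill = 1)
    sig <- .unflatten(p <= alpha, fl$mask, fill = FALSE) & fl$mask
    clusters <- NULL
  }
  structure(list(tmap = tmap, pmap_fwe = pmap, mask = sig, method = method,
                 null_max = null_max, alpha = alpha, df = df,
                 analysis_mask = fl$mask, clusters = clusters,
                 height_t = if (method == "cluster") height_t else NA_real_),
            class = "statmap_result")
}

#' Cluster-extent thresholding with a permutation null
#'
#' The published analysis thresholded at voxel height p < 0.01 and assessed
#' cluster significance at p < 0.05; here the cluster-level null comes from
#' permutation rather than Gaussian-random-field theory (documented
#' deviation), using cluster *mass* (summed |t| excess over the threshold)
#' as the statistic — extent with small samples has a heavily tied null
#' that makes the test conservative.  Thin wrapper over [permutation_fwe()]
#' with `method = "cluster"`.
#'
#' @inheritParams permutation_fwe
#' @return a `statmap_result` (see [permutation_fwe()]).
#' @export
cluster_threshold <- function(maps, outcome, covariates = NULL,
                              height_p = 0.01, n_perm = 1000L, alpha = 0.05,
                              seed = 1L, analysis_mask = NULL,
                              connectivity = 26) {
  permutation_fwe(maps, outcome, covariates, n_perm = n_perm,
                  method = "cluster", alpha = alpha, seed = seed,
                  analysis_mask = analysis_mask, height_p = height_p,
                  connectivity = connectivity)
}

#' Per-subject mean over significant regions
#'
#' Extracts each subject's mean map value inside each mask — the ROI values
#' that feed the varying-coefficient model.
#'
#' @param maps 4D array (x, y, z, subject).
#' @param mask_set named list of logical 3D arrays (or a single mask).
#' @return data.frame, one column per ROI, one row per subject; an empty
#'   mask gives an `NaN` column with a warning.
#' @export
extract_roi_means <- function(maps, mask_set) {
  if (!is.list(mask_set)) mask_set <- list(roi = mask_set)
  if (is.null(names(mask_set)) || any(!nzchar(names(mask_set)))) {
    names(mask_set) <- paste0("roi", seq_along(mask_set))
  }
  dims <- dim(maps)
  n <- dims[4]
  out <- lapply(names(mask_set), function(nm) {
    m <- mask_set[[nm]]
    if (!all(dim(m) == dims[1:3])) stop("mask '", nm, "' grid does not match maps")
    if (!any(m)) {
      warning("mask '", nm, "' is empty; returning NaN")
      return(rep(NaN, n))
    }
    flat <- matrix(aperm(maps, c(4, 1, 2, 3)), nrow = n)
    rowMeans(flat[, as.vector(m), drop = FALSE])
  })
  setNames(as.data.frame(out), names(mask_set))
}

#' Fisher r-to-z transform
#'
#' Utility for converting correlation maps to z maps, \eqn{z = \mathrm{atanh}(r)}.
#' @param r correlations in (-1, 1).
#' @return transformed values.
#' @export
fisher_r_to_z <- function(r) atanh(r)
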