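#' Default single-shell acquisition gradient table
#'
#' 7 b0 volumes followed by 61 diffusion-weighted directions at
#' b = 1150 s/mm^2 — the acquisition the bi-tensor model is designed for.
#' Directions are a deterministic Fibonacci-sphere set (hemisphere).
#'
#' @param n_dir number of DW directions.
#' @param n_b0 number of b = 0 volumes.
#' @param bval shell b-value in s/mm^2.
#' @return a [gradient_table()].
#' @export
default_gradient_table <- function(n_dir = 61L, n_b0 = 7L, bval = 1150) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_dir              # hemisphere z in (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  bvals <- c(rep(0, n_b0), rep(bval, n_dir))
  gradient_table(bvals, bvecs)
}

#' Build a symmetric tensor from eigenvalues and an orientation
#'
#' @param evals length-3 nonnegative eigenvalues (mm^2/s).
#' @param angles optional length-3 Euler angles (radians) rotating the
#'   principal frame; default is axis-aligned.
#' @return 3 x 3 symmetric matrix.
#' @export
tensor_from_eigen <- function(evals, angles = c(0, 0, 0)) {
  stopifnot(length(evals) == 3L, all(evals >= 0))
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Q <- Rz %*% Ry %*% Rx
  Q %*% diag(evals) %*% t(Q)
}

#' Simulate a single-voxel bi-tensor diffusion signal
#'
#' Forward model \eqn{S = S_0 [ f e^{-b d_{free}} + (1-f) e^{-b g^\top D g}]}
#' with the free compartment's diffusivity fixed at
#' \eqn{d_{free} = 3\times10^{-3}} mm^2/s; b = 0 volumes carry \eqn{S_0}.
#' Optional Rician noise (magnitude of complex Gaussian noise).
#'
#' @param f free-water fraction in \[0, 1\].
#' @param tensor 3 x 3 symmetric positive-semidefinite tissue tensor (mm^2/s).
#' @param gradient_table a [gradient_table()].
#' @param S0 reference signal.
#' @param noise_sd Rician noise SD in signal units (0 = noiseless).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return numeric signal vector, one value per volume.
#' @export
generate_dwi_voxel <- function(f, tensor, gradient_table,
                               S0 = 1000, noise_sd = 0, seed = 1L) {
  if (f < 0 || f > 1) stop("free-water fraction f must lie in [0, 1]")
  check_tensor(tensor)
  s <- predict_signal(list(fw = f, tensor = tensor), gradient_table, S0 = S0)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    n <- length(s)
    s <- sqrt((s + rnorm(n, 0, noise_sd))^2 + rnorm(n, 0, noise_sd)^2)
  }
  s
}

#' Simulate a two-region 4D diffusion phantom
#'
#' Small grid whose voxels belong to one of two regions with distinct
#' free-water fractions and tensors; used to exercise the volumewise fit.
#'
#' @param dims length-3 grid dimensions.
#' @param region_mask logical array (`dims`); `TRUE` voxels use `f2`/`tensor2`.
#' @param f1,f2 free-water fractions of the two regions.
#' @param tensor1,tensor2 tissue tensors.
#' @param gradient_table acquisition table.
#' @param S0,noise_sd,seed as in [generate_dwi_voxel()].
#' @return list with `dwi` (4D array, last dim = volumes) and `mask`.
#' @export
generate_dwi_phantom <- function(dims = c(4, 4, 4), region_mask = NULL,
                                 f1 = 0.15, f2 = 0.6,
                                 tensor1 = tensor_from_eigen(c(1.4, 0.4, 0.4) * 1e-3),
                                 tensor2 = tensor_from_eigen(c(1.0, 0.6, 0.6) * 1e-3),
                                 gradient_table = default_gradient_table(),
                                 S0 = 1000, noise_sd = 0, seed = 1L) {
  if (is.null(region_mask)) {
    region_mask <- array(FALSE, dims)
    region_mask[seq_len(ceiling(dims[1] / 2)), , ] <- TRUE
  }
  set.seed(as.integer(seed))
  nvol <- length(gradient_table$bvals)
  dwi <- array(0, c(dims, nvol))
  idx <- which(array(TRUE, dims))
  coords <- arrayInd(idx, dims)
  for (v in seq_along(idx)) {
    inner <- region_mask[coords[v, 1], coords[v, 2], coords[v, 3]]
    s <- predict_signal(
      list(fw = if (inner) f2 else f1,
           tensor = if (inner) tensor2 else tensor1),
      gradient_table, S0 = S0)
    if (noise_sd > 0) {
      s <- sqrt((s + rnorm(nvol, 0, noise_sd))^2 + rnorm(nvol, 0, noise_sd)^2)
    }
    dwi[coords[v, 1], coords[v, 2], coords[v, 3], ] <- s
  }
  list(dwi = dwi, region_mask = region_mask)
}

#' Simulate subject-level 3D statistical maps with embedded effects
#'
#' Per-subject map = baseline Gaussian noise plus, inside each spherical
#' cluster, an effect proportional to the subject's outcome value.  Returns
#' the ground-truth effect mask alongside, for screening calibration tests.
#'
#' @param grid_shape length-3 dims.
#' @param effect_clusters list of `list(center =, radius =, amplitude =)`;
#'   empty list gives a pure-null stack.
#' @param outcome numeric outcome per subject (e.g. memory z-scores).
#' @param noise_sd baseline noise SD.
#' @param seed integer seed.
#' @return list with `maps` (4D array, last dim = subject) and `truth`
#'   (logical 3D array).
#' @export
generate_stat_maps <- function(grid_shape = c(16, 16, 16),
                               effect_clusters = list(),
                               outcome, noise_sd = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape <= 0)) stop("grid dimensions must be positive")
  n <- length(outcome)
  set.seed(as.integer(seed))
  truth <- array(FALSE, grid_shape)
  effect <- array(0, grid_shape)
  if (length(effect_clusters)) {
    ax <- lapply(grid_shape, seq_len)
    gx <- array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape)
    gy <- aperm(array(rep(ax[[2]], times = grid_shape[1] * grid_shape[3]),
                      grid_shape[c(2, 1, 3)]), c(2, 1, 3))
    gz <- aperm(array(rep(ax[[3]], times = grid_shape[1] * grid_shape[2]),
                      grid_shape[c(3, 1, 2)]), c(2, 3, 1))
    for (cl in effect_clusters) {
      if (any(cl$center < 1 | cl$center > grid_shape)) {
        stop("effect cluster centre outside grid")
      }
      d2 <- (gx - cl$center[1])^2 + (gy - cl$center[2])^2 + (gz - cl$center[3])^2
      inside <- d2 <= cl$radius^2
      truth <- truth | (inside & cl$amplitude != 0)
      effect[inside] <- effect[inside] + cl$amplitude
    }
  }
  maps <- array(rnorm(prod(grid_shape) * n, 0, noise_sd), c(grid_shape, n))
  for (i in seq_len(n)) {
    maps[, , , i] <- maps[, , , i] + effect * outcome[i]
  }
  list(maps = maps, truth = truth)
}
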