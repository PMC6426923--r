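# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths.

# Cox-de Boor recursion, written directly from the recurrence.
cox_de_boor <- function(knots, t, i, k) {
  if (k == 0) {
    # half-open spans; the last span is closed at the right boundary
    last <- max(which(knots < max(knots)))
    if (i == last) {
      return(as.numeric(t >= knots[i] & t <= knots[i + 1]))
    }
    return(as.numeric(t >= knots[i] & t < knots[i + 1]))
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  a <- if (d1 > 0) (t - knots[i]) / d1 * cox_de_boor(knots, t, i, k - 1) else 0
  b <- if (d2 > 0) {
    (knots[i + k + 1] - t) / d2 * cox_de_boor(knots, t, i + 1, k - 1)
  } else 0
  a + b
}

cox_de_boor_basis <- function(knots, t, degree) {
  L <- length(knots) - degree - 1
  sapply(seq_len(L), function(i) cox_de_boor(knots, t, i, degree))
}

# Group-LASSO objective in the transformed coordinates.
gl_objective <- function(Zt, y, gt, lambda, p, L) {
  n <- length(y)
  r <- y - Zt %*% as.vector(gt)
  sum(r^2) / (2 * n) + lambda * sum(sqrt(colSums(matrix(gt, L, p)^2)))
}

# Brute-force minimizer for tiny group-LASSO problems: coarse grid search
# refined around the incumbent; independent of the BCD solver.
gl_grid_search <- function(Zt, y, lambda, p, L, half_width = 2,
                           n_refine = 6, n_grid = 7) {
  centre <- rep(0, p * L)
  width <- half_width
  best <- list(par = centre,
               value = gl_objective(Zt, y, centre, lambda, p, L))
  for (r in seq_len(n_refine)) {
    axes <- lapply(seq_len(p * L), function(i) {
      seq(best$par[i] - width, best$par[i] + width, length.out = n_grid)
    })
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(grid, 1, function(g) gl_objective(Zt, y, g, lambda, p, L))
    i <- which.min(vals)
    best <- list(par = grid[i, ], value = vals[i])
    width <- width * 2.5 / n_grid
  }
  best
}

# FA from eigenvalues, straight from the definition.
fa_formula <- function(ev) {
  md <- mean(ev)
  sqrt(3 / 2) * sqrt(sum((ev - md)^2)) / sqrt(sum(ev^2))
}

# Axially symmetric eigenvalues (l1, l2, l2) with given mean diffusivity and
# FA, solved numerically from the FA formula.
evals_from_fa <- function(fa, md = 0.7e-3) {
  if (fa == 0) return(rep(md, 3))
  f <- function(r) {            # r = l1 / l2
    ev <- c(r, 1, 1)
    fa_formula(ev) - fa
  }
  r <- uniroot(f, c(1 + 1e-9, 2000))$root
  l2 <- 3 * md / (r + 2)
  c(r * l2, l2, l2)
}

# Small random observation set with a known generating signal.
make_obs <- function(n = 60, p = 3, seed = 1, beta_fun = NULL, eps_sd = 0.1) {
  set.seed(seed)
  t <- round(runif(n, 0, 10) * 2) / 2
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  Xs <- scale(X)
  y <- if (is.null(beta_fun)) {
    rnorm(n, 0, eps_sd)
  } else {
    sig <- rowSums(sapply(seq_len(p), function(j) beta_fun(j, t) * Xs[, j]))
    sig + rnorm(n, 0, eps_sd)
  }
  observation_set(y, t, X)
}

# Discrete TFCE sum for a single isolated voxel of height h0.
tfce_single_voxel <- function(h0, E, H, dh) {
  s <- seq_len(floor(h0 / dh + 1e-12))
  sum(1^E * (s * dh)^H * dh)
}
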