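#' Replicate stability bands for the coefficient trajectories
#'
#' Refits the whole SVC pipeline (including CV) on `n_rep` resampled
#' datasets and summarizes the coefficient trajectories pointwise: mean,
#' standard error (SD across replicates), and per-predictor selection
#' counts.  "Stably selected" predictors are those selected in every
#' replicate.  The resampling scheme defaults to the nonparametric bootstrap
#' over subjects; subsampling (fraction 0.8) and plain CV-seed refitting are
#' available alternatives.
#'
#' @param obs an [observation_set()].
#' @param config an [svc_config()]; the basis domain is pinned to the full
#'   observed severity range so every replicate shares one grid.
#' @param n_rep number of replicates (published setup: 100).
#' @param seed integer seed.
#' @param scheme `"bootstrap"`, `"subsample"` or `"cv-refit"`.
#' @param t_grid optional severity grid for the bands.
#' @return list of class `stability_bands`: `mean`, `se` (grid x predictor
#'   matrices), `t_grid`, `selection_count`, `n_rep`, `n_failed`, `scheme`,
#'   `stable` (logical: selected in all replicates), `trajectories`
#'   (grid x predictor x replicate array).
#' @export
stability_replicates <- function(obs, config = svc_config(), n_rep = 100L,
                                 seed = 1L, scheme = c("bootstrap",
                                                       "subsample",
                                                       "cv-refit"),
                                 t_grid = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(obs, "observation_set"))
  n_rep <- as.integer(n_rep)
  config$domain <- range(obs$t)
  config$allow_constant <- TRUE   # a bootstrap draw can flatten a rare binary
  if (is.null(t_grid)) {
    t_grid <- seq(config$domain[1], config$domain[2], by = config$t_grid_step)
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_rep)
  traj <- array(NA_real_, c(length(t_grid), obs$p, n_rep))
  sel <- matrix(FALSE, n_rep, obs$p)
  failed <- logical(n_rep)
  for (b in seq_len(n_rep)) {
    set.seed(rep_seeds[b])
    idx <- switch(scheme,
      bootstrap = sample.int(obs$n, obs$n, replace = TRUE),
      subsample = sample.int(obs$n, ceiling(0.8 * obs$n)),
      `cv-refit` = seq_len(obs$n)
    )
    ob <- observation_set(obs$y[idx], obs$t[idx],
                          obs$X[idx, , drop = FALSE],
                          obs$predictor_names)
    cfg <- config
    cfg$seed <- rep_seeds[b]
    res <- tryCatch({
      fit <- fit_svc(ob, cfg)
      list(beta = evaluate_trajectories(fit, t_grid), sel = fit$selected)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[b] <- TRUE
    } else {
      traj[, , b] <- res$beta
      sel[b, ] <- res$sel
    }
  }
  n_failed <- sum(failed)
  if (n_failed > 0.1 * n_rep) {
    stop("more than 10% of replicates failed (", n_failed, "/", n_rep, ")")
  }
  ok <- !failed
  mean_tr <- apply(traj[, , ok, drop = FALSE], c(1, 2), mean)
  se_tr <- apply(traj[, , ok, drop = FALSE], c(1, 2), sd)
  colnames(mean_tr) <- colnames(se_tr) <- obs$predictor_names
  counts <- colSums(sel[ok, , drop = FALSE])
  structure(list(mean = mean_tr, se = se_tr, t_grid = t_grid,
                 selection_count = setNames(counts, obs$predictor_names),
                 n_rep = sum(ok), n_failed = n_failed, scheme = scheme,
                 stable = setNames(counts == sum(ok), obs$predictor_names),
                 trajectories = traj[, , ok, drop = FALSE]),
            class = "stability_bands")
}

#' @export
print.stability_bands <- function(x, ...) {
  cat("Stability bands over", x$n_rep, "replicates (", x$scheme, ")\n")
  cat("  selection counts:\n")
  print(x$selection_count)
  cat("  stably selected:", if (any(x$stable))
    paste(names(x$stable)[x$stable], collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Permutation specificity of the stable-selection rule
#'
#' Repeats the full stability analysis on datasets whose memory scores were
#' randomly permuted across subjects (destroying every brain-memory
#' association while keeping the marginals).  For each permuted dataset the
#' stably-selected set (selected in all `n_rep` replicates) is recorded; a
#' specific model should most often select nothing at all on permuted data.
#'
#' @param obs an [observation_set()].
#' @param config an [svc_config()].
#' @param n_perm number of outcome permutations (published setup 100).
#' @param n_rep replicates per permutation (published setup 100).
#' @param seed integer seed.
#' @param scheme resampling scheme for the inner stability loop.
#' @return list of class `permutation_specificity`: `stable_sets` (list of
#'   character vectors), `n_empty` (permutations with no stable predictor),
#'   `frequency` (per-predictor count of permutations in which it was
#'   stable), `n_perm`, `n_rep`.
#' @export
permutation_specificity <- function(obs, config = svc_config(),
                                    n_perm = 100L, n_rep = 100L, seed = 1L,
                                    scheme = "bootstrap") {
  stopifnot(inherits(obs, "observation_set"))
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  stable_sets <- vector("list", n_perm)
  for (q in seq_len(n_perm)) {
    set.seed(perm_seeds[q])
    yq <- obs$y[sample.int(obs$n)]
    ob <- observation_set(yq, obs$t, obs$X, obs$predictor_names)
    bands <- stability_replicates(ob, config, n_rep = n_rep,
                                  seed = perm_seeds[q], scheme = scheme)
    stable_sets[[q]] <- names(bands$stable)[bands$stable]
  }
  freq <- table(factor(unlist(stable_sets), levels = obs$predictor_names))
  structure(list(stable_sets = stable_sets,
                 n_empty = sum(lengths(stable_sets) == 0),
                 frequency = setNames(as.integer(freq), obs$predictor_names),
                 n_perm = n_perm, n_rep = n_rep),
            class = "permutation_specificity")
}

#' @export
print.permutation_specificity <- function(x, ...) {
  cat("Permutation specificity:", x$n_perm, "permutations x", x$n_rep,
      "replicates\n")
  cat("  permutations with empty stable set:", x$n_empty, "/", x$n_perm, "\n")
  cat("  per-predictor stable counts:\n")
  print(x$frequency)
  invisible(x)
}

#' Plot coefficient trajectories with stability bands
#'
#' One panel per predictor: replicate-mean trajectory (solid) with
#' pointwise mean +/- 2 SE bands (dashed), in the style of varying
#' coefficient trajectory figures.
#'
#' @param x a `stability_bands` object.
#' @param predictors subset of predictor names (default: all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.stability_bands <- function(x, predictors = colnames(x$mean), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(predictors)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in predictors) {
    m <- x$mean[, nm]
    s <- x$se[, nm]
    graphics::matplot(x$t_grid, cbind(m, m - 2 * s, m + 2 * s),
                      type = "l", lty = c(1, 2, 2),
                      col = c("black", "grey40", "grey40"),
                      xlab = "CDR-SB severity", ylab = "beta(t)",
                      main = nm, ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
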