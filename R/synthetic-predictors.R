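# Severity-dependent deterioration means of the six brain measures, in
# plausible native units: FW fraction rises with severity, everything else
# declines monotonically.  `sd0` is each measure's natural noise scale.
.measure_models <- list(
  FW          = list(mean = function(t) 0.15 + 0.012 * t, sd0 = 0.100),
  FA_T_fornix = list(mean = function(t) 0.50 - 0.010 * t, sd0 = 0.072),
  GMV_mPFC    = list(mean = function(t) 8.0 - 0.12 * t,   sd0 = 1.45),
  GMV_PCC     = list(mean = function(t) 6.0 - 0.10 * t,   sd0 = 1.10),
  GMV_HIP     = list(mean = function(t) 7.5 - 0.15 * t,   sd0 = 1.25),
  FC_DMN      = list(mean = function(t) 0.45 - 0.012 * t, sd0 = 0.145)
)

#' Generate the subject-by-predictor table
#'
#' Each brain measure is its severity-dependent deterioration mean plus
#' independent Gaussian noise (`noise_sd` scales every measure's natural
#' noise SD); nuisance columns are numeric encodings of the cohort
#' demographics (gender F=1, handedness L=1, ethnicity C=1).
#'
#' @param cohort a [generate_cohort()] table.
#' @param scenario trajectory list fixing predictor names/order
#'   (default [paper_trajectory_scenario()]).
#' @param noise_sd nonnegative noise multiplier; 0 gives deterministic
#'   functions of severity.
#' @param seed integer seed.
#' @return `data.frame` of class `predictor_table`, columns in scenario order.
#' @export
generate_predictors <- function(cohort, scenario = paper_trajectory_scenario(),
                                noise_sd = 1, seed = 1L) {
  if (!nrow(cohort)) stop("cohort is empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  t <- cohort$severity
  n <- nrow(cohort)
  cols <- lapply(names(scenario), function(nm) {
    if (nm %in% names(.measure_models)) {
      m <- .measure_models[[nm]]
      m$mean(t) + rnorm(n, 0, noise_sd * m$sd0)
    } else {
      switch(nm,
        age = cohort$age,
        gender = as.numeric(cohort$gender == "F"),
        handedness = as.numeric(cohort$handedness == "L"),
        ethnicity = as.numeric(cohort$ethnicity == "C"),
        stop("no generating rule for predictor '", nm, "'")
      )
    }
  })
  out <- as.data.frame(cols, col.names = names(scenario))
  if (anyNA(out)) stop("predictor generation produced missing values")
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' Generate memory z-scores from the varying-coefficient model
#'
#' Simulates the outcome \eqn{y_i = \sum_j \beta_j(t_i)\,\tilde x_{ij} +
#' \varepsilon_i}, where \eqn{\tilde x} are the predictors standardized to
#' zero mean / unit variance over the cohort (matching how the model is fit)
#' and \eqn{\varepsilon_i \sim N(0, \mathrm{eps\_sd}^2)} i.i.d.
#'
#' @param cohort cohort table (supplies severities).
#' @param predictors matching [generate_predictors()] table.
#' @param scenario named list of [trajectory_spec()] covering every predictor
#'   column.
#' @param eps_sd residual SD in memory z-score units.
#' @param seed integer seed.
#' @return numeric vector of memory z-scores, one per subject.
#' @export
generate_memory <- function(cohort, predictors,
                            scenario = paper_trajectory_scenario(),
                            eps_sd = 0.5, seed = 1L) {
  if (nrow(cohort) != nrow(predictors)) {
    stop("cohort and predictor tables have different numbers of rows")
  }
  if (eps_sd < 0) stop("eps_sd must be >= 0")
  miss <- setdiff(colnames(predictors), names(scenario))
  if (length(miss)) stop("no trajectory for predictor(s): ",
                         paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  Xs <- standardize_predictors(as.matrix(predictors))$x
  t <- cohort$severity
  signal <- rowSums(vapply(colnames(predictors), function(nm) {
    eval_trajectory(scenario[[nm]], t) * Xs[, nm]
  }, numeric(nrow(cohort))))
  signal + rnorm(nrow(cohort), 0, eps_sd)
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper chaining [generate_cohort()], [generate_predictors()]
#' and [generate_memory()] under one seed, returning the pieces plus an
#' [observation_set()] ready for [fit_svc()].
#'
#' @param n_total cohort size (groups scaled from the 51/54/46 default).
#' @param scenario generating trajectories.
#' @param noise_sd,eps_sd generator noise levels (see the individual
#'   generators).
#' @param seed integer seed; the three stages use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return list with `cohort`, `predictors`, `memory_z`, `scenario`, `obs`.
#' @export
simulate_svc_dataset <- function(n_total = 151L,
                                 scenario = paper_trajectory_scenario(),
                                 noise_sd = 1, eps_sd = 0.5, seed = 1L) {
  seed <- as.integer(seed)
  cohort <- generate_cohort(default_group_specs(n_total), seed = seed)
  predictors <- generate_predictors(cohort, scenario, noise_sd = noise_sd,
                                    seed = seed + 1L)
  y <- generate_memory(cohort, predictors, scenario, eps_sd = eps_sd,
                       seed = seed + 2L)
  cohort$memory_z <- y
  obs <- observation_set(y = y, t = cohort$severity,
                         X = as.matrix(predictors),
                         predictor_names = colnames(predictors))
  list(cohort = cohort, predictors = predictors, memory_z = y,
       scenario = scenario, obs = obs)
}
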