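#' Specification of one diagnostic group
#'
#' Captures the sampling rule for one diagnostic group's CDR-SB severity:
#' a truncated normal on `severity_bounds`, rounded to the instrument's 0.5
#' granularity.  Healthy controls have severity identically 0 by diagnosis.
#'
#' @param label one of `"HC"`, `"aMCI"`, `"AD"`.
#' @param n number of subjects (> 0).
#' @param severity_mean,severity_sd truncated-normal location/scale in CDR-SB
#'   units (the *untruncated* parameters).
#' @param severity_bounds closed-open interval `[lo, hi)` for aMCI, closed
#'   `[lo, hi]` for AD; ignored for HC (always exactly 0).
#' @param upper_open logical; `TRUE` means the upper bound is excluded
#'   (aMCI diagnostic rule CDR-SB < 4).
#' @return list of class `group_spec`.
#' @export
group_spec <- function(label, n, severity_mean, severity_sd,
                       severity_bounds, upper_open = FALSE) {
  label <- match.arg(label, c("HC", "aMCI", "AD"))
  n <- as.integer(n)
  if (n <= 0L) stop("group '", label, "': n must be > 0")
  if (severity_sd < 0) stop("group '", label, "': severity_sd must be >= 0")
  severity_bounds <- as.numeric(severity_bounds)
  if (length(severity_bounds) != 2L || severity_bounds[2] < severity_bounds[1]) {
    stop("group '", label, "': invalid severity bounds [",
         severity_bounds[1], ", ", severity_bounds[2], "]")
  }
  structure(list(label = label, n = n, severity_mean = severity_mean,
                 severity_sd = severity_sd, severity_bounds = severity_bounds,
                 upper_open = isTRUE(upper_open)),
            class = "group_spec")
}

# Table-1-style demographic frequencies/means per group, used by the cohort
# generator.  Age/education are mean (sd) in years; gender is P(female),
# handedness P(left), ethnicity P(Chinese).
.group_demographics <- list(
  HC   = list(age = c(72.0, 4.1), education = c(8.8, 4.6),
              p_female = 35 / 51, p_left = 3 / 51, p_chinese = 43 / 51),
  aMCI = list(age = c(73.5, 7.9), education = c(6.8, 5.1),
              p_female = 31 / 54, p_left = 3 / 54, p_chinese = 47 / 54),
  AD   = list(age = c(75.2, 7.9), education = c(5.0, 4.7),
              p_female = 31 / 46, p_left = 1 / 46, p_chinese = 38 / 46)
)

#' Default three-group specification (HC / aMCI / AD)
#'
#' The default cohort reproduces the published group structure: 151 subjects
#' split 51/54/46 with CDR-SB 0 (0), 0.8 (0.8) and 6.7 (2.8), and the
#' diagnostic bounds HC = 0, aMCI in \[0, 4), AD in \[4, 18\].  For other
#' totals the groups are scaled proportionally (largest-remainder rounding).
#'
#' @param n_total total cohort size.
#' @return list of three [group_spec()] objects.
#' @export
default_group_specs <- function(n_total = 151L) {
  base_n <- c(HC = 51, aMCI = 54, AD = 46)
  if (n_total == 151L) {
    n <- base_n
  } else {
    raw <- base_n / sum(base_n) * n_total
    n <- floor(raw)
    rem <- n_total - sum(n)
    if (rem > 0) {
      bump <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
      n[bump] <- n[bump] + 1
    }
    n <- pmax(n, 1)
  }
  list(
    group_spec("HC",   n[["HC"]],   0,   0,   c(0, 0)),
    group_spec("aMCI", n[["aMCI"]], 0.8, 0.8, c(0, 4),  upper_open = TRUE),
    group_spec("AD",   n[["AD"]],   6.7, 2.8, c(4, 18))
  )
}

# Inverse-CDF sampler for a truncated normal on [lo, hi].
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Draw CDR-SB severities for one group
#'
#' Truncated-normal draw, rounded to the nearest 0.5 (the CDR-SB step) and
#' clipped back into the diagnostic bounds; an open upper bound maps rounded
#' values at the bound down one step (so aMCI never reaches 4.0).
#'
#' @param spec a [group_spec()].
#' @param n number of draws (defaults to `spec$n`).
#' @param seed optional integer seed.
#' @return numeric vector of severities on the 0.5 grid.
#' @export
sample_severity <- function(spec, n = spec$n, seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  if (!is.null(seed)) set.seed(seed)
  b <- spec$severity_bounds
  if (spec$label == "HC" || b[2] == b[1]) return(rep(b[1], n))
  x <- .rtruncnorm(n, spec$severity_mean, spec$severity_sd, b[1], b[2])
  x <- round(x * 2) / 2
  if (spec$upper_open) x <- pmin(x, b[2] - 0.5)
  pmin(pmax(x, b[1]), b[2])
}

#' Exact mean of a group's severity generator
#'
#' The sampled severity is a rounded truncated normal supported on the 0.5
#' grid; its exact mean follows from normal CDF differences over rounding
#' cells.  Used by calibration tests as the analytic reference.
#'
#' @param spec a [group_spec()].
#' @return the exact expectation of [sample_severity()] draws.
#' @export
severity_generator_mean <- function(spec) {
  b <- spec$severity_bounds
  if (spec$label == "HC" || b[2] == b[1]) return(b[1])
  hi_val <- if (spec$upper_open) b[2] - 0.5 else b[2]
  vals <- seq(b[1], hi_val, by = 0.5)
  plo <- pnorm(b[1], spec$severity_mean, spec$severity_sd)
  phi <- pnorm(b[2], spec$severity_mean, spec$severity_sd)
  z <- pmax(phi - plo, .Machine$double.eps)
  # rounding cell of grid value v is [v - .25, v + .25), clipped to bounds;
  # the last cell absorbs everything up to the truncation bound
  lo_edge <- pmax(vals - 0.25, b[1])
  hi_edge <- pmin(vals + 0.25, b[2])
  hi_edge[length(hi_edge)] <- b[2]
  p <- (pnorm(hi_edge, spec$severity_mean, spec$severity_sd) -
          pnorm(lo_edge, spec$severity_mean, spec$severity_sd)) / z
  sum(vals * p) / sum(p)
}

#' Generate a synthetic cohort table
#'
#' One row per subject: diagnostic group, CDR-SB severity drawn from the
#' group's truncated-normal rule, and demographics (age, gender, handedness,
#' ethnicity, education) drawn from per-group published frequencies/means.
#' Memory z-scores are added later by [generate_memory()].
#'
#' @param group_specs list of [group_spec()] (default [default_group_specs()]).
#' @param seed integer seed; identical seeds give identical tables.
#' @return `data.frame` of class `cohort_table` with columns `id`, `group`,
#'   `severity`, `age`, `gender` (`"F"`/`"M"`), `handedness` (`"L"`/`"R"`),
#'   `ethnicity` (`"C"`/`"N"`), `education`.
#' @export
generate_cohort <- function(group_specs = default_group_specs(), seed = 1L) {
  stopifnot(all(vapply(group_specs, inherits, logical(1), "group_spec")))
  set.seed(as.integer(seed))
  rows <- lapply(group_specs, function(sp) {
    dem <- .group_demographics[[sp$label]]
    n <- sp$n
    data.frame(
      group = sp$label,
      severity = sample_severity(sp, n),
      age = round(rnorm(n, dem$age[1], dem$age[2]), 1),
      gender = ifelse(runif(n) < dem$p_female, "F", "M"),
      handedness = ifelse(runif(n) < dem$p_left, "L", "R"),
      ethnicity = ifelse(runif(n) < dem$p_chinese, "C", "N"),
      education = pmax(0, round(rnorm(n, dem$education[1], dem$education[2]))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = sprintf("S%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort or predictor table as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_subject_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
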