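# Core value types of the cohort model: the population projection, the
# prevalence and incidence curves, the stage transition matrix, the per-age
# stage split and the yearly disease state. All are light S3 wrappers with
# strict validators; invalid inputs raise conditions of class
# "adburden_schema_error" so callers (and the CLI) can map them to exit codes.

STAGES <- c("mild", "moderate", "severe")
STATES <- c(STAGES, "death")

#' Age cohort labels of a population projection
#'
#' The model uses 96 single-year-of-age cohorts, `0` through `94` plus an
#' aggregated open-ended `95+` cohort.
#'
#' @return Character vector of length 96.
#' @export
age_labels <- function() c(as.character(0:94), "95+")

#' Age cohort labels of the modelled AD population
#'
#' Prevalence, incidence and disease states are defined for ages 65 to 95+,
#' i.e. 31 cohorts.
#'
#' @return Character vector of length 31.
#' @export
ad_age_labels <- function() c(as.character(65:94), "95+")

N_AD_AGES <- 31L

abort_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("adburden_schema_error", "adburden_error")))
}

abort_convergence <- function(msg, ..., data = NULL) {
  cond <- errorCondition(sprintf(msg, ...),
                         class = c("adburden_convergence_error", "adburden_error"))
  cond$data <- data
  stop(cond)
}

abort_calibration <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("adburden_calibration_error", "adburden_error")))
}

check_finite_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_schema("%s must be finite and non-missing", what)
  }
  if (any(x < 0)) abort_schema("%s must be non-negative", what)
  invisible(x)
}

#' Regional population projection
#'
#' A matrix of projected person counts for one region, with 96 single-year
#' age cohorts (`0`..`94`, `95+`) in rows and contiguous calendar years in
#' columns.
#'
#' @param counts Numeric matrix, 96 rows by `length(years)` columns, all
#'   entries finite and non-negative.
#' @param years Integer vector of contiguous calendar years (columns).
#' @param region Region identifier (single string).
#' @return An object of class `population_projection` with fields `region`,
#'   `years` and `counts` (dimnames set to age labels and years).
#' @export
population_projection <- function(counts, years, region = "region") {
  counts <- as.matrix(counts)
  years <- as.integer(years)
  if (length(region) != 1L || is.na(region)) abort_schema("region must be a single string")
  if (nrow(counts) != 96L) {
    abort_schema("projection must have 96 age cohorts (0-94, 95+), got %d", nrow(counts))
  }
  if (ncol(counts) != length(years)) {
    abort_schema("projection has %d year columns but %d years", ncol(counts), length(years))
  }
  if (length(years) < 2L || any(diff(years) != 1L)) {
    abort_schema("projection years must be contiguous calendar years")
  }
  check_finite_nonneg(counts, "projection counts")
  dimnames(counts) <- list(age = age_labels(), year = as.character(years))
  structure(list(region = as.character(region), years = years, counts = counts),
            class = "population_projection")
}

#' @export
print.population_projection <- function(x, ...) {
  cat(sprintf("population_projection: region '%s', %d cohorts (0-95+), years %d-%d\n",
              x$region, nrow(x$counts), min(x$years), max(x$years)))
  cat(sprintf("  total population %d: %.0f; %d: %.0f\n",
              min(x$years), sum(x$counts[, 1L]),
              max(x$years), sum(x$counts[, ncol(x$counts)])))
  invisible(x)
}

proj_col <- function(projection, year) {
  j <- match(as.character(year), colnames(projection$counts))
  if (is.na(j)) abort_schema("year %s not covered by the population projection", year)
  projection$counts[, j]
}

# Projected counts for the 31 AD ages (65..95+) in a given year.
proj_ad_col <- function(projection, year) {
  proj_col(projection, year)[66:96]
}

#' Age-specific AD prevalence curve
#'
#' Proportion of each age cohort (65..95+) living with AD.
#'
#' @param values Numeric vector of 31 proportions in `[0, 1]` for ages
#'   65..95+.
#' @return An object of class `prevalence_curve` (a named numeric vector).
#' @export
prevalence_curve <- function(values) {
  values <- as.numeric(values)
  if (length(values) != N_AD_AGES) {
    abort_schema("prevalence curve must have 31 values (ages 65-95+), got %d", length(values))
  }
  if (anyNA(values) || any(!is.finite(values))) abort_schema("prevalence values must be finite")
  if (any(values < 0 | values > 1)) abort_schema("prevalence values must lie in [0, 1]")
  structure(stats::setNames(values, ad_age_labels()), class = "prevalence_curve")
}

#' @export
print.prevalence_curve <- function(x, ...) {
  cat(sprintf("prevalence_curve: ages 65-95+, range [%.4f, %.4f]\n",
              min(x), max(x)))
  invisible(x)
}

#' Stage transition probability matrix
#'
#' One-year transition probabilities over the ordered states Mild, Moderate,
#' Severe, Death. Rows must sum to 1 and Death is absorbing.
#'
#' @param probabilities 4x4 numeric matrix; entry `(i, j)` is the one-year
#'   probability of moving from state `i` to state `j`.
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(probabilities, tol = 1e-9) {
  p <- as.matrix(probabilities)
  if (!all(dim(p) == c(4L, 4L))) abort_schema("transition matrix must be 4x4")
  if (anyNA(p) || any(!is.finite(p))) abort_schema("transition probabilities must be finite")
  if (any(p < 0 | p > 1)) abort_schema("transition probabilities must lie in [0, 1]")
  rs <- rowSums(p)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    abort_schema("transition matrix row '%s' sums to %.6f, not 1",
                 STATES[bad[1L]], rs[bad[1L]])
  }
  if (any(abs(p[4L, ] - c(0, 0, 0, 1)) > tol)) {
    abort_schema("death row must be absorbing: (0, 0, 0, 1)")
  }
  p[4L, ] <- c(0, 0, 0, 1)
  dimnames(p) <- list(from = STATES, to = STATES)
  structure(p, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix (one-year stage transition probabilities):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Per-age stage distribution
#'
#' Proportions of the AD population in the Mild, Moderate and Severe stages,
#' per age cohort 65..95+. A single length-3 vector is recycled across ages.
#'
#' @param proportions Either a length-3 numeric vector or a 31x3 matrix;
#'   each row must be in `[0, 1]` and sum to 1.
#' @return An object of class `stage_distribution` (31x3 matrix).
#' @export
stage_distribution <- function(proportions) {
  if (is.null(dim(proportions))) {
    if (length(proportions) != 3L) {
      abort_schema("stage proportions must have 3 values (mild, moderate, severe)")
    }
    proportions <- matrix(as.numeric(proportions), nrow = N_AD_AGES, ncol = 3L,
                          byrow = TRUE)
  }
  p <- as.matrix(proportions)
  if (!all(dim(p) == c(N_AD_AGES, 3L))) {
    abort_schema("stage distribution must be 31 ages x 3 stages")
  }
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort_schema("stage proportions must be finite and in [0, 1]")
  }
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-9)) {
    abort_schema("stage proportions must sum to 1 per age (worst deviation %.2e)",
                 max(abs(rs - 1)))
  }
  dimnames(p) <- list(age = ad_age_labels(), stage = STAGES)
  structure(p, class = c("stage_distribution", "matrix", "array"))
}

#' Aggregate a per-age stage distribution into a single 3-value split
#'
#' Count-weighted mean of the per-age proportions, using per-age AD head
#' counts as weights.
#'
#' @param x A `stage_distribution`.
#' @param weights Numeric vector of 31 per-age AD counts.
#' @return Named length-3 numeric vector summing to 1.
#' @export
aggregate_stage_distribution <- function(x, weights) {
  stopifnot(inherits(x, "stage_distribution"), length(weights) == N_AD_AGES)
  check_finite_nonneg(weights, "weights")
  if (sum(weights) <= 0) abort_schema("weights must have positive total")
  agg <- colSums(unclass(x) * weights) / sum(weights)
  agg / sum(agg)
}

#' @export
print.stage_distribution <- function(x, ...) {
  cat("stage_distribution (per-age proportions, ages 65-95+):\n")
  cat(sprintf("  unweighted mean split: mild %.3f, moderate %.3f, severe %.3f\n",
              mean(x[, 1L]), mean(x[, 2L]), mean(x[, 3L])))
  invisible(x)
}

#' Yearly disease state of the modelled population
#'
#' Person counts by age (65..95+) and stage, plus the disease-free residual,
#' for one calendar year.
#'
#' @param year Calendar year.
#' @param ad_counts 31x3 numeric matrix of AD person counts by age and stage.
#' @param healthy Numeric vector of 31 disease-free counts by age.
#' @return An object of class `ad_state`.
#' @export
ad_state <- function(year, ad_counts, healthy) {
  ad_counts <- as.matrix(ad_counts)
  if (!all(dim(ad_counts) == c(N_AD_AGES, 3L))) {
    abort_schema("ad_counts must be 31 ages x 3 stages")
  }
  if (anyNA(ad_counts) || any(!is.finite(ad_counts))) abort_schema("ad_counts must be finite")
  if (any(ad_counts < -1e-9)) {
    abort_schema("negative AD count (%.3e) beyond tolerance", min(ad_counts))
  }
  ad_counts[ad_counts < 0] <- 0
  if (length(healthy) != N_AD_AGES) abort_schema("healthy counts must cover 31 ages")
  if (anyNA(healthy) || any(!is.finite(healthy))) abort_schema("healthy counts must be finite")
  if (any(healthy < -1e-9)) abort_schema("negative healthy count beyond tolerance")
  healthy <- pmax(healthy, 0)
  dimnames(ad_counts) <- list(age = ad_age_labels(), stage = STAGES)
  structure(list(year = as.integer(year), ad_counts = ad_counts,
                 healthy = stats::setNames(as.numeric(healthy), ad_age_labels())),
            class = "ad_state")
}

#' @export
print.ad_state <- function(x, ...) {
  tot <- colSums(x$ad_counts)
  cat(sprintf("ad_state %d: AD total %.1f (mild %.1f, moderate %.1f, severe %.1f)\n",
              x$year, sum(tot), tot[1L], tot[2L], tot[3L]))
  invisible(x)
}

#' Total AD count of a yearly state
#'
#' @param state An `ad_state`.
#' @return Total number of people with AD across ages and stages.
#' @export
ad_total <- function(state) {
  stopifnot(inherits(state, "ad_state"))
  sum(state$ad_counts)
}

#' Scenario configuration
#'
#' Bundles the inputs and numerical settings of one projection run. The
#' component objects may be supplied inline (as constructed objects) or read
#' from files with [read_scenario()].
#'
#' @param region Region identifier.
#' @param start_year,end_year First and last simulated calendar years
#'   (`start_year < end_year`; both within the projection's years, with
#'   `start_year` at least one year after the first projection year so that
#'   the 64-year-old feeder cohort exists).
#' @param projection A [population_projection()].
#' @param prevalence A [prevalence_curve()].
#' @param transitions A [transition_matrix()].
#' @param calibration_tol Relative tolerance used when verifying that the
#'   calibrated run reproduces the prevalence target (default `1e-6`).
#' @param limit_tol Sup-norm convergence tolerance of the limit-distribution
#'   initialisation (default `1e-8`).
#' @param max_iter Maximum limit-distribution iterations (default 200).
#' @param base_year Base year of the cost growth index (default `start_year`).
#' @param seed Optional seed recorded for provenance (generation only; the
#'   simulation itself is deterministic).
#' @param medical_costs,treated_shares,residential,nonresidential Optional
#'   cost-side inputs (see [medical_cost_table()], [treated_share_table()],
#'   [service_inventory()]).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(region, start_year, end_year, projection,
                            prevalence, transitions,
                            calibration_tol = 1e-6, limit_tol = 1e-8,
                            max_iter = 200L, base_year = start_year,
                            seed = NULL, medical_costs = NULL,
                            treated_shares = NULL, residential = NULL,
                            nonresidential = NULL) {
  start_year <- as.integer(start_year); end_year <- as.integer(end_year)
  if (start_year >= end_year) abort_schema("start_year must precede end_year")
  if (calibration_tol <= 0 || limit_tol <= 0) abort_schema("tolerances must be positive")
  if (max_iter < 1L) abort_schema("max_iter must be at least 1")
  stopifnot(inherits(projection, "population_projection"),
            inherits(prevalence, "prevalence_curve"),
            inherits(transitions, "transition_matrix"))
  yrs <- projection$years
  if (start_year - 1L < min(yrs) || end_year > max(yrs)) {
    abort_schema("simulated years %d-%d (plus the preceding feeder year) must lie within the projection years %d-%d",
                 start_year, end_year, min(yrs), max(yrs))
  }
  structure(list(region = as.character(region), start_year = start_year,
                 end_year = end_year, projection = projection,
                 prevalence = prevalence, transitions = transitions,
                 calibration_tol = calibration_tol, limit_tol = limit_tol,
                 max_iter = as.integer(max_iter),
                 base_year = as.integer(base_year), seed = seed,
                 medical_costs = medical_costs, treated_shares = treated_shares,
                 residential = residential, nonresidential = nonresidential),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: region '%s', simulated years %d-%d\n",
              x$region, x$start_year, x$end_year))
  cat(sprintf("  calibration tol %.1e, limit tol %.1e, max %d iterations\n",
              x$calibration_tol, x$limit_tol, x$max_iter))
  invisible(x)
}
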