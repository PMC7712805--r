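# Age-structured multi-state cohort engine. One simulated year applies, in
# this fixed order: (1) age every AD cohort by one year, the open 95+ cohort
# absorbing; (2) apply the stage transition matrix as expected counts, which
# removes deaths; (3) take the disease-free population as the residual of the
# official projection, floored at 0; (4) add incident Mild cases drawn from
# the previous year's disease-free pool. Incidence values are indexed by
# ATTAINED age a in 65..95+: incidence[a] is the probability that a person
# who was disease-free at age a-1 in year t is a new Mild case at age a in
# year t+1 (for attained age 65 the feeder pool is the disease-free
# 64-year-olds of the projection; for 95+ it is the pool at ages 94 and 95+).
# This convention makes prevalence calibration a closed-form one-step solve
# covering every modelled age.

# Shift AD counts one age up; row 1 = age 65 empties, row 31 = 95+ absorbs.
age_ad_counts <- function(ad) {
  aged <- matrix(0, N_AD_AGES, 3L, dimnames = dimnames(ad))
  aged[2:30, ] <- ad[1:29, ]
  aged[31L, ] <- ad[30L, ] + ad[31L, ]
  aged
}

# Expected survivors by stage after ageing + one transition cycle, and the
# expected deaths, for the step from state$year to state$year + 1.
step_survivors <- function(state, transitions) {
  aged <- age_ad_counts(state$ad_counts)
  p <- unclass(transitions)
  list(survivors = aged %*% p[1:3, 1:3], deaths = as.numeric(aged %*% p[1:3, 4L]))
}

# Disease-free feeder pool by attained age for the step t -> t+1.
origin_healthy_pool <- function(state, projection) {
  pool <- numeric(N_AD_AGES)
  pool[1L] <- proj_col(projection, state$year)[["64"]]  # no AD below 65
  pool[2:30] <- state$healthy[1:29]
  pool[31L] <- state$healthy[30L] + state$healthy[31L]
  pool
}

incidence_for_year <- function(incidence, year) {
  if (inherits(incidence, "incidence_set")) {
    i <- match(year, incidence$origin_years)
    if (is.na(i)) {
      abort_calibration("no incidence available for year %d; run derive_incidence() over the full horizon",
                        year)
    }
    return(incidence$values[i, ])
  }
  inc <- as.numeric(incidence)
  if (length(inc) != N_AD_AGES) {
    abort_schema("incidence must have 31 values (attained ages 65-95+)")
  }
  if (anyNA(inc) || any(inc < 0 | inc > 1)) {
    abort_schema("incidence values must lie in [0, 1]")
  }
  inc
}

#' Advance the disease state by one simulated year
#'
#' Applies the fixed yearly update order (ageing, stage transitions, residual
#' disease-free counts, incident Mild cases) and returns the state for the
#' next calendar year. Deterministic expected-count propagation: counts are
#' multiplied by probabilities, nothing is sampled.
#'
#' @param state Current [ad_state()].
#' @param projection The [population_projection()] covering `state$year + 1`.
#' @param incidence Either an `incidence_set` from [derive_incidence()] or a
#'   numeric vector of 31 attained-age incidence probabilities for this step.
#' @param transitions A [transition_matrix()].
#' @return The [ad_state()] for `state$year + 1`, with attributes `deaths`
#'   (expected AD deaths during the step) and `new_cases` (incident Mild
#'   cases by attained age).
#' @export
simulate_step <- function(state, projection, incidence, transitions) {
  stopifnot(inherits(state, "ad_state"),
            inherits(projection, "population_projection"),
            inherits(transitions, "transition_matrix"))
  year_next <- state$year + 1L
  proj_next <- proj_ad_col(projection, year_next)
  inc <- incidence_for_year(incidence, state$year)

  s <- step_survivors(state, transitions)
  pool <- origin_healthy_pool(state, projection)
  # incident cases cannot exceed the projection's headroom at the attained age
  headroom <- pmax(0, proj_next - rowSums(s$survivors))
  new_cases <- pmin(pool * inc, headroom)
  ad_next <- s$survivors
  ad_next[, 1L] <- ad_next[, 1L] + new_cases
  if (min(ad_next) < -1e-9) {
    abort_schema("internal consistency: negative AD count (%.3e) in year %d",
                 min(ad_next), year_next)
  }
  healthy_next <- pmax(0, proj_next - rowSums(ad_next))
  out <- ad_state(year_next, ad_next, healthy_next)
  attr(out, "deaths") <- s$deaths
  attr(out, "new_cases") <- new_cases
  out
}

# Initial state: prevalence x projection at the start year, split across
# stages by the per-age stage distribution.
initial_ad_state <- function(projection, prevalence, props, year) {
  n <- proj_ad_col(projection, year)
  total_ad <- as.numeric(prevalence) * n
  ad <- unclass(props) * total_ad
  ad_state(year, ad, pmax(0, n - total_ad))
}

# Core calibrated run: solves the one-step incidence so that the AD count at
# each attained age equals prevalence(age) x projection(age, year + 1), then
# advances the state with exactly the simulate_step arithmetic. Returns the
# incidence set and the trajectory it generates.
calibrate_run <- function(projection, prevalence, transitions, props,
                          start_year, end_year) {
  years <- start_year:end_year
  state <- initial_ad_state(projection, prevalence, props, start_year)
  trajectory <- vector("list", length(years))
  trajectory[[1L]] <- state
  values <- matrix(0, length(years) - 1L, N_AD_AGES,
                   dimnames = list(year = as.character(years[-length(years)]),
                                   age = ad_age_labels()))
  clamps <- list(); infeasible <- list()
  for (k in seq_len(length(years) - 1L)) {
    year_next <- years[k + 1L]
    proj_next <- proj_ad_col(projection, year_next)
    target <- as.numeric(prevalence) * proj_next
    s <- step_survivors(state, transitions)
    surv_tot <- rowSums(s$survivors)
    required <- target - surv_tot
    pool <- origin_healthy_pool(state, projection)

    inc <- ifelse(pool > 0, required / pool, 0)
    bad_pool <- pool <= 0 & required > 1e-12
    if (any(bad_pool)) {
      inc[bad_pool] <- 1
      infeasible[[length(infeasible) + 1L]] <- data.frame(
        year = year_next, age = ad_age_labels()[bad_pool],
        required = required[bad_pool])
    }
    clamped <- pmin(1, pmax(0, inc))
    hit <- which(abs(clamped - inc) > 0)
    if (length(hit)) {
      clamps[[length(clamps) + 1L]] <- data.frame(
        year = year_next, age = ad_age_labels()[hit],
        raw = inc[hit], clamped = clamped[hit])
    }
    values[k, ] <- clamped

    new_cases <- pmin(pool * clamped, pmax(0, proj_next - surv_tot))
    ad_next <- s$survivors
    ad_next[, 1L] <- ad_next[, 1L] + new_cases
    state <- ad_state(year_next, ad_next, pmax(0, proj_next - rowSums(ad_next)))
    trajectory[[k + 1L]] <- state
  }
  bind_or_empty <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  incidence <- structure(
    list(origin_years = years[-length(years)], values = values,
         clamps = bind_or_empty(clamps, data.frame(year = integer(), age = character(),
                                                   raw = numeric(), clamped = numeric())),
         infeasible = bind_or_empty(infeasible, data.frame(year = integer(), age = character(),
                                                           required = numeric()))),
    class = "incidence_set")
  list(incidence = incidence, trajectory = trajectory)
}

#' Back-calculate incidence from a prevalence target
#'
#' Runs the baseline calibration: starting from an initial state built as
#' prevalence times projection at the start year, it solves — one step at a
#' time, in closed form — for the attained-age incidence that makes the AD
#' count at every age equal `prevalence(age) * projection(age, year + 1)` in
#' every simulated year. The one-step target is linear in incidence, so the
#' solve is the ratio of required new cases to the disease-free feeder pool,
#' clamped to `[0, 1]`; clamping events are recorded.
#'
#' @param projection A [population_projection()].
#' @param prevalence A [prevalence_curve()] (the calibration target).
#' @param transitions A [transition_matrix()].
#' @param props Initial per-age [stage_distribution()]; defaults to a uniform
#'   split, but for a full run use the converged limit distribution from
#'   [init_stage_proportions()] (the survivor mix, and hence the required
#'   incidence, depends on the stage split through stage-specific mortality).
#' @param start_year,end_year Simulated horizon.
#' @return An object of class `incidence_set`: per-year attained-age
#'   incidence values (`$values`, years-1 by 31), the years they apply to
#'   (`$origin_years`), and data frames `$clamps` and `$infeasible` logging
#'   calibration edge cases. Infeasible cells (empty feeder pool with new
#'   cases still required) are set to incidence 1 and flagged.
#' @export
derive_incidence <- function(projection, prevalence, transitions,
                             props = stage_distribution(rep(1 / 3, 3)),
                             start_year = min(projection$years) + 1L,
                             end_year = max(projection$years)) {
  stopifnot(inherits(projection, "population_projection"),
            inherits(prevalence, "prevalence_curve"),
            inherits(transitions, "transition_matrix"))
  props <- stage_distribution(props)
  calibrate_run(projection, prevalence, transitions, props,
                as.integer(start_year), as.integer(end_year))$incidence
}

#' @export
print.incidence_set <- function(x, ...) {
  cat(sprintf("incidence_set: %d yearly curves (origin years %d-%d), ages 65-95+\n",
              nrow(x$values), min(x$origin_years), max(x$origin_years)))
  cat(sprintf("  %d clamped and %d infeasible calibration cells\n",
              nrow(x$clamps), nrow(x$infeasible)))
  invisible(x)
}

trajectory_props <- function(trajectory, fallback) {
  final <- trajectory[[length(trajectory)]]$ad_counts
  tot <- rowSums(final)
  p <- unclass(fallback)
  ok <- tot > 0
  p[ok, ] <- final[ok, , drop = FALSE] / tot[ok]
  stage_distribution(p / rowSums(p))
}

#' Limit-distribution initialisation of the stage split
#'
#' Determines the per-age proportions of Mild, Moderate and Severe used to
#' split the AD population at model initialisation. The calibrated simulation
#' is run repeatedly, each time feeding the end-state per-age stage
#' proportions back in as the initial split, until successive runs change by
#' less than `tol` in sup-norm — i.e. the split is the limit distribution of
#' the stage process under the model's own dynamics.
#'
#' @param transitions A [transition_matrix()].
#' @param projection A [population_projection()].
#' @param prevalence A [prevalence_curve()].
#' @param start_year,end_year Simulated horizon used for the convergence runs.
#' @param tol Sup-norm convergence tolerance (default `1e-8`).
#' @param max_iter Maximum number of feedback runs (default 200).
#' @param init Starting split: `"uniform"` (default) or `"mild"` (all Mild),
#'   or a [stage_distribution()].
#' @return Converged [stage_distribution()] with attributes `iterations` and
#'   `delta` (final sup-norm change). Ages that carry no AD population keep
#'   their previous split. Raises a condition of class
#'   `adburden_convergence_error` (carrying the last two iterates in
#'   `$data`) after `max_iter` runs without convergence.
#' @export
init_stage_proportions <- function(transitions, projection, prevalence,
                                   start_year = min(projection$years) + 1L,
                                   end_year = max(projection$years),
                                   tol = 1e-8, max_iter = 200L,
                                   init = c("uniform", "mild")) {
  if (tol <= 0) abort_schema("tolerance must be positive")
  props <- if (inherits(init, "stage_distribution")) {
    init
  } else {
    switch(match.arg(init),
           uniform = stage_distribution(rep(1 / 3, 3)),
           mild = stage_distribution(c(1, 0, 0)))
  }
  start_year <- as.integer(start_year); end_year <- as.integer(end_year)
  for (iter in seq_len(max_iter)) {
    run <- calibrate_run(projection, prevalence, transitions, props,
                         start_year, end_year)
    nxt <- trajectory_props(run$trajectory, props)
    delta <- max(abs(unclass(nxt) - unclass(props)))
    if (delta < tol) {
      attr(nxt, "iterations") <- iter
      attr(nxt, "delta") <- delta
      return(nxt)
    }
    prev <- props
    props <- nxt
  }
  abort_convergence(
    "stage proportions did not converge within %d runs (last change %.3e)",
    max_iter, delta, data = list(previous = prev, last = props))
}

#' Run the full calibrated population projection
#'
#' Orchestrates the model: converges the limit-distribution stage split,
#' back-calculates incidence from the prevalence target, then advances the
#' state year by year with [simulate_step()]. Deterministic given its inputs.
#'
#' @param config A [scenario_config()].
#' @return An object of class `ad_trajectory`: a list of [ad_state()] objects
#'   (one per simulated year) with attributes `region`, `incidence` (the
#'   `incidence_set` used), `stage_props` (converged initial split) and
#'   `config`.
#' @export
run_projection <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  props <- init_stage_proportions(config$transitions, config$projection,
                                  config$prevalence,
                                  start_year = config$start_year,
                                  end_year = config$end_year,
                                  tol = config$limit_tol,
                                  max_iter = config$max_iter)
  incidence <- derive_incidence(config$projection, config$prevalence,
                                config$transitions, props = props,
                                start_year = config$start_year,
                                end_year = config$end_year)
  state <- initial_ad_state(config$projection, config$prevalence, props,
                            config$start_year)
  trajectory <- vector("list", config$end_year - config$start_year + 1L)
  trajectory[[1L]] <- state
  for (k in seq_len(length(trajectory) - 1L)) {
    state <- simulate_step(state, config$projection, incidence,
                           config$transitions)
    trajectory[[k + 1L]] <- state
  }
  structure(trajectory, class = "ad_trajectory", region = config$region,
            incidence = incidence, stage_props = props, config = config)
}

#' @export
print.ad_trajectory <- function(x, ...) {
  yrs <- vapply(x, function(s) s$year, integer(1))
  tot <- vapply(x, ad_total, numeric(1))
  cat(sprintf("ad_trajectory: region '%s', years %d-%d\n",
              attr(x, "region") %||% "?", min(yrs), max(yrs)))
  cat(sprintf("  AD population %d: %.1f -> %d: %.1f (factor %.2f)\n",
              min(yrs), tot[1L], max(yrs), tot[length(tot)],
              tot[length(tot)] / max(tot[1L], .Machine$double.eps)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format view of a projection trajectory
#'
#' @param x An `ad_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `region`, `year`, `age`, `stage`, `count`.
#' @export
as.data.frame.ad_trajectory <- function(x, ...) {
  region <- attr(x, "region") %||% "region"
  do.call(rbind, lapply(x, function(s) {
    data.frame(region = region, year = s$year,
               age = rep(ad_age_labels(), times = 3L),
               stage = rep(STAGES, each = N_AD_AGES),
               count = as.numeric(s$ad_counts), row.names = NULL)
  }))
}

#' Per-year summary of a projection trajectory
#'
#' @param trajectory An `ad_trajectory`.
#' @return Data frame with columns `region`, `year`, `ad_total`, `mild`,
#'   `moderate`, `severe`.
#' @export
trajectory_summary <- function(trajectory) {
  region <- attr(trajectory, "region") %||% "region"
  do.call(rbind, lapply(trajectory, function(s) {
    tot <- colSums(s$ad_counts)
    data.frame(region = region, year = s$year, ad_total = sum(tot),
               mild = tot[[1L]], moderate = tot[[2L]], severe = tot[[3L]],
               row.names = NULL)
  }))
}

# AD counts by stage x age band for one state (cost-model view).
counts_by_band <- function(state, bands) {
  ages <- c(65:94, 95L)
  band_of <- cut(ages, breaks = c(64, 69, 79, 89, Inf), labels = bands)
  t(apply(state$ad_counts, 2L, function(col) {
    tapply(col, band_of, sum)
  }))  # stages x bands
}
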