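# Shared fixtures, all built in code.

# Projection with every cohort held at `value` in every year (a stationary
# population), convenient for hand-computed step examples.
flat_projection <- function(years, value = 1000, region = "toy") {
  population_projection(matrix(value, 96L, length(years)), years, region)
}

# Empty disease state (no AD) consistent with a flat projection.
empty_state <- function(year, value = 1000) {
  ad_state(year, matrix(0, 31L, 3L), rep(value, 31L))
}

# Progressive matrix from explicit row probabilities.
toy_transitions <- function(mild = c(0.6, 0.3, 0, 0.1),
                            moderate = c(0, 0.5, 0.3, 0.2),
                            severe = c(0, 0, 0.6, 0.4)) {
  transition_matrix(rbind(mild, moderate, severe, c(0, 0, 0, 1)))
}

identity_transitions <- function() {
  transition_matrix(diag(4))
}

# Wrap manually built states as a trajectory.
as_trajectory <- function(states, region = "toy") {
  structure(states, class = "ad_trajectory", region = region)
}

# A state with given per-stage totals placed at age 70 (row 6).
state_with_totals <- function(year, mild = 0, moderate = 0, severe = 0,
                              healthy = 1000) {
  ad <- matrix(0, 31L, 3L)
  ad[6L, ] <- c(mild, moderate, severe)
  ad_state(year, ad, rep(healthy, 31L))
}

# Maximum relative deviation of simulated AD totals from the prevalence
# target over a trajectory (the calibration round-trip error).
round_trip_error <- function(trajectory, config) {
  err <- 0
  for (s in trajectory[-1]) {
    target <- as.numeric(config$prevalence) *
      adburden:::proj_ad_col(config$projection, s$year)
    err <- max(err, abs(rowSums(s$ad_counts) - target) / pmax(target, 1e-12))
  }
  err
}

# Stationary distribution of the renewal chain in which deaths are replaced
# by incident Mild cases: brute-force power iteration, independent of the
# cohort engine.
renewal_chain_stationary <- function(transitions) {
  p <- unclass(transitions)
  R <- p[1:3, 1:3]
  R[, 1L] <- R[, 1L] + p[1:3, 4L]
  v <- rep(1 / 3, 3)
  for (i in 1:100000) {
    v2 <- as.numeric(v %*% R)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < 1e-14) break
    v <- v2
  }
  v2
}
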