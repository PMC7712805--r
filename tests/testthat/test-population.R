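# Cohort engine: yearly step, incidence back-calculation, limit-distribution
# initialisation, full projection runs.

test_that("identity transitions and zero incidence shift AD counts one age up", {
  proj <- flat_projection(2019:2022)
  ad <- matrix(runif(31 * 3, 0, 5), 31, 3)
  state <- ad_state(2020, ad, rep(900, 31))
  nxt <- simulate_step(state, proj, rep(0, 31), identity_transitions())
  expect_equal(nxt$year, 2021L)
  expect_equal(unname(nxt$ad_counts[2:30, ]), unname(ad[1:29, ]))
  expect_equal(unname(nxt$ad_counts[31, ]), unname(ad[30, ] + ad[31, ]))
  expect_equal(unname(nxt$ad_counts[1, ]), c(0, 0, 0))
})

test_that("one step applies the expected-count Markov update", {
  proj <- flat_projection(2019:2022, value = 1e6)
  state <- state_with_totals(2020, mild = 100, healthy = 1e6)
  nxt <- simulate_step(state, proj, rep(0, 31),
                       toy_transitions(mild = c(0.6, 0.3, 0, 0.1)))
  # the age-70 cohort is at age 71 (row 7) a year later
  expect_equal(unname(nxt$ad_counts[7, ]), c(60, 30, 0))
  expect_equal(sum(attr(nxt, "deaths")), 10)
  expect_equal(sum(nxt$ad_counts), 90)
})

test_that("incident cases are incidence times the disease-free feeder pool", {
  proj <- flat_projection(2019:2022, value = 1000)
  state <- empty_state(2020, value = 1000)
  inc <- rep(0, 31)
  inc[7] <- 0.02  # attained age 71: pool is the healthy 70-year-olds
  nxt <- simulate_step(state, proj, inc, toy_transitions())
  expect_equal(unname(nxt$ad_counts[7, ]), c(20, 0, 0))
  expect_equal(sum(nxt$ad_counts) - nxt$ad_counts[7, 1], 0)
  expect_equal(unname(nxt$healthy[7]), 980)
})

test_that("a year without derived incidence raises a calibration error", {
  cfg <- generate_scenario(synthetic_spec(seed = 3, n_years = 6))
  inc <- derive_incidence(cfg$projection, cfg$prevalence, cfg$transitions,
                          start_year = cfg$start_year, end_year = cfg$start_year + 2L)
  state <- empty_state(cfg$start_year + 3L, 500)
  expect_error(simulate_step(state, cfg$projection, inc, cfg$transitions),
               class = "adburden_calibration_error")
})

test_that("zero prevalence back-calculates to zero incidence everywhere", {
  proj <- generate_projection(synthetic_spec(seed = 5, n_years = 10))
  inc <- derive_incidence(proj, prevalence_curve(rep(0, 31)), toy_transitions())
  expect_true(all(inc$values == 0))
  expect_equal(nrow(inc$clamps), 0L)
})

test_that("one-step inversion recovers incidence = p * N' / N in a closed cohort", {
  # no deaths, two years, prevalence only at age 71: required cases p * N',
  # feeder pool N, so with constant cohort size the incidence equals p
  p <- 0.05
  proj <- flat_projection(2019:2020, value = 1000)
  prev <- rep(0, 31); prev[7] <- p
  no_death <- transition_matrix(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                      c(0, 0, 1, 0), c(0, 0, 0, 1)))
  inc <- derive_incidence(proj, prevalence_curve(prev), no_death,
                          start_year = 2019, end_year = 2020)
  expect_equal(unname(inc$values[1, 7]), p, tolerance = 1e-12)
  expect_equal(sum(inc$values[1, -7]), 0)
})

test_that("re-simulating with derived incidence reproduces the prevalence target", {
  cfg <- generate_scenario(synthetic_spec(seed = 11, randomize = TRUE))
  traj <- run_projection(cfg)
  inc <- attr(traj, "incidence")
  expect_equal(nrow(inc$clamps), 0L)
  expect_equal(nrow(inc$infeasible), 0L)
  expect_lt(round_trip_error(traj, cfg), 1e-6)
})

test_that("infeasible calibration (empty pool, positive target) is flagged", {
  proj <- flat_projection(2019:2020, value = 1000)
  proj$counts["64", ] <- 0  # nobody can reach age 65 disease-free
  prev <- rep(0, 31); prev[1] <- 0.1
  inc <- derive_incidence(proj, prevalence_curve(prev), toy_transitions(),
                          start_year = 2019, end_year = 2020)
  expect_gt(nrow(inc$infeasible), 0L)
  expect_equal(unname(inc$values[1, 1]), 1)
})

test_that("unreachable stages converge to an all-mild limit split", {
  flush <- transition_matrix(rbind(c(0.8, 0, 0, 0.2), c(0, 0.8, 0, 0.2),
                                   c(0, 0, 0.8, 0.2), c(0, 0, 0, 1)))
  spec <- synthetic_spec(seed = 2, n_years = 60)
  props <- init_stage_proportions(flush, generate_projection(spec),
                                  generate_prevalence(spec))
  expect_true(all(abs(props[, 1] - 1) < 1e-6))
  expect_true(all(props[, 2:3] < 1e-6))
})

test_that("limit split matches the survivor-renewal power-iteration oracle", {
  set.seed(421)
  for (k in 1:3) {
    spec <- synthetic_spec(
      seed = 500 + k, n_years = 261, birth_decline = 0, drift = 0,
      trans_mild = c(progress = runif(1, 0.2, 0.3), death = runif(1, 0.10, 0.16)),
      trans_moderate = c(progress = runif(1, 0.25, 0.35), death = runif(1, 0.20, 0.30)),
      trans_severe = c(death = runif(1, 0.32, 0.45)))
    proj <- generate_projection(spec)
    prev <- generate_prevalence(spec)
    tm <- generate_transition_matrix(spec)
    props <- init_stage_proportions(tm, proj, prev)
    weights <- as.numeric(prev) * proj$counts[66:96, ncol(proj$counts)]
    agg <- aggregate_stage_distribution(props, weights)
    expect_equal(unname(agg), renewal_chain_stationary(tm), tolerance = 1e-6)
  }
})

test_that("the limit split does not depend on the starting split", {
  spec <- synthetic_spec(seed = 9)
  proj <- generate_projection(spec)
  prev <- generate_prevalence(spec)
  tm <- generate_transition_matrix(spec)
  tol <- 1e-8
  a <- init_stage_proportions(tm, proj, prev, tol = tol, init = "uniform")
  b <- init_stage_proportions(tm, proj, prev, tol = tol, init = "mild")
  expect_lt(max(abs(unclass(a) - unclass(b))), 2 * tol)
})

test_that("non-convergence raises an error carrying the last iterates", {
  # a horizon shorter than the 65 -> 95+ passage time keeps the feedback map
  # genuinely dependent on the starting split, so an absurd tolerance cannot
  # be met within two runs
  spec <- synthetic_spec(seed = 9, n_years = 12)
  err <- tryCatch(
    init_stage_proportions(generate_transition_matrix(spec),
                           generate_projection(spec),
                           generate_prevalence(spec),
                           tol = 1e-300, max_iter = 2L),
    adburden_convergence_error = function(e) e)
  expect_s3_class(err, "adburden_convergence_error")
  expect_named(err$data, c("previous", "last"))
})

test_that("zero prevalence propagates to an all-zero trajectory", {
  spec <- synthetic_spec(seed = 4, n_years = 12, prev_base = 0, prev_cap = 0)
  traj <- run_projection(generate_scenario(spec))
  expect_true(all(vapply(traj, ad_total, numeric(1)) == 0))
})

test_that("stationary demography with constant prevalence keeps AD totals constant", {
  spec <- synthetic_spec(seed = 6, n_years = 40, birth_decline = 0, drift = 0)
  cfg <- generate_scenario(spec)
  totals <- vapply(run_projection(cfg), ad_total, numeric(1))
  expect_lt(max(abs(totals / totals[1] - 1)), 1e-6)
})

test_that("AD counts scale linearly with the population projection", {
  g <- 1.37
  spec <- synthetic_spec(seed = 8, n_years = 20)
  cfg <- generate_scenario(spec)
  cfg2 <- cfg
  cfg2$projection <- population_projection(cfg$projection$counts * g,
                                           cfg$projection$years, cfg$region)
  t1 <- vapply(run_projection(cfg), ad_total, numeric(1))
  t2 <- vapply(run_projection(cfg2), ad_total, numeric(1))
  expect_equal(t2, g * t1, tolerance = 1e-6)
})

test_that("a pointwise-larger prevalence target gives larger incidence and counts", {
  spec <- synthetic_spec(seed = 13, n_years = 25)
  proj <- generate_projection(spec)
  prev1 <- generate_prevalence(spec)
  prev2 <- prevalence_curve(as.numeric(prev1) * 1.2)
  tm <- generate_transition_matrix(spec)
  props <- init_stage_proportions(tm, proj, prev1)
  i1 <- derive_incidence(proj, prev1, tm, props = props)
  i2 <- derive_incidence(proj, prev2, tm, props = props)
  expect_equal(nrow(i1$clamps) + nrow(i2$clamps), 0L)
  expect_true(all(i2$values >= i1$values))
})

test_that("each step conserves people: survivors plus incident cases", {
  cfg <- generate_scenario(synthetic_spec(seed = 21, n_years = 15))
  traj <- run_projection(cfg)
  for (k in seq_len(length(traj) - 1L)) {
    nxt <- simulate_step(traj[[k]], cfg$projection, attr(traj, "incidence"),
                         cfg$transitions)
    expect_equal(sum(nxt$ad_counts),
                 ad_total(traj[[k]]) - sum(attr(nxt, "deaths")) +
                   sum(attr(nxt, "new_cases")),
                 tolerance = 1e-12)
    expect_true(all(nxt$ad_counts >= 0))
  }
})

test_that("identical configuration reproduces a bit-identical trajectory", {
  cfg <- generate_scenario(synthetic_spec(seed = 17, n_years = 15))
  t1 <- run_projection(cfg)
  t2 <- run_projection(cfg)
  expect_identical(lapply(t1, function(s) s$ad_counts),
                   lapply(t2, function(s) s$ad_counts))
})

test_that("trajectory views carry the full count set", {
  cfg <- generate_scenario(synthetic_spec(seed = 19, n_years = 8))
  traj <- run_projection(cfg)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), length(traj) * 31L * 3L)
  smry <- trajectory_summary(traj)
  expect_equal(smry$ad_total, vapply(traj, ad_total, numeric(1)))
  expect_equal(smry$ad_total, smry$mild + smry$moderate + smry$severe)
})
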