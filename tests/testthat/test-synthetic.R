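# Synthetic input generator: determinism, closed-form shapes, constructive
# validity, and the full-pipeline smoke property.

test_that("generation is fully reproducible from the seed", {
  s1 <- synthetic_spec(seed = 123, randomize = TRUE)
  s2 <- synthetic_spec(seed = 123, randomize = TRUE)
  expect_identical(generate_projection(s1)$counts, generate_projection(s2)$counts)
  expect_identical(as.numeric(generate_prevalence(s1)),
                   as.numeric(generate_prevalence(s2)))
  c1 <- generate_cost_inputs(s1); c2 <- generate_cost_inputs(s2)
  expect_identical(c1$medical_costs$eur_per_treated_year,
                   c2$medical_costs$eur_per_treated_year)
  expect_identical(c1$residential$beds, c2$residential$beds)
  # and a different seed gives different draws
  c3 <- generate_cost_inputs(synthetic_spec(seed = 124, randomize = TRUE))
  expect_false(identical(c1$medical_costs$eur_per_treated_year,
                         c3$medical_costs$eur_per_treated_year))
})

test_that("zero drift and flat births give a constant projection", {
  spec <- synthetic_spec(seed = 1, n_years = 15, birth_decline = 0, drift = 0)
  proj <- generate_projection(spec)
  expect_true(all(proj$counts == proj$counts[, 1]))
})

test_that("requested 65+ drift is realised over a 30-year horizon", {
  spec <- synthetic_spec(seed = 1, n_years = 31, birth_decline = 0, drift = 0.027)
  proj <- generate_projection(spec)
  old <- colSums(proj$counts[66:96, ])
  realised <- old[31] / old[1]
  expect_lt(abs(realised / 1.027^30 - 1), 0.05)
})

test_that("default demography ages and eventually declines", {
  proj <- generate_projection(synthetic_spec(seed = 2))
  total <- colSums(proj$counts)
  old_share <- colSums(proj$counts[66:96, ]) / total
  expect_gt(old_share[length(old_share)], old_share[1])      # ageing
  expect_lt(total[length(total)], max(total))                # late decline
})

test_that("prevalence follows the capped exponential closed form", {
  spec <- synthetic_spec(seed = 1, prev_base = 0.01, prev_rate = 0.1, prev_cap = 1)
  prev <- generate_prevalence(spec)
  expect_equal(unname(prev[["75"]]), 0.01 * exp(1), tolerance = 1e-12)
  expect_true(all(diff(as.numeric(prev)) >= 0))
  flat <- generate_prevalence(synthetic_spec(seed = 1, prev_base = 0.02,
                                             prev_rate = 0, prev_cap = 1))
  expect_true(all(as.numeric(flat) == 0.02))
})

test_that("generated transition matrices are progressive and valid", {
  spec <- synthetic_spec(seed = 1, trans_mild = c(progress = 0.3, death = 0.1))
  tm <- generate_transition_matrix(spec)
  expect_equal(unname(unclass(tm)[1, ]), c(0.6, 0.3, 0, 0.1))
  expect_true(all(unclass(tm)[lower.tri(unclass(tm))] == 0))  # no reverse moves
  frozen <- generate_transition_matrix(
    synthetic_spec(seed = 1, trans_mild = c(progress = 0, death = 0),
                   trans_moderate = c(progress = 0, death = 0),
                   trans_severe = c(death = 0)))
  expect_equal(unclass(frozen), unclass(identity_transitions()),
               ignore_attr = TRUE)
  expect_error(synthetic_spec(seed = 1, trans_mild = c(progress = 0.7, death = 0.4)),
               class = "adburden_schema_error")
  for (k in 1:5) {
    expect_s3_class(generate_transition_matrix(synthetic_spec(seed = k, randomize = TRUE)),
                    "transition_matrix")
  }
})

test_that("fixture mode returns the packaged regional tables verbatim", {
  khk <- generate_cost_inputs(synthetic_spec(seed = 1), fixture = "khk")
  srh <- khk$residential[khk$residential$service == "Special Regime Homes", ]
  expect_equal(srh$beds, 447)
  expect_equal(srh$ad_share, 0.90)
  expect_equal(srh$eur_per_bed_day, 44.73)
  vys <- generate_cost_inputs(synthetic_spec(seed = 1), fixture = "vys")
  dc <- vys$nonresidential[vys$nonresidential$service == "Daycare Centres", ]
  expect_equal(dc$fte, 117)
  expect_equal(dc$eur_per_fte_month, 2153.85)
})

test_that("any valid spec runs the full pipeline to an additive cost projection", {
  for (seed in c(101, 202)) {
    cfg <- generate_scenario(synthetic_spec(seed = seed, n_years = 20,
                                            randomize = TRUE))
    traj <- run_projection(cfg)
    costs <- project_costs(cfg, traj)
    expect_true(all(costs$by_year$medical_eur >= 0))
    expect_true(all(costs$by_year$nonmedical_eur >= 0))
    expect_equal(costs$by_year$total_eur,
                 costs$by_year$medical_eur + costs$by_year$nonmedical_eur)
    expect_equal(sum(costs$by_stage$total_eur), sum(costs$by_year$total_eur),
                 tolerance = 1e-9)
  }
})
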