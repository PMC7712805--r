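# Cost model: medical unit-cost application, growth index, capacity-based
# non-medical costs, aggregation and per-person figures.

khk_shares <- function(share = 1) {
  treated_share_table(data.frame(region = "khk", stage = c("mild", "moderate", "severe"),
                                 share = share))
}

test_that("a single treated mild patient aged 65-69 costs the summed unit-cost row", {
  ad <- matrix(0, 31, 3); ad[3, 1] <- 1  # one mild person aged 67
  traj <- as_trajectory(list(ad_state(2020, ad, rep(0, 31))), region = "khk")
  med <- medical_costs(traj, fixture_medical_costs("khk"), khk_shares(1))
  expect_equal(unname(med[1, "mild"]),
               435.77 + 31.77 + 72.00 + 0.00 + 243.42 + 442.54)  # 1225.50
  expect_equal(unname(med[1, c("moderate", "severe")]), c(0, 0))
})

test_that("medical costs are zero when nobody is treated and linear in counts", {
  cfg <- generate_scenario(synthetic_spec(seed = 31, n_years = 10))
  traj <- run_projection(cfg)
  zero <- medical_costs(traj, cfg$medical_costs, khk_shares(0))
  expect_true(all(zero == 0))
  med <- medical_costs(traj, cfg$medical_costs, cfg$treated_shares)
  doubled <- as_trajectory(lapply(traj, function(s) {
    ad_state(s$year, s$ad_counts * 2, s$healthy)
  }), region = cfg$region)
  expect_equal(unclass(medical_costs(doubled, cfg$medical_costs, cfg$treated_shares)),
               2 * unclass(med))
  # and linear in the unit costs themselves
  uc2 <- cfg$medical_costs
  uc2$eur_per_treated_year <- uc2$eur_per_treated_year * 2
  expect_equal(unclass(medical_costs(traj, uc2, cfg$treated_shares)),
               2 * unclass(med))
})

test_that("growth index normalises to the base year", {
  states <- list(state_with_totals(2020, mild = 100),
                 state_with_totals(2021, mild = 90, moderate = 60),
                 state_with_totals(2022, severe = 300))
  idx <- growth_index(as_trajectory(states), 2020)
  expect_equal(unname(idx), c(1, 1.5, 3))
  flat <- as_trajectory(list(state_with_totals(2020, mild = 70),
                             state_with_totals(2021, mild = 70)))
  expect_equal(unname(growth_index(flat, 2020)), c(1, 1))
  none <- as_trajectory(list(state_with_totals(2020)))
  expect_error(growth_index(none, 2020), class = "adburden_schema_error")
})

test_that("non-medical costs follow the bed-day / FTE-month conventions", {
  res <- service_inventory(data.frame(region = "toy", service = "home",
                                      beds = 10, ad_share = 1,
                                      eur_per_bed_day = 1), "residential")
  nonres <- service_inventory(data.frame(region = "toy", service = "none",
                                         fte = 0, ad_share = 0.5,
                                         eur_per_fte_month = 100), "nonresidential")
  nm <- nonmedical_costs(res, nonres, c(`2020` = 1))
  expect_equal(unname(nm[1]), 10 * 1 * 1 * 365)
  # a zero-capacity service contributes nothing (KHK non-residential respite care)
  khk <- fixture_services("khk")
  zero_fte <- khk$nonresidential[khk$nonresidential$fte == 0, ]
  expect_equal(nrow(zero_fte), 1L)
  with_it <- nonmedical_costs(khk$residential, khk$nonresidential, c(`2020` = 1))
  without <- nonmedical_costs(khk$residential,
                              khk$nonresidential[khk$nonresidential$fte > 0, ],
                              c(`2020` = 1))
  expect_equal(unname(with_it[1]), unname(without[1]))
  # exactly linear in the growth index
  idx <- c(`2020` = 1, `2021` = 2)
  nm2 <- nonmedical_costs(khk$residential, khk$nonresidential, idx)
  expect_identical(unname(nm2[2]), 2 * unname(nm2[1]))
})

test_that("aggregation is additive and aligns years", {
  med <- c(`2020` = 1e6, `2021` = 2e6)
  nm <- c(`2020` = 5e6, `2021` = 4e6)
  cp <- aggregate_costs(med, nm, region = "toy")
  expect_equal(cp$by_year$total_eur, cp$by_year$medical_eur + cp$by_year$nonmedical_eur)
  expect_error(aggregate_costs(med, nm[1], region = "toy"),
               class = "adburden_schema_error")
  empty <- aggregate_costs(stats::setNames(numeric(0), character(0)),
                           stats::setNames(numeric(0), character(0)), region = "toy")
  expect_equal(nrow(empty$by_year), 0L)
})

test_that("the stage split allocates non-medical costs by head count", {
  ad <- matrix(0, 31, 3); ad[6, ] <- c(60, 30, 10)
  traj <- as_trajectory(list(ad_state(2020, ad, rep(0, 31))), region = "toy")
  med <- matrix(c(100, 200, 300), 1, 3,
                dimnames = list("2020", c("mild", "moderate", "severe")))
  class(med) <- c("medical_cost_stream", "matrix", "array")
  cp <- aggregate_costs(med, c(`2020` = 1000), trajectory = traj)
  expect_equal(cp$by_stage$nonmedical_alloc_eur, c(600, 300, 100))
  expect_equal(cp$by_stage$total_eur, c(700, 500, 400))
  expect_equal(sum(cp$by_stage$total_eur), cp$by_year$total_eur)
})

test_that("per-person costs are stage-resolved for medical, flat for non-medical", {
  ad <- matrix(0, 31, 3); ad[6, ] <- c(100, 80, 40)
  traj <- as_trajectory(list(ad_state(2020, ad, rep(0, 31))), region = "khk")
  med <- matrix(c(359, 298, 1624) * c(100, 80, 40), 1, 3,
                dimnames = list("2020", c("mild", "moderate", "severe")))
  class(med) <- c("medical_cost_stream", "matrix", "array")
  cp <- aggregate_costs(med, c(`2020` = 2330 * 220), trajectory = traj)
  pp <- per_person_costs(cp, 2020)
  expect_equal(pp$medical_eur_pp[pp$stage == "mild"], 359)
  expect_equal(unique(pp$nonmedical_eur_pp), 2330)
  expect_equal(pp$total_eur_pp[pp$stage == "mild"], 2689)
  expect_equal(pp$total_eur_pp[pp$stage == "moderate"], 2628)
  expect_equal(pp$total_eur_pp[pp$stage == "severe"], 3954)
  # doubling all costs doubles every per-person figure
  cp2 <- aggregate_costs(med * 2, c(`2020` = 2 * 2330 * 220), trajectory = traj)
  pp2 <- per_person_costs(cp2, 2020)
  expect_equal(pp2$total_eur_pp, 2 * pp$total_eur_pp)
  # zero head count is an error
  none <- as_trajectory(list(ad_state(2020, matrix(0, 31, 3), rep(0, 31))))
  cp0 <- aggregate_costs(c(`2020` = 0), c(`2020` = 0), trajectory = none)
  expect_error(per_person_costs(cp0, 2020), class = "adburden_schema_error")
})

test_that("cost table validators reject incomplete or malformed inputs", {
  mc <- fixture_medical_costs("khk")
  expect_error(medical_cost_table(mc[-1, ]), class = "adburden_schema_error")
  expect_error(treated_share_table(data.frame(region = "x", stage = "mild",
                                              share = 0.2)),
               class = "adburden_schema_error")
  expect_error(treated_share_table(data.frame(region = "x",
                                              stage = c("mild", "moderate", "severe"),
                                              share = c(0.2, 0.3, 1.7))),
               class = "adburden_schema_error")
  res <- fixture_services("vys")$residential
  res$beds[1] <- 2.5
  expect_error(service_inventory(res, "residential"), class = "adburden_schema_error")
})
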