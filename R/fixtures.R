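# Packaged reference cost tables for two Czech regions, Kralovehradecky kraj
# (KHK) and Kraj Vysocina (VYS): direct medical unit costs per treated
# patient (2017 prices), social-service inventories (2019-2020 prices), and
# the published regional cost summaries used in worked examples. Treated
# shares were never published for these regions; synthetic defaults live in
# the generator, not here.

fixture_region <- function(region) {
  region <- tolower(as.character(region))
  if (!region %in% c("khk", "vys")) {
    abort_schema("unknown fixture region '%s' (use 'khk' or 'vys')", region)
  }
  region
}

# 12 rows per region: stage x band, category values in the order
# outpatient_points, outpatient_other, medicines, inpatient_points,
# acute_care, other_care.
medical_fixture_values <- function(region) {
  khk <- c(
    435.77, 31.77, 72.00, 0.00, 243.42, 442.54,
    268.15, 34.35, 22.35, 0.00, 236.88, 489.04,
    187.77, 15.23, 33.35, 0.00, 264.69, 574.23,
    164.85,  6.27,  3.35, 0.00, 263.15, 976.08,
    227.35, 23.46, 77.27, 0.00, 166.77, 557.00,
    212.31, 24.12,  9.46, 0.00, 291.65, 772.62,
    182.96, 13.08, 50.15, 0.15, 242.38, 506.92,
    154.69, 10.19,  5.54, 0.00, 125.00,   0.00,
    188.42, 52.58, 25.58, 0.00, 170.04, 356.77,
    213.77, 21.85, 294.54, 0.00, 307.88, 685.92,
    161.15, 11.81,  9.00, 0.00, 298.85, 715.96,
    120.42,  8.35,  7.65, 0.00, 224.54, 891.38)
  vys <- c(
    244.69, 30.85, 454.62, 0.00, 316.85, 586.85,
    232.23, 19.54,  75.58, 0.00, 194.00, 453.85,
    251.15, 12.00,  14.19, 0.00, 260.92, 711.69,
    157.42,  6.54,   7.08, 0.00, 308.73, 668.38,
    194.35, 24.38,   1.85, 0.00, 107.42, 761.92,
    202.00, 19.12,   5.92, 0.00, 167.58, 708.12,
    201.35,  8.65,   3.92, 0.00, 193.62, 722.12,
    187.04, 13.50,   4.54, 0.00, 263.73, 868.12,
    185.35, 25.23,   2.73, 0.00, 187.19, 647.42,
    210.12, 18.42,  41.81, 0.00, 215.08, 531.62,
    261.31,  9.08,  12.58, 0.00, 257.73, 832.12,
    157.92,  3.23,  19.58, 0.00, 276.35, 987.19)
  if (region == "khk") khk else vys
}

#' Packaged medical unit-cost table for a Czech region
#'
#' Direct medical unit costs in EUR per treated patient per year, by disease
#' stage and age band, for the KHK or VYS region (2017 price base).
#'
#' @param region `"khk"` or `"vys"`.
#' @return A [medical_cost_table()].
#' @export
fixture_medical_costs <- function(region = c("khk", "vys")) {
  region <- fixture_region(region[1L])
  vals <- medical_fixture_values(region)
  grid <- expand.grid(category = COST_CATEGORIES, age_band = AGE_BANDS,
                      stage = STAGES, stringsAsFactors = FALSE)
  medical_cost_table(data.frame(region = region, stage = grid$stage,
                                age_band = grid$age_band,
                                category = grid$category,
                                eur_per_treated_year = vals))
}

#' Packaged social-service inventories for a Czech region
#'
#' Residential bed capacities (EUR per bed-day) and non-residential FTE
#' capacities (EUR per FTE-month) with their AD utilisation shares, for the
#' KHK or VYS region (2019-2020 price base).
#'
#' @param region `"khk"` or `"vys"`.
#' @return List with elements `residential` and `nonresidential`, both
#'   [service_inventory()] objects.
#' @export
fixture_services <- function(region = c("khk", "vys")) {
  region <- fixture_region(region[1L])
  res_names <- c("Respite Care", "Week Care Centres", "Homes for the Elderly",
                 "Special Regime Homes", "Health Care Facilities")
  nonres_names <- c("Personal Assistance", "Day Services Centres",
                    "Daycare Centres", "Domiciliary Service", "Respite Care")
  if (region == "khk") {
    res <- data.frame(region = region, service = res_names,
                      beds = c(67, 9, 2019, 447, 34),
                      ad_share = c(0.78, 0.47, 0.17, 0.90, 0.47),
                      eur_per_bed_day = c(44.65, 45.58, 39.77, 44.73, 23.77))
    nonres <- data.frame(region = region, service = nonres_names,
                         fte = c(82, 8, 31, 412, 0),
                         ad_share = c(0.50, 0.50, 0.50, 0.50, 0.78),
                         eur_per_fte_month = c(1605.96, 2184.31, 1681.62,
                                               1804.54, 0.00))
  } else {
    res <- data.frame(region = region, service = res_names,
                      beds = c(39, 0, 1977, 812, 57),
                      ad_share = c(0.78, 0.47, 0.20, 0.80, 0.47),
                      eur_per_bed_day = c(71.15, 76.92, 51.92, 53.85, 33.08))
    nonres <- data.frame(region = region, service = nonres_names,
                         fte = c(83, 23, 117, 405, 25),
                         ad_share = c(0.50, 0.50, 0.50, 0.50, 0.78),
                         eur_per_fte_month = c(1961.54, 2153.85, 2153.85,
                                               1961.54, 2346.15))
  }
  list(residential = service_inventory(res, "residential"),
       nonresidential = service_inventory(nonres, "nonresidential"))
}

#' Published yearly cost summaries for the KHK and VYS regions
#'
#' Direct medical and non-medical costs in million EUR for selected years
#' 2020-2070, together with the published totals. One published cell (VYS
#' 2020 total, 38.484) differs from the sum of its components (38.485) by a
#' display-rounding artefact; worked examples exclude it from exact checks.
#'
#' @return Data frame with columns `region`, `year`, `medical_meur`,
#'   `nonmedical_meur`, `total_printed_meur`.
#' @export
fixture_cost_summary <- function() {
  years <- c(2020L, 2030L, 2040L, 2050L, 2060L, 2070L)
  data.frame(
    region = rep(c("khk", "vys"), each = length(years)),
    year = rep(years, times = 2L),
    medical_meur = c(4.289, 6.866, 8.589, 9.592, 10.695, 11.245,
                     3.977, 6.441, 8.229, 9.490, 10.683, 11.184),
    nonmedical_meur = c(21.347, 33.422, 42.795, 47.671, 53.730, 57.773,
                        34.508, 54.593, 70.358, 81.184, 91.342, 96.799),
    total_printed_meur = c(25.636, 40.288, 51.384, 57.263, 64.425, 69.018,
                           38.484, 61.034, 78.587, 90.674, 102.025, 107.983))
}

#' Published per-person cost summaries for the KHK and VYS regions
#'
#' Annual direct costs in EUR per person with AD, by disease stage and
#' stage-agnostic (`all`). Non-medical per-person costs are identical across
#' stages because social-care records cannot resolve disease stages.
#'
#' @return Data frame with columns `region`, `stage`, `medical_eur_pp`,
#'   `nonmedical_eur_pp`, `total_printed_eur_pp`.
#' @export
fixture_per_person_summary <- function() {
  stages <- c(STAGES, "all")
  data.frame(
    region = rep(c("khk", "vys"), each = 4L),
    stage = rep(stages, times = 2L),
    medical_eur_pp = c(359, 298, 1624, 482, 354, 389, 1671, 504),
    nonmedical_eur_pp = c(rep(2330, 4L), rep(4229, 4L)),
    total_printed_eur_pp = c(2689, 2628, 3954, 2812, 4583, 4618, 5900, 4733))
}
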