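# Direct-cost model. Medical costs are per-treated-patient unit costs by
# stage x age band x category, applied to the treated fraction of the
# projected AD population. Non-medical (social) costs are capacity costs of
# residential services (beds, priced per bed-day) and non-residential
# services (full-time employees, priced per FTE-month), attributed to AD by
# a utilisation share and scaled over time with the growth of the AD
# population while unit costs stay at constant base-year prices.

COST_CATEGORIES <- c("outpatient_points", "outpatient_other", "medicines",
                     "inpatient_points", "acute_care", "other_care")
AGE_BANDS <- c("65-69", "70-79", "80-89", "90+")

#' Medical unit-cost table
#'
#' Annual direct medical costs in EUR per treated patient, by disease stage,
#' age band and cost category. All 12 stage-by-band cells must be present
#' for each of the 6 categories.
#'
#' @param x Data frame with columns `region`, `stage` (`mild`, `moderate`,
#'   `severe`), `age_band` (`65-69`, `70-79`, `80-89`, `90+`), `category`
#'   (`outpatient_points`, `outpatient_other`, `medicines`,
#'   `inpatient_points`, `acute_care`, `other_care`) and
#'   `eur_per_treated_year` (non-negative).
#' @return The validated data frame with class `medical_cost_table`.
#' @export
medical_cost_table <- function(x) {
  need <- c("region", "stage", "age_band", "category", "eur_per_treated_year")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort_schema("medical cost table misses columns: %s",
                                 paste(miss, collapse = ", "))
  if (!all(x$stage %in% STAGES)) abort_schema("unknown stage in medical cost table")
  if (!all(x$age_band %in% AGE_BANDS)) abort_schema("unknown age band in medical cost table")
  if (!all(x$category %in% COST_CATEGORIES)) abort_schema("unknown category in medical cost table")
  check_finite_nonneg(x$eur_per_treated_year, "medical unit costs")
  cells <- with(x, table(stage, age_band, category))
  if (any(cells != 1L)) {
    abort_schema("medical cost table must contain each stage x age-band x category cell exactly once (%d missing or duplicated)",
                 sum(cells != 1L))
  }
  structure(as.data.frame(x), class = c("medical_cost_table", "data.frame"))
}

#' Treated-share table
#'
#' Fraction of the AD population that is treated within a year, per stage.
#' Shares are held constant over the simulated horizon.
#'
#' @param x Data frame with columns `region`, `stage` and `share` in `[0,1]`,
#'   one row per stage.
#' @return The validated data frame with class `treated_share_table`.
#' @export
treated_share_table <- function(x) {
  need <- c("region", "stage", "share")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort_schema("treated-share table misses columns: %s",
                                 paste(miss, collapse = ", "))
  if (!setequal(x$stage, STAGES) || nrow(x) != 3L) {
    abort_schema("treated-share table must have exactly one row per stage")
  }
  if (anyNA(x$share) || any(x$share < 0 | x$share > 1)) {
    abort_schema("treated shares must lie in [0, 1]")
  }
  structure(as.data.frame(x), class = c("treated_share_table", "data.frame"))
}

#' Social-service inventory
#'
#' Residential services carry a bed capacity priced in EUR per bed-day;
#' non-residential (outpatient and domiciliary) services carry a full-time
#' employee (FTE) capacity priced in EUR per FTE-month. `ad_share` is the
#' proportion of the capacity used by people with AD.
#'
#' @param x Data frame. Residential columns: `region`, `service`, `beds`,
#'   `ad_share`, `eur_per_bed_day`. Non-residential columns: `region`,
#'   `service`, `fte`, `ad_share`, `eur_per_fte_month`.
#' @param type `"residential"` or `"nonresidential"`.
#' @return Validated data frame with class `service_inventory`; the type is
#'   kept in attribute `service_type`.
#' @export
service_inventory <- function(x, type = c("residential", "nonresidential")) {
  type <- match.arg(type)
  need <- if (type == "residential") {
    c("region", "service", "beds", "ad_share", "eur_per_bed_day")
  } else {
    c("region", "service", "fte", "ad_share", "eur_per_fte_month")
  }
  miss <- setdiff(need, names(x))
  if (length(miss)) abort_schema("%s inventory misses columns: %s", type,
                                 paste(miss, collapse = ", "))
  cap <- x[[need[3L]]]
  check_finite_nonneg(cap, "service capacity")
  if (type == "residential" && any(cap != round(cap))) {
    abort_schema("bed capacities must be whole numbers")
  }
  if (anyNA(x$ad_share) || any(x$ad_share < 0 | x$ad_share > 1)) {
    abort_schema("AD utilisation shares must lie in [0, 1]")
  }
  check_finite_nonneg(x[[need[5L]]], "service unit costs")
  structure(as.data.frame(x), class = c("service_inventory", "data.frame"),
            service_type = type)
}

share_vector <- function(shares) {
  stats::setNames(shares$share[match(STAGES, shares$stage)], STAGES)
}

# stage x band matrix of summed per-treated-patient costs over categories
unit_cost_matrix <- function(unit_costs) {
  agg <- stats::aggregate(eur_per_treated_year ~ stage + age_band,
                          data = unit_costs, FUN = sum)
  m <- matrix(0, 3L, length(AGE_BANDS), dimnames = list(STAGES, AGE_BANDS))
  m[cbind(agg$stage, agg$age_band)] <- agg$eur_per_treated_year
  m
}

#' Annual direct medical costs of a projected AD population
#'
#' For each simulated year, the treated population per stage and age band is
#' the AD head count times the stage's treated share; its cost is the sum
#' over stages, bands and categories of treated patients times the unit cost.
#'
#' @param trajectory An `ad_trajectory` from [run_projection()] (all modelled
#'   ages are 65+).
#' @param unit_costs A [medical_cost_table()].
#' @param shares A [treated_share_table()].
#' @return Numeric matrix (years by stages, in EUR) of class
#'   `medical_cost_stream`, with the region kept as an attribute.
#' @export
medical_costs <- function(trajectory, unit_costs, shares) {
  stopifnot(inherits(trajectory, "ad_trajectory") || is.list(trajectory))
  unit_costs <- medical_cost_table(unit_costs)
  shares <- treated_share_table(shares)
  u <- unit_cost_matrix(unit_costs)
  sh <- share_vector(shares)
  years <- vapply(trajectory, function(s) s$year, integer(1))
  out <- matrix(0, length(years), 3L,
                dimnames = list(year = as.character(years), stage = STAGES))
  for (i in seq_along(trajectory)) {
    cb <- counts_by_band(trajectory[[i]], AGE_BANDS)       # stages x bands
    out[i, ] <- rowSums(cb * u) * sh
  }
  structure(out, class = c("medical_cost_stream", "matrix", "array"),
            region = attr(trajectory, "region") %||% unit_costs$region[1L])
}

#' Growth index of the AD population
#'
#' Ratio of the total AD population in each year to the base year; used to
#' scale social-service capacities (and hence non-medical costs) while unit
#' costs stay constant.
#'
#' @param trajectory An `ad_trajectory`.
#' @param base_year Base calendar year (must be in the trajectory and have a
#'   positive AD count).
#' @return Named numeric vector of dimensionless factors, one per year, with
#'   `index[base_year] == 1`.
#' @export
growth_index <- function(trajectory, base_year) {
  years <- vapply(trajectory, function(s) s$year, integer(1))
  totals <- vapply(trajectory, ad_total, numeric(1))
  i <- match(as.integer(base_year), years)
  if (is.na(i)) abort_schema("base year %s is not in the trajectory", base_year)
  if (totals[i] <= 0) abort_schema("AD population is zero in base year %s; growth index undefined", base_year)
  stats::setNames(totals / totals[i], as.character(years))
}

#' Annual direct non-medical (social) costs
#'
#' Residential: beds x AD share x EUR per bed-day x 365; non-residential:
#' FTE x AD share x EUR per FTE-month x 12. The base-year capacity cost is
#' scaled by the AD growth index in every year; unit costs are constant
#' base-year prices and are not discounted.
#'
#' @param residential Residential [service_inventory()].
#' @param nonresidential Non-residential [service_inventory()].
#' @param index Growth index from [growth_index()] (values must be
#'   non-negative).
#' @return Named numeric vector of EUR per year (same names as `index`),
#'   with attributes `residential_base` and `nonresidential_base` (EUR in
#'   the base year).
#' @export
nonmedical_costs <- function(residential, nonresidential, index) {
  residential <- service_inventory(residential, "residential")
  nonresidential <- service_inventory(nonresidential, "nonresidential")
  if (anyNA(index) || any(index < 0)) abort_schema("growth index must be non-negative")
  res_base <- sum(residential$beds * residential$ad_share *
                    residential$eur_per_bed_day) * 365
  nonres_base <- sum(nonresidential$fte * nonresidential$ad_share *
                       nonresidential$eur_per_fte_month) * 12
  structure((res_base + nonres_base) * index,
            residential_base = res_base, nonresidential_base = nonres_base)
}

#' Assemble a cost projection
#'
#' Aligns the medical and non-medical cost streams on their common years and
#' builds the reporting object: yearly medical, non-medical and total costs,
#' plus — when stage-resolved medical costs and head counts are available —
#' stage-split totals in which the non-medical pool is allocated to stages in
#' proportion to head counts (a presentation convention; social-care data
#' cannot resolve disease stages).
#'
#' @param medical Either a `medical_cost_stream` (years by stages, EUR) or a
#'   named numeric vector of yearly medical totals in EUR.
#' @param nonmedical Named numeric vector of yearly non-medical costs in EUR
#'   (e.g. from [nonmedical_costs()]).
#' @param trajectory Optional `ad_trajectory` supplying head counts for the
#'   stage split and per-person figures.
#' @param region Region identifier (defaults to the stream's attribute).
#' @return An object of class `cost_projection` with fields `by_year` (data
#'   frame `region`, `year`, `medical_eur`, `nonmedical_eur`, `total_eur`),
#'   `by_stage` (stage-split data frame or `NULL`), `counts` (years by
#'   stages head counts or `NULL`).
#' @export
aggregate_costs <- function(medical, nonmedical, trajectory = NULL,
                            region = NULL) {
  if (is.matrix(medical)) {
    med_years <- rownames(medical)
    med_total <- rowSums(medical)
    med_stage <- unclass(medical)
  } else {
    med_years <- names(medical)
    med_total <- as.numeric(medical)
    med_stage <- NULL
  }
  if (is.null(med_years) || is.null(names(nonmedical))) {
    abort_schema("medical and non-medical streams must carry year names")
  }
  if (!identical(med_years, names(nonmedical))) {
    abort_schema("medical and non-medical streams cover different years")
  }
  check_finite_nonneg(med_total, "medical costs")
  check_finite_nonneg(as.numeric(nonmedical), "non-medical costs")
  region <- region %||% attr(medical, "region") %||%
    attr(trajectory, "region") %||% "region"
  years <- as.integer(med_years)
  by_year <- data.frame(region = rep(region, length(years)), year = years,
                        medical_eur = med_total,
                        nonmedical_eur = as.numeric(nonmedical),
                        total_eur = med_total + as.numeric(nonmedical),
                        row.names = NULL)
  counts <- NULL
  by_stage <- NULL
  if (!is.null(trajectory)) {
    traj_years <- vapply(trajectory, function(s) s$year, integer(1))
    if (!identical(as.integer(traj_years), years)) {
      abort_schema("trajectory years do not match the cost streams")
    }
    counts <- t(vapply(trajectory, function(s) colSums(s$ad_counts), numeric(3)))
    dimnames(counts) <- list(year = med_years, stage = STAGES)
  }
  if (!is.null(med_stage) && !is.null(counts)) {
    tot_counts <- rowSums(counts)
    share <- counts / ifelse(tot_counts > 0, tot_counts, 1)
    nm_alloc <- share * as.numeric(nonmedical)
    by_stage <- data.frame(region = region,
                           year = rep(years, times = 3L),
                           stage = rep(STAGES, each = length(years)),
                           medical_eur = as.numeric(med_stage),
                           nonmedical_alloc_eur = as.numeric(nm_alloc),
                           total_eur = as.numeric(med_stage + nm_alloc),
                           count = as.numeric(counts), row.names = NULL)
  }
  structure(list(region = region, years = years, by_year = by_year,
                 by_stage = by_stage, medical_by_stage = med_stage,
                 counts = counts),
            class = "cost_projection")
}

#' @export
print.cost_projection <- function(x, ...) {
  cat(sprintf("cost_projection: region '%s', years %d-%d\n",
              x$region, min(x$years), max(x$years)))
  first <- x$by_year[1L, ]; last <- x$by_year[nrow(x$by_year), ]
  cat(sprintf("  %d: medical %.3f M, non-medical %.3f M, total %.3f M EUR\n",
              first$year, first$medical_eur / 1e6, first$nonmedical_eur / 1e6,
              first$total_eur / 1e6))
  cat(sprintf("  %d: medical %.3f M, non-medical %.3f M, total %.3f M EUR\n",
              last$year, last$medical_eur / 1e6, last$nonmedical_eur / 1e6,
              last$total_eur / 1e6))
  invisible(x)
}

#' Annual costs per person with AD
#'
#' Medical costs per person are stage-specific (stage cost over stage head
#' count); non-medical costs per person are the total non-medical pool over
#' the total AD head count and are by construction identical across stages
#' (social-care data cannot resolve disease stages). Totals are the sums of
#' the two components. The `all` row is stage-agnostic.
#'
#' @param costs A `cost_projection` from [aggregate_costs()].
#' @param year Calendar year to evaluate.
#' @param trajectory Optional `ad_trajectory` supplying head counts when the
#'   cost projection does not already carry them.
#' @return Data frame with columns `region`, `stage` (`mild`, `moderate`,
#'   `severe` when stage-resolved, plus `all`), `medical_eur_pp`,
#'   `nonmedical_eur_pp`, `total_eur_pp`.
#' @export
per_person_costs <- function(costs, year, trajectory = NULL) {
  stopifnot(inherits(costs, "cost_projection"))
  year <- as.integer(year)
  i <- match(year, costs$years)
  if (is.na(i)) abort_schema("year %d is not covered by the cost projection", year)
  counts <- costs$counts
  if (is.null(counts) && !is.null(trajectory)) {
    counts <- t(vapply(trajectory, function(s) colSums(s$ad_counts), numeric(3)))
    rownames(counts) <- vapply(trajectory, function(s) as.character(s$year),
                               character(1))
  }
  if (is.null(counts)) {
    abort_schema("per-person costs need AD head counts; supply a trajectory")
  }
  n_stage <- counts[as.character(year), ]
  n_total <- sum(n_stage)
  if (n_total <= 0) abort_schema("AD population is zero in %d; per-person costs undefined", year)
  nm_pp <- costs$by_year$nonmedical_eur[i] / n_total
  rows <- data.frame(region = costs$region, stage = "all",
                     medical_eur_pp = costs$by_year$medical_eur[i] / n_total,
                     nonmedical_eur_pp = nm_pp, row.names = NULL)
  if (!is.null(costs$medical_by_stage)) {
    if (any(n_stage <= 0)) {
      abort_schema("a stage has zero head count in %d; stage per-person costs undefined", year)
    }
    stage_rows <- data.frame(region = costs$region, stage = STAGES,
                             medical_eur_pp = costs$medical_by_stage[i, ] / n_stage,
                             nonmedical_eur_pp = nm_pp, row.names = NULL)
    rows <- rbind(stage_rows, rows)
  }
  rows$total_eur_pp <- rows$medical_eur_pp + rows$nonmedical_eur_pp
  rows
}
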