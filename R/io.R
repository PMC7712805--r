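# CSV/YAML readers and writers for every input and output schema, plus the
# run orchestration (scenario -> trajectory -> costs -> report) and the run
# manifest. All files are UTF-8 with a decimal point; ages are written as
# integers 0-94 plus the literal "95+".

read_csv_checked <- function(path) {
  if (!file.exists(path)) abort_schema("input file does not exist: %s", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

with_file_context <- function(path, expr) {
  tryCatch(expr, adburden_schema_error = function(e) {
    abort_schema("%s: %s", path, conditionMessage(e))
  })
}

#' Read and write a population projection CSV
#'
#' Long format with header `region,year,age,count`; ages `0`-`94` plus
#' `95+`.
#'
#' @param path File path.
#' @param projection A [population_projection()] (writer).
#' @return Reader: a [population_projection()]; writer: the path, invisibly.
#' @export
read_projection_csv <- function(path) {
  df <- read_csv_checked(path)
  with_file_context(path, {
    need <- c("region", "year", "age", "count")
    if (!all(need %in% names(df))) {
      abort_schema("expected columns %s", paste(need, collapse = ","))
    }
    if (!all(age_labels() %in% df$age)) {
      miss <- setdiff(age_labels(), unique(df$age))
      abort_schema("projection misses age cohort(s): %s",
                   paste(utils::head(miss, 3L), collapse = ", "))
    }
    years <- sort(unique(as.integer(df$year)))
    counts <- matrix(NA_real_, 96L, length(years),
                     dimnames = list(age_labels(), years))
    counts[cbind(match(df$age, age_labels()),
                 match(as.integer(df$year), years))] <- df$count
    if (anyNA(counts)) abort_schema("projection is missing age x year cells")
    population_projection(counts, years, df$region[1L])
  })
}

#' @rdname read_projection_csv
#' @export
write_projection_csv <- function(projection, path) {
  stopifnot(inherits(projection, "population_projection"))
  df <- data.frame(region = projection$region,
                   year = rep(projection$years, each = 96L),
                   age = rep(age_labels(), times = length(projection$years)),
                   count = as.numeric(projection$counts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a prevalence CSV
#'
#' Header `age,prevalence`, ages `65`-`94` plus `95+`.
#'
#' @param path File path.
#' @param prevalence A [prevalence_curve()] (writer).
#' @return Reader: a [prevalence_curve()]; writer: the path, invisibly.
#' @export
read_prevalence_csv <- function(path) {
  df <- read_csv_checked(path)
  with_file_context(path, {
    if (!all(c("age", "prevalence") %in% names(df))) {
      abort_schema("expected columns age,prevalence")
    }
    if (!setequal(df$age, ad_age_labels()) || nrow(df) != N_AD_AGES) {
      abort_schema("prevalence must cover exactly ages 65-94 and 95+")
    }
    prevalence_curve(df$prevalence[match(ad_age_labels(), df$age)])
  })
}

#' @rdname read_prevalence_csv
#' @export
write_prevalence_csv <- function(prevalence, path) {
  stopifnot(inherits(prevalence, "prevalence_curve"))
  utils::write.csv(data.frame(age = ad_age_labels(),
                              prevalence = as.numeric(prevalence)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a transition matrix CSV
#'
#' 4x4 matrix with a `stage` header column and columns
#' `mild,moderate,severe,death`.
#'
#' @param path File path.
#' @param transitions A [transition_matrix()] (writer).
#' @return Reader: a [transition_matrix()]; writer: the path, invisibly.
#' @export
read_transition_csv <- function(path) {
  df <- read_csv_checked(path)
  with_file_context(path, {
    if (!identical(names(df), c("stage", STATES)) ||
        !identical(df$stage, STATES)) {
      abort_schema("transition CSV must have rows and columns mild,moderate,severe,death")
    }
    m <- as.matrix(df[, STATES])
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad)) {
      abort_schema("row '%s' sums to %.6f, not 1", df$stage[bad[1L]], rs[bad[1L]])
    }
    transition_matrix(m)
  })
}

#' @rdname read_transition_csv
#' @export
write_transition_csv <- function(transitions, path) {
  stopifnot(inherits(transitions, "transition_matrix"))
  df <- data.frame(stage = STATES, unclass(transitions), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cost-side input CSVs
#'
#' Medical unit costs: `region,stage,age_band,category,eur_per_treated_year`;
#' treated shares: `region,stage,share`; residential services:
#' `region,service,beds,ad_share,eur_per_bed_day`; non-residential services:
#' `region,service,fte,ad_share,eur_per_fte_month`.
#'
#' @param path File path.
#' @param x The corresponding validated object (writers).
#' @return Readers: the validated object; writers: the path, invisibly.
#' @export
read_medical_costs_csv <- function(path) {
  with_file_context(path, medical_cost_table(read_csv_checked(path)))
}

#' @rdname read_medical_costs_csv
#' @export
read_treated_shares_csv <- function(path) {
  with_file_context(path, treated_share_table(read_csv_checked(path)))
}

#' @rdname read_medical_costs_csv
#' @export
read_residential_csv <- function(path) {
  with_file_context(path, service_inventory(read_csv_checked(path), "residential"))
}

#' @rdname read_medical_costs_csv
#' @export
read_nonresidential_csv <- function(path) {
  with_file_context(path, service_inventory(read_csv_checked(path), "nonresidential"))
}

#' @rdname read_medical_costs_csv
#' @export
write_cost_input_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario YAML file
#'
#' The YAML holds the `scenario_config` fields (`region`, `start_year`,
#' `end_year`, optional `base_year`, `calibration_tol`, `limit_tol`,
#' `max_iter`, `seed`) and an `inputs` map of CSV paths (`projection`,
#' `prevalence`, `transitions`, and optionally `medical_costs`,
#' `treated_shares`, `residential`, `nonresidential`). Paths are resolved
#' relative to the YAML file.
#'
#' @param path Path to the scenario YAML.
#' @return A [scenario_config()] with attribute `input_files` (the resolved
#'   paths).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort_schema("scenario file does not exist: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else file.path(base, p)
  inputs <- cfg$inputs %||% list()
  files <- list(
    projection = resolve(inputs$projection),
    prevalence = resolve(inputs$prevalence),
    transitions = resolve(inputs$transitions),
    medical_costs = resolve(inputs$medical_costs),
    treated_shares = resolve(inputs$treated_shares),
    residential = resolve(inputs$residential),
    nonresidential = resolve(inputs$nonresidential))
  for (k in c("projection", "prevalence", "transitions")) {
    if (is.null(files[[k]])) abort_schema("%s: scenario misses required input '%s'", path, k)
  }
  config <- scenario_config(
    region = cfg$region %||% "region",
    start_year = cfg$start_year, end_year = cfg$end_year,
    projection = read_projection_csv(files$projection),
    prevalence = read_prevalence_csv(files$prevalence),
    transitions = read_transition_csv(files$transitions),
    calibration_tol = cfg$calibration_tol %||% 1e-6,
    limit_tol = cfg$limit_tol %||% 1e-8,
    max_iter = cfg$max_iter %||% 200L,
    base_year = cfg$base_year %||% cfg$start_year,
    seed = cfg$seed,
    medical_costs = if (!is.null(files$medical_costs)) read_medical_costs_csv(files$medical_costs),
    treated_shares = if (!is.null(files$treated_shares)) read_treated_shares_csv(files$treated_shares),
    residential = if (!is.null(files$residential)) read_residential_csv(files$residential),
    nonresidential = if (!is.null(files$nonresidential)) read_nonresidential_csv(files$nonresidential))
  attr(config, "input_files") <- Filter(Negate(is.null), files)
  attr(config, "config_file") <- normalizePath(path)
  config
}

#' Write a synthetic input bundle to a directory
#'
#' Writes all input CSVs and a `scenario.yaml` pointing at them, ready for
#' [read_scenario()] / the `simulate` CLI subcommand.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Target directory (created if needed).
#' @param fixture Passed to [generate_cost_inputs()] (`NULL`, `"khk"` or
#'   `"vys"`).
#' @return The path of the written `scenario.yaml`, invisibly.
#' @export
write_scenario_bundle <- function(spec, dir, fixture = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- generate_scenario(spec, fixture = fixture)
  write_projection_csv(config$projection, file.path(dir, "projection.csv"))
  write_prevalence_csv(config$prevalence, file.path(dir, "prevalence.csv"))
  write_transition_csv(config$transitions, file.path(dir, "transitions.csv"))
  write_cost_input_csv(config$medical_costs, file.path(dir, "medical_costs.csv"))
  write_cost_input_csv(config$treated_shares, file.path(dir, "treated_shares.csv"))
  write_cost_input_csv(config$residential, file.path(dir, "residential.csv"))
  write_cost_input_csv(config$nonresidential, file.path(dir, "nonresidential.csv"))
  yaml::write_yaml(list(
    region = config$region,
    start_year = config$start_year, end_year = config$end_year,
    base_year = config$base_year,
    calibration_tol = config$calibration_tol,
    limit_tol = config$limit_tol, max_iter = config$max_iter,
    seed = spec$seed,
    inputs = list(projection = "projection.csv",
                  prevalence = "prevalence.csv",
                  transitions = "transitions.csv",
                  medical_costs = "medical_costs.csv",
                  treated_shares = "treated_shares.csv",
                  residential = "residential.csv",
                  nonresidential = "nonresidential.csv")),
    file.path(dir, "scenario.yaml"))
  invisible(file.path(dir, "scenario.yaml"))
}

#' Compute the cost projection of a scenario
#'
#' Applies the cost model (medical unit costs, growth-indexed social-service
#' capacity costs) to a simulated trajectory.
#'
#' @param config A [scenario_config()] carrying the cost-side inputs.
#' @param trajectory An `ad_trajectory` from [run_projection()].
#' @return A `cost_projection` (see [aggregate_costs()]).
#' @export
project_costs <- function(config, trajectory) {
  stopifnot(inherits(config, "scenario_config"))
  for (k in c("medical_costs", "treated_shares", "residential", "nonresidential")) {
    if (is.null(config[[k]])) abort_schema("scenario carries no '%s' input", k)
  }
  med <- medical_costs(trajectory, config$medical_costs, config$treated_shares)
  idx <- growth_index(trajectory, config$base_year)
  nonmed <- nonmedical_costs(config$residential, config$nonresidential, idx)
  aggregate_costs(med, nonmed, trajectory = trajectory, region = config$region)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Write run reports
#'
#' Writes the trajectory (long and per-year summary), the yearly cost table
#' (million EUR, three decimals), the per-person cost table for the base
#' year (whole EUR), and the run manifest. Per-person rows re-check the
#' additivity `total = medical + non-medical` before writing.
#'
#' @param costs A `cost_projection`.
#' @param trajectory An `ad_trajectory`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional [scenario_config()] for manifest provenance.
#' @param per_person_year Year of the per-person table (default: first year).
#' @return Invisibly, a named list of the written file paths.
#' @export
report <- function(costs, trajectory, out_dir, config = NULL,
                   per_person_year = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trajectory = file.path(out_dir, "trajectory.csv"),
    summary = file.path(out_dir, "trajectory_summary.csv"),
    costs_by_year = file.path(out_dir, "costs_by_year.csv"),
    per_person = file.path(out_dir, "costs_per_person.csv"))
  utils::write.csv(as.data.frame(trajectory), paths$trajectory,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(trajectory_summary(trajectory), paths$summary,
                   row.names = FALSE, quote = FALSE)
  by_year <- costs$by_year
  out_year <- data.frame(region = by_year$region, year = by_year$year,
                         medical_meur = round_half_up(by_year$medical_eur / 1e6, 3),
                         nonmedical_meur = round_half_up(by_year$nonmedical_eur / 1e6, 3),
                         total_meur = round_half_up(by_year$total_eur / 1e6, 3))
  utils::write.csv(out_year, paths$costs_by_year, row.names = FALSE, quote = FALSE)
  year <- per_person_year %||% costs$years[1L]
  pp <- per_person_costs(costs, year, trajectory = trajectory)
  stopifnot(all(abs(pp$total_eur_pp - pp$medical_eur_pp - pp$nonmedical_eur_pp) < 0.5))
  out_pp <- data.frame(region = pp$region, stage = pp$stage,
                       medical_eur_pp = round_half_up(pp$medical_eur_pp),
                       nonmedical_eur_pp = round_half_up(pp$nonmedical_eur_pp),
                       total_eur_pp = round_half_up(pp$medical_eur_pp + pp$nonmedical_eur_pp))
  utils::write.csv(out_pp, paths$per_person, row.names = FALSE, quote = FALSE)
  paths$manifest <- write_manifest(out_dir, trajectory, config = config,
                                   outputs = unlist(paths))
  invisible(paths)
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  summary <- list(region = config$region, start_year = config$start_year,
                  end_year = config$end_year, base_year = config$base_year,
                  calibration_tol = config$calibration_tol,
                  limit_tol = config$limit_tol, max_iter = config$max_iter,
                  seed = config$seed)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Run manifest: config hash, input/output checksums, package version,
# timestamp, and the calibration/convergence warnings of the run.
write_manifest <- function(out_dir, trajectory, config = NULL, outputs = character()) {
  incidence <- attr(trajectory, "incidence")
  props <- attr(trajectory, "stage_props")
  input_files <- if (!is.null(config)) attr(config, "input_files") else NULL
  manifest <- list(
    tool = "adburden",
    version = as.character(utils::packageVersion("adburden")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = if (!is.null(config)) config_digest(config) else NULL,
    inputs = if (length(input_files)) {
      lapply(input_files, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
    } else NULL,
    outputs = lapply(as.list(outputs), function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    warnings = list(
      incidence_clamps = if (!is.null(incidence)) nrow(incidence$clamps) else NA,
      infeasible_cells = if (!is.null(incidence)) nrow(incidence$infeasible) else NA,
      limit_iterations = if (!is.null(props)) attr(props, "iterations") else NA))
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Run a scenario end to end
#'
#' Loads (or takes) a scenario, runs the calibrated population projection,
#' applies the cost model when cost inputs are present, and writes reports.
#'
#' @param config A [scenario_config()] or the path of a scenario YAML.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `trajectory`, `costs` (or `NULL`) and the
#'   report `paths`.
#' @export
run_scenario <- function(config, out_dir) {
  if (is.character(config)) config <- read_scenario(config)
  stopifnot(inherits(config, "scenario_config"))
  trajectory <- run_projection(config)
  costs <- if (!is.null(config$medical_costs)) project_costs(config, trajectory)
  if (!is.null(costs)) {
    paths <- report(costs, trajectory, out_dir, config = config)
  } else {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(trajectory = file.path(out_dir, "trajectory.csv"),
                  summary = file.path(out_dir, "trajectory_summary.csv"))
    utils::write.csv(as.data.frame(trajectory), paths$trajectory,
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(trajectory_summary(trajectory), paths$summary,
                     row.names = FALSE, quote = FALSE)
    paths$manifest <- write_manifest(out_dir, trajectory, config = config,
                                     outputs = unlist(paths))
  }
  invisible(list(trajectory = trajectory, costs = costs, paths = paths))
}

#' Stage-split cost chart
#'
#' Optional ggplot2 figure of yearly total costs split by disease stage
#' (non-medical costs allocated to stages by head count).
#'
#' @param costs A `cost_projection` with a stage split.
#' @return A ggplot object.
#' @export
plot_stage_costs <- function(costs) {
  stopifnot(inherits(costs, "cost_projection"))
  if (is.null(costs$by_stage)) abort_schema("cost projection has no stage split")
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_stage_costs() needs the ggplot2 package")
  }
  df <- costs$by_stage
  df$meur <- df$total_eur / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$meur,
                                   fill = .data$stage)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "year", y = "direct costs (million EUR)",
                  fill = "stage",
                  title = sprintf("Direct AD care costs by stage, region %s",
                                  costs$region)) +
    ggplot2::theme_minimal()
}
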