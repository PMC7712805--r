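# Seeded generator of internally consistent model inputs: an ageing,
# eventually declining regional population projection; an exponential-in-age
# prevalence curve; a progressive stage transition matrix; treated shares;
# and cost tables bracketing the packaged regional magnitudes. All
# randomness flows through one seed in the spec, so identical specs yield
# identical bundles.

# Evaluate fn with a private RNG stream; leaves the caller's RNG untouched.
with_spec_rng <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Specification of a synthetic scenario
#'
#' Fixes every parameter of the synthetic input bundle. The defaults emulate
#' the study conditions of a mid-sized Central European region: a Gompertz
#' mortality schedule, a birth cohort around 5000 that declines slowly (so
#' the population ages and eventually shrinks), AD prevalence rising roughly
#' exponentially from under 1% at age 65 towards ~40% at the oldest ages,
#' and a progressive Mild -> Moderate -> Severe -> Death stage chain whose
#' mortality exceeds general-population mortality at the oldest ages.
#'
#' @param seed Integer seed; fixes the whole bundle.
#' @param region Region identifier of the generated data.
#' @param start_year First projection year.
#' @param n_years Number of projection years (default 53).
#' @param births Newborn cohort size in the first year.
#' @param birth_decline Annual relative decline of the newborn cohort
#'   (default 0.008).
#' @param drift Per-year net migration-like multiplicative drift applied to
#'   all cohorts; either a single number or a vector of `n_years - 1` rates.
#'   The default is +0.94% per year for the first three decades and -0.56%
#'   per year afterwards, reproducing the roughly one-third rise of the 65+
#'   population to mid-century followed by a decline that is typical of
#'   Czech regional projections.
#' @param gompertz_a,gompertz_b Gompertz mortality parameters; the hazard at
#'   age a is `gompertz_a * exp(gompertz_b * a)`.
#' @param prev_base Prevalence at age 65.
#' @param prev_rate Exponential prevalence rate per year of age.
#' @param prev_cap Prevalence cap (upper bound of the curve).
#' @param trans_mild,trans_moderate Named vectors `c(progress =, death =)`:
#'   one-year progression and death probabilities from Mild and Moderate.
#' @param trans_severe Named vector `c(death =)`.
#' @param treated_shares Named vector of treated fractions per stage.
#' @param cost_jitter Half-width of the relative range around the packaged
#'   regional cost magnitudes used in random cost generation (default 0.3).
#' @param randomize If `TRUE`, epidemiological and demographic parameters are
#'   themselves drawn (deterministically from `seed`) within plausible
#'   ranges, emulating between-region variation; if `FALSE` the stated
#'   defaults are used as-is.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, region = "synthia",
                           start_year = 2019L, n_years = 53L,
                           births = 5000, birth_decline = 0.008,
                           drift = NULL,
                           gompertz_a = 1.6e-4, gompertz_b = 0.075,
                           prev_base = 0.008, prev_rate = 0.13,
                           prev_cap = 0.6,
                           trans_mild = c(progress = 0.25, death = 0.12),
                           trans_moderate = c(progress = 0.30, death = 0.25),
                           trans_severe = c(death = 0.40),
                           treated_shares = c(mild = 0.20, moderate = 0.35,
                                              severe = 0.50),
                           cost_jitter = 0.3, randomize = FALSE) {
  seed <- as.integer(seed)
  if (is.na(seed)) abort_schema("seed must be an integer")
  if (n_years < 3L) abort_schema("need at least 3 projection years")
  if (prev_cap > 1 || prev_base < 0 || prev_base > prev_cap) {
    abort_schema("prevalence parameters must satisfy 0 <= base <= cap <= 1")
  }
  if (is.null(drift)) {
    n_up <- min(31L, n_years - 1L)
    drift <- c(rep(0.0094, n_up), rep(-0.0056, max(0L, n_years - 1L - n_up)))
  } else if (length(drift) == 1L) {
    drift <- rep(drift, n_years - 1L)
  } else if (length(drift) != n_years - 1L) {
    abort_schema("drift must have length 1 or n_years - 1")
  }
  if (randomize) {
    pars <- with_spec_rng(seed, function() {
      list(prev_base = stats::runif(1, 0.006, 0.010),
           prev_rate = stats::runif(1, 0.120, 0.140),
           births = stats::runif(1, 3000, 8000),
           mild = c(progress = trans_mild[["progress"]] * stats::runif(1, 0.85, 1.15),
                    death = trans_mild[["death"]] * stats::runif(1, 0.90, 1.10)),
           moderate = c(progress = trans_moderate[["progress"]] * stats::runif(1, 0.85, 1.15),
                        death = trans_moderate[["death"]] * stats::runif(1, 0.90, 1.10)),
           severe = c(death = trans_severe[["death"]] * stats::runif(1, 0.90, 1.10)))
    })
    prev_base <- pars$prev_base; prev_rate <- pars$prev_rate
    births <- pars$births
    trans_mild <- pars$mild; trans_moderate <- pars$moderate
    trans_severe <- pars$severe
  }
  for (row in list(c(trans_mild, 0), c(trans_moderate, 0), c(trans_severe, 0))) {
    if (any(row < 0) || sum(row) > 1) {
      abort_schema("per-stage progression + death probabilities must be in [0, 1] and sum to at most 1")
    }
  }
  structure(list(seed = seed, region = as.character(region),
                 start_year = as.integer(start_year),
                 n_years = as.integer(n_years), births = births,
                 birth_decline = birth_decline, drift = drift,
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 prev_base = prev_base, prev_rate = prev_rate,
                 prev_cap = prev_cap, trans_mild = trans_mild,
                 trans_moderate = trans_moderate, trans_severe = trans_severe,
                 treated_shares = treated_shares, cost_jitter = cost_jitter,
                 randomize = randomize),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: seed %d, region '%s', years %d-%d\n",
              x$seed, x$region, x$start_year, x$start_year + x$n_years - 1L))
  cat(sprintf("  prevalence %.4f * exp(%.3f * (age - 65)), cap %.2f\n",
              x$prev_base, x$prev_rate, x$prev_cap))
  invisible(x)
}

# One-year survival by age 0..94 plus the within-bin survival of 95+
# (hazard evaluated at age 96.5 for the open cohort). Internal-consistency
# constraint on the defaults: the AD death probabilities must exceed the
# demographic outflow rate of the aggregated 95+ cohort (1 - s_top), or the
# prevalence target there is unreachable with non-negative incidence.
survival_schedule <- function(spec) {
  hazard <- function(a) spec$gompertz_a * exp(spec$gompertz_b * a)
  list(s = exp(-hazard(0:94)), s_top = exp(-hazard(96.5)))
}

#' Generate a synthetic population projection
#'
#' Builds a cohort-consistent projection: the first-year age structure is the
#' stationary profile of the survival schedule, cohorts then age with that
#' schedule under a multiplicative drift (net-migration-like), while the
#' newborn cohort declines. With the default drift the 65+ population first
#' grows and the total eventually declines; with zero drift and zero birth
#' decline the projection is constant.
#'
#' @param spec A [synthetic_spec()].
#' @return A [population_projection()] (96 cohorts by `n_years` years).
#' @export
generate_projection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sched <- survival_schedule(spec)
  s <- sched$s
  years <- spec$start_year + seq_len(spec$n_years) - 1L
  counts <- matrix(0, 96L, spec$n_years)
  # stationary first-year profile
  counts[1L, 1L] <- spec$births
  for (a in 2:95) counts[a, 1L] <- counts[a - 1L, 1L] * s[a - 1L]
  counts[96L, 1L] <- counts[95L, 1L] * s[95L] / (1 - sched$s_top)
  for (t in seq_len(spec$n_years - 1L)) {
    g <- 1 + spec$drift[t]
    counts[1L, t + 1L] <- spec$births * (1 - spec$birth_decline)^t
    counts[2:95, t + 1L] <- counts[1:94, t] * s[1:94] * g
    counts[96L, t + 1L] <- (counts[95L, t] * s[95L] +
                              counts[96L, t] * sched$s_top) * g
  }
  population_projection(counts, years, spec$region)
}

#' Generate a synthetic prevalence curve
#'
#' `p(a) = min(cap, base * exp(rate * (a - 65)))` for ages 65..95+ — the
#' roughly exponential age trend characteristic of AD prevalence.
#'
#' @param spec A [synthetic_spec()].
#' @return A [prevalence_curve()].
#' @export
generate_prevalence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ages <- c(65:94, 95)
  prevalence_curve(pmin(spec$prev_cap,
                        spec$prev_base * exp(spec$prev_rate * (ages - 65))))
}

#' Generate a progressive stage transition matrix
#'
#' Mild can stay, progress to Moderate or die; Moderate can stay, progress to
#' Severe or die; Severe can stay or die; Death is absorbing. No reverse or
#' skip transitions. Stay probabilities are the complements, so rows sum to 1
#' by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return A [transition_matrix()].
#' @export
generate_transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- spec$trans_mild; mo <- spec$trans_moderate; sv <- spec$trans_severe
  p <- rbind(
    c(1 - m[["progress"]] - m[["death"]], m[["progress"]], 0, m[["death"]]),
    c(0, 1 - mo[["progress"]] - mo[["death"]], mo[["progress"]], mo[["death"]]),
    c(0, 0, 1 - sv[["death"]], sv[["death"]]),
    c(0, 0, 0, 1))
  transition_matrix(p)
}

#' Generate synthetic cost-side inputs
#'
#' In random mode, every medical unit cost and service inventory value is
#' drawn (deterministically from the spec's seed) within
#' `±cost_jitter` of the packaged KHK magnitudes. With `fixture` set to
#' `"khk"` or `"vys"`, the packaged regional tables are returned verbatim
#' instead. Treated shares always come from the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param fixture `NULL` (random mode), `"khk"` or `"vys"`.
#' @return List with elements `medical_costs` ([medical_cost_table()]),
#'   `treated_shares` ([treated_share_table()]), `residential` and
#'   `nonresidential` ([service_inventory()]).
#' @export
generate_cost_inputs <- function(spec, fixture = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  shares <- treated_share_table(data.frame(
    region = spec$region, stage = STAGES,
    share = as.numeric(spec$treated_shares[STAGES])))
  if (!is.null(fixture)) {
    region <- fixture_region(fixture)
    svc <- fixture_services(region)
    return(list(medical_costs = fixture_medical_costs(region),
                treated_shares = shares,
                residential = svc$residential,
                nonresidential = svc$nonresidential))
  }
  j <- spec$cost_jitter
  out <- with_spec_rng(spec$seed + 1L, function() {
    jitter_vals <- function(x) x * stats::runif(length(x), 1 - j, 1 + j)
    med <- fixture_medical_costs("khk")
    med$region <- spec$region
    med$eur_per_treated_year <- jitter_vals(med$eur_per_treated_year)
    svc <- fixture_services("khk")
    res <- svc$residential; nonres <- svc$nonresidential
    res$region <- spec$region; nonres$region <- spec$region
    res$beds <- round(jitter_vals(res$beds))
    res$eur_per_bed_day <- jitter_vals(res$eur_per_bed_day)
    nonres$fte <- jitter_vals(nonres$fte)
    nonres$eur_per_fte_month <- jitter_vals(nonres$eur_per_fte_month)
    list(medical_costs = medical_cost_table(med),
         residential = service_inventory(res, "residential"),
         nonresidential = service_inventory(nonres, "nonresidential"))
  })
  c(out[1L], list(treated_shares = shares), out[2:3])
}

#' Generate a complete synthetic scenario
#'
#' Bundles a projection, prevalence curve, transition matrix and cost inputs
#' into a ready-to-run [scenario_config()].
#'
#' @param spec A [synthetic_spec()].
#' @param fixture Passed to [generate_cost_inputs()].
#' @param start_year,end_year Simulated horizon; defaults to the second
#'   projection year through the last.
#' @return A [scenario_config()].
#' @export
generate_scenario <- function(spec, fixture = NULL,
                              start_year = spec$start_year + 1L,
                              end_year = spec$start_year + spec$n_years - 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  costs <- generate_cost_inputs(spec, fixture = fixture)
  scenario_config(region = spec$region,
                  start_year = start_year, end_year = end_year,
                  projection = generate_projection(spec),
                  prevalence = generate_prevalence(spec),
                  transitions = generate_transition_matrix(spec),
                  seed = spec$seed,
                  medical_costs = costs$medical_costs,
                  treated_shares = costs$treated_shares,
                  residential = costs$residential,
                  nonresidential = costs$nonresidential)
}
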