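---
title: "Projecting regional Alzheimer's disease populations and direct care costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting regional Alzheimer's disease populations and direct care costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adburden)
```

## The problem

Regional governments and health insurers that plan long-term care need two
numbers decades ahead: how many people will live with Alzheimer's disease
(AD), and what their care will cost. `adburden` implements a deterministic
two-pillar pipeline for this question: an age-structured multi-state cohort
model of the AD population, and a direct-cost model that converts the
projected population into annual medical and non-medical (social-care)
expenditure at constant prices.

## The population model

The unit of state is the number of people of each single year of age 65 to
95+ in each disease stage — Mild, Moderate, Severe — plus the disease-free
residual. Stages are ordered and progressive; Death is an absorbing fourth
state. Each simulated year applies a fixed update order:

1. **Ageing.** Every AD cohort moves up one year of age; the open-ended 95+
   cohort absorbs the 94-year-olds and its own survivors.
2. **Stage transitions.** A single 4×4 one-year transition matrix
   $P$ is applied to each aged cohort as expected counts
   ($x' = xP$); the Death column removes people from the model. The same
   matrix is used at every age, mirroring the stage-resolved (not
   age-resolved) granularity at which such probabilities are clinically
   estimated.
3. **Disease-free residual.** The disease-free population is the official
   projection count minus the simulated AD count, floored at zero. The
   projection already embeds general-population mortality and migration, so
   the model never simulates demography for the disease-free group.
4. **Incidence.** New Mild cases at attained age $a$ are
   $h(a-1, t)\,\iota(a, t)$, where $h$ is last year's disease-free pool
   (for attained age 65 the pool is the disease-free 64-year-olds; for 95+
   it is the pools at ages 94 and 95+).

Propagation is by expected counts throughout — nothing is sampled — so a
configuration determines its trajectory bit-for-bit.

### Why incidence is indexed by attained age

Storing $\iota$ by the age a person *reaches* (rather than the age they
start from) means every modelled age 65..95+ — including new 65-year-old
entrants — has exactly one incidence value, which makes the calibration
below a closed-form solve with no uncovered edge age. The numerical content
is the familiar one: with a closed cohort of size $N$ at age $a$, no deaths,
and a prevalence target $p$ first applying at age $a+1$ where the cohort
has size $N'$, the solved incidence is $pN'/N$, i.e. $p$ when the cohort
size is constant.

### Back-calculating incidence from prevalence

Age-specific AD *prevalence* is far better evidenced than incidence, so the
model treats prevalence as the calibration target of a baseline run: for
each year transition and each attained age, the required new cases are

$$\text{required}(a, t+1) = p(a)\,N(a, t+1) - \text{survivors}(a, t+1),$$

and the incidence is $\text{required}/h$, clamped to $[0,1]$. Because the
one-step map is linear in $\iota$, this is exact, and re-simulating with
the derived incidence reproduces the target prevalence surface to floating
point accuracy (the round-trip property the test suite asserts at
$10^{-6}$ relative error). Clamps — cells where the target would need
negative incidence, or where the feeder pool is empty — are logged and
surfaced in the run manifest; a clean scenario has none. Calibration is
solved per year (a fresh 31-value curve for each year transition), since a
single static curve cannot track a shifting age composition exactly.

### Initial stage split: the limit distribution

The split of the initial AD population across Mild/Moderate/Severe is not
an input: the calibrated simulation is run repeatedly, feeding the
end-state per-age stage proportions back as the initial split until the
proportions change by less than `limit_tol` (default $10^{-8}$, sup-norm,
at most `max_iter = 200` runs). Because stage-specific mortality differs,
the derived incidence depends on the split, so each feedback iteration
re-derives incidence. On horizons longer than the 30-year passage from 65
to 95+ the map loses almost all memory of its starting point and converges
in two or three runs; the suite checks that a uniform and an all-Mild start
agree within twice the tolerance.

The converged *aggregate* split has an independent characterisation: in a
stationary scenario the aggregate stage composition satisfies
$X = XP_{3\times3} + (X p_{death})\,e_{mild}$ — deaths are replaced by
incident Mild cases — so it equals the stationary distribution of the
"renewal" chain $R = P_{3\times3} + p_{death}\,e_{mild}^{\top}$. The test
suite exploits this as a brute-force power-iteration oracle on long
stationary scenarios (260 years, so that the geometric memory of the 95+
bin decays below $10^{-6}$).

## The cost model

**Medical.** Unit costs are EUR per *treated* patient per year, by stage ×
age band (65–69, 70–79, 80–89, 90+) × category (outpatient point-system
services, other outpatient services, medicines, inpatient point-system,
acute inpatient care, other inpatient care). The treated population is the
AD head count times a per-stage treated share, held constant over the
horizon. Costs are therefore exactly linear in head counts, in shares and
in unit costs.

**Non-medical.** Social care is costed at the *capacity* level:
residential services as beds × AD-utilisation share × EUR per bed-day ×
365, non-residential services as FTE × share × EUR per FTE-month × 12 (the
only annualisation consistent with the unit definitions). The base-year
capacity cost is scaled each year by the growth index
$g(t) = \text{AD}(t)/\text{AD}(t_0)$ — capacity is assumed to keep pace
with the AD population while unit costs stay at constant base-year prices,
undiscounted. The index uses the *total* AD population, matching the
stage-flat nature of social-care records.

**Reporting.** Totals are medical + non-medical at every granularity.
Per-person medical costs are stage-resolved; per-person non-medical costs
are the pooled non-medical cost over the total head count and are by
construction identical across stages, because social-care client records
carry no stage information. Where a stage-split of total costs is shown,
the non-medical pool is allocated to stages proportionally to head counts —
a presentation convention, not a data claim. Reports round per-person
figures to whole EUR and yearly totals to thousandths of millions;
internal arithmetic is full precision.

The package ships the published cost tables of two Czech regions,
Kralovehradecky kraj (`khk`) and Kraj Vysocina (`vys`) — medical unit
costs at 2017 prices, service inventories at 2019–2020 prices, and the
published yearly and per-person summaries — as worked-example fixtures
(`fixture_medical_costs()`, `fixture_services()`, `fixture_cost_summary()`,
`fixture_per_person_summary()`). One published total (VYS 2020) differs
from the sum of its components by one display unit (38.484 vs 38.485
million EUR); exact checks exclude that cell.

## The synthetic-data generator

Real regional inputs (statistical-office projections, prevalence studies,
clinically estimated transition probabilities, insurer treated shares) are
not freely machine-readable, so `synthetic_spec()` fixes a fully seeded
synthetic region:

* **Demography.** A Gompertz mortality schedule (hazard
  $1.6\times10^{-4} e^{0.075a}$), a stationary initial age profile with a
  newborn cohort near 5000 declining 0.8% per year, and a
  net-migration-like drift of +0.94%/yr for three decades then −0.56%/yr —
  the one-third rise of the 65+ population to mid-century followed by
  decline that Czech regional projections show. The 65+ share rises
  throughout and the total eventually declines.
* **Epidemiology.** Prevalence
  $p(a) = \min(\text{cap}, 0.008\,e^{0.13(a-65)})$ — the roughly
  exponential age trend of AD prevalence, reaching ~39% at 95+ (cap 0.6
  never binds below the top bin). Transitions: Mild stays 0.63 / progresses
  0.25 / dies 0.12; Moderate 0.45/0.30/0.25; Severe stays 0.60 / dies
  0.40 — within the range of published annual progression and mortality
  for AD stages.
* **Costs.** Random mode draws every unit cost and capacity within ±30% of
  the packaged KHK magnitudes; treated shares default to 0.20/0.35/0.50
  (Mild/Moderate/Severe) — plausible treated fractions, labelled synthetic
  because no regional values were ever published. `randomize = TRUE`
  additionally jitters the epidemiological and demographic parameters
  (deterministically from the seed) to emulate between-region variation.

**A consistency constraint worth stating.** Because one transition matrix
serves all ages while general-population mortality rises steeply with age,
a prevalence target is only reachable with non-negative incidence if AD
mortality in the aggregated 95+ bin is at least the bin's demographic
outflow rate ($1 - s_{top}$). The defaults satisfy this with margin
(AD mix mortality ≈ 0.29 vs outflow ≈ 0.20 plus drift); violating it does
not crash the model but produces logged zero-clamps at the top bin — the
known end-of-range artefact of an aggregated open cohort.

**What the generator does not emulate.** The initial age profile is
stationary, so the oldest-old compositional bulge that real Czech cohorts
carry is absent; synthetic AD populations therefore grow far more mildly
(factor ≈ 1.2 over five decades) than real regional projections, which
roughly triple. Passing tests demonstrate the *mechanics* — calibration,
conservation, linearity, convergence — not the magnitude of real
demographic change. Nor does the generator attempt real geographic cost
variation: the cost side is anchored to one region's magnitudes.

## Numerical choices

* Calibration is closed-form; `calibration_tol` ($10^{-6}$ relative) is a
  verification threshold, not an iteration control.
* Incidence clamps to $[0,1]$ with a log entry; an empty feeder pool with
  positive required cases sets incidence 1 and flags the cell infeasible.
* Ages that carry no AD population keep their previous stage split during
  the limit-distribution iteration (their split is irrelevant downstream).
* The 95+ cohort is absorbing for both people and bookkeeping; the
  within-bin survival uses the hazard at age 96.5.
* Incident cases are capped at the projection's headroom at the attained
  age, so the AD population can never exceed the official cohort count.
* Ages below 65 carry zero prevalence and incidence.
* Row sums of transition matrices must be 1 within $10^{-9}$ (CSV-friendly
  but strict); Death must be exactly absorbing.
* Money is EUR end to end; rounding happens only at report time
  (half-up, whole EUR per person, three decimals for millions).

## Problem sizes in the test suite

The suite runs the full pipeline on 20 randomised 53-year scenarios for
the calibration round-trip, 10 random progressive matrices on 260-year
stationary scenarios for the limit-distribution oracle, and factor-2
perturbations for the linearity checks; the whole suite completes in well
under a minute on one core. These sizes were chosen as the smallest that
exercise every mechanism at full fidelity — each scenario still carries
the complete 96-cohort age structure.

## Known limitations

* Medical unit costs (2017 prices) and social-care costs (2019–2020
  prices) are combined without a price-level adjustment, and no discounting
  or inflation is applied: results are constant-price planning figures,
  not present values.
* Indirect costs — productivity losses of patients and informal
  caregivers — are out of scope, as is the MCI prodrome and any reverse or
  skip stage transition.
* Treated shares and the transition matrix are inputs, not estimates; the
  package fits nothing to individual-level data.
* A single age-invariant transition matrix understates mortality
  differences at extreme ages; its interaction with the aggregated 95+
  cohort is the one place the calibration can become infeasible (logged,
  never silent).
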