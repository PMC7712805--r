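# adburden

Projection of regional Alzheimer's disease (AD) populations and the direct
costs of their care, for health-economic and long-term-care capacity
planning.

The package is built around a two-pillar pipeline:

1. **Population pillar** — a deterministic age-structured multi-state
   cohort model. People aged 65 to 95+ are tracked by single year of age in
   three ordered disease stages (Mild, Moderate, Severe) with an absorbing
   Death state and a 4×4 one-year transition matrix *P*. Age-specific
   incidence is not an input: it is back-calculated, in closed form, so
   that a baseline run reproduces an age-specific prevalence target
   *p(a)* against the official population projection *N(a, t)*,

   required(a, t+1) = p(a) N(a, t+1) − survivors(a, t+1),
   ι(a, t) = required / disease-free pool, clamped to [0, 1].

   The initial split of patients across stages is the limit distribution of
   the stage process: the simulation is re-run with its own end-state
   proportions fed back until they converge.
2. **Cost pillar** — annual direct medical costs (EUR per treated patient
   by stage × age band × category, times constant per-stage treated
   shares) and direct non-medical costs (residential beds × AD share × EUR
   per bed-day × 365 plus non-residential FTE × share × EUR per FTE-month
   × 12, scaled by the AD population growth index), reported in constant
   prices without discounting, overall, by stage and per person.

A fully seeded synthetic-data generator supplies internally consistent
inputs (projection, prevalence, transition matrix, cost tables), and the
published cost tables of two Czech regions (KHK, VYS) are packaged for
worked examples. See the vignette `vignettes/ad-cost-projection.Rmd` for
the model's assumptions, numerical choices and limitations.

## Worked example

```r
library(adburden)

cfg  <- generate_scenario(synthetic_spec(seed = 1, randomize = TRUE))
traj <- run_projection(cfg)
traj
#> ad_trajectory: region 'synthia', years 2020-2071
#>   AD population 2020: 4157.6 -> 2071: 4892.5 (factor 1.18)

costs <- project_costs(cfg, traj)
costs
#> cost_projection: region 'synthia', years 2020-2071
#>   2020: medical 1.330 M, non-medical 19.874 M, total 21.203 M EUR
#>   2071: medical 1.565 M, non-medical 23.386 M, total 24.951 M EUR

per_person_costs(costs, 2020)
#>    region    stage medical_eur_pp nonmedical_eur_pp total_eur_pp
#> 1 synthia     mild       224.1573          4780.047     5004.205
#> 2 synthia moderate       276.7028          4780.047     5056.750
#> 3 synthia   severe       621.0873          4780.047     5401.135
#> 4 synthia      all       319.8039          4780.047     5099.851
```

The trajectory is the simulated AD population by year, age and stage: here
a synthetic region whose AD population rises from ~4158 to a mid-century
peak (~5253 in 2045) and then declines with the overall population.
Medical costs per person are stage-resolved; non-medical costs per person
are identical across stages because social-care records carry no stage
information — their dominance over medical costs (here ~15:1 at synthetic
KHK-like capacities; 5:1 and 8.5:1 in the packaged KHK/VYS summaries) is
the central planning message of this kind of model.

Reading real inputs instead of generating them:

```r
cfg <- read_scenario("scenario.yaml")   # CSV paths resolved relative to the YAML
run_scenario(cfg, "out/")               # trajectory, cost tables, manifest
```

A thin command-line wrapper with the same steps (`synth`, `simulate`,
`costs`, `report`; exit codes 0/2/3 for success / schema error /
convergence failure) is installed at `inst/cli/adburden.R`.

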