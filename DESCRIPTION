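Package: adburden
Title: Multi-State Cohort Projection of Alzheimer's Disease Populations
    and Direct Care Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the number of people living with Alzheimer's disease
    (AD) in a region from an official single-year-of-age population
    projection, using a deterministic multi-state cohort model with Mild,
    Moderate and Severe disease stages and an absorbing Death state.
    Age-specific incidence is back-calculated from a prevalence target in a
    baseline run, and the initial split of patients across stages is obtained
    as the limit distribution of the stage process. A companion cost model
    converts the projected AD population into annual direct medical costs
    (per-treated-patient unit costs by stage and age band) and direct
    non-medical costs (residential bed-day and non-residential FTE-month
    social-service capacity, scaled with AD population growth), reported in
    constant prices without discounting. Includes a seeded synthetic-data
    generator, packaged regional cost tables for two Czech regions, CSV/YAML
    readers and writers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
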