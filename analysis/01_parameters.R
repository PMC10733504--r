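#!/usr/bin/env Rscript
# Stage 1 — model inputs and derived economic constants.
#
# Exports the full calibrated parameter set (costs in 2021 USD, branch
# probabilities, utilities) with provenance tags, and reproduces the derived
# economic constants: the per-person screening cost, the implied income
# growth rates, the calibrated discounted-lifetime factor and the lifetime
# values it generates, the deaf lifetime QALY and the willingness-to-pay
# threshold.

suppressPackageStartupMessages(library(deafscreenCEA))
dir.create("results", showWarnings = FALSE)

params <- default_parameters()
write_parameters(params, "results/parameters.json")

v <- params$values
derived <- data.frame(
  quantity = c(
    "per_person_screening_cost_usd",
    "income_growth_rate_2018_2021",
    "disabled_medical_growth_rate_2019_2021",
    "calibrated_lifetime_factor",
    "lifetime_income_healthy_usd",
    "lifetime_medical_disabled_usd",
    "healthy_lifetime_qaly",
    "deaf_lifetime_qaly",
    "wtp_per_life_usd"),
  value = c(
    per_person_screening_cost(params),
    growth_rate(4213.10, 5243.00, 3),
    growth_rate(402.50, 505.20, 2),
    v[["u.lifetime_factor"]],
    lifetime_value(5243.00, v[["u.lifetime_factor"]]),
    lifetime_value(505.20, v[["u.lifetime_factor"]]),
    v[["u.healthy_qaly"]],
    derive_deaf_qaly(v[["u.healthy_qaly"]], v[["u.deaf_utility_weight"]],
                     rounded = TRUE),
    derive_wtp(v[["u.gdp_per_capita"]], v[["u.wtp_multiplier"]],
               v[["u.healthy_qaly"]])))
write_table(derived, "results/derived_constants.csv")
run_manifest("parameters", params,
             outputs = c("results/parameters.json",
                         "results/derived_constants.csv"),
             path = "results/manifest_01.json")

cat("Derived economic constants:\n")
print(transform(derived, value = signif(value, 6)), row.names = FALSE)
cat("\nScreening one person costs", per_person_screening_cost(params),
    "USD; a whole discounted healthy life is valued at",
    derive_wtp(v[["u.gdp_per_capita"]], v[["u.wtp_multiplier"]],
               v[["u.healthy_qaly"]]), "USD.\n")
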