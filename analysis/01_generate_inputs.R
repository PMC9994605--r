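#!/usr/bin/env Rscript
# Generate the synthetic input bundle: CISNET-style initiation/cessation
# surfaces, Gompertz-Makeham baseline mortality, hazard ratios, the 1997
# baseline populations for the SPD and no-SPD strata, and noisy survey
# prevalence targets generated from a known SPD scaling-factor truth.
#
# Writes results/inputs/ (CSV + JSON). Deterministic given the seed.

library(spdsmoke)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

dir.create("results", showWarnings = FALSE)
cfg <- synthetic_config(seed = seed)
generate_fixtures("results/inputs", cfg)

base <- make_baseline_population(cfg)
tg <- read_targets_csv("results/inputs/targets.csv")

message(sprintf("wrote results/inputs (seed %d)", seed))
message(sprintf("  base-year population: %.0f (SPD %.0f, no-SPD %.0f)",
                cfg$pop_size, sum(base$SPD$counts), sum(base$NoSPD$counts)))
message(sprintf("  survey targets: %d rows, %d-%d, SPD adult prevalence %.1f%% -> %.1f%%",
                nrow(tg), min(tg$year), max(tg$year),
                100 * mean(tg$prevalence[tg$year == min(tg$year)]),
                100 * mean(tg$prevalence[tg$year == max(tg$year)])))
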