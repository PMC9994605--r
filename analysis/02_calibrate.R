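#!/usr/bin/env Rscript
# Calibrate the SPD stratum's initiation/cessation scaling factors to the
# survey prevalence targets by least squares (the no-SPD stratum keeps the
# unscaled schedule, factors = 1).
#
# Reads results/inputs/, writes results/calibration.json.

library(spdsmoke)

inputs <- "results/inputs"
for (f in c("rates.csv", "baseline_mortality.csv", "population_spd.csv",
            "targets.csv", "config.json"))
  if (!file.exists(file.path(inputs, f)))
    stop("missing input file: ", file.path(inputs, f),
         " (run 01_generate_inputs.R first)", call. = FALSE)

cfgj <- jsonlite::read_json(file.path(inputs, "config.json"),
                            simplifyVector = TRUE)
rates <- read_rates_csv(file.path(inputs, "rates.csv"))
mort <- read_baseline_csv(file.path(inputs, "baseline_mortality.csv"),
                          hr_current = matrix(cfgj$hr_current, 5, 2),
                          hr_spd = cfgj$hr_spd, lambda = cfgj$lambda)
baseline <- read_population_csv(file.path(inputs, "population_spd.csv"))
targets <- read_targets_csv(file.path(inputs, "targets.csv"))
births <- synthetic_births(synthetic_config(seed = cfgj$seed))$SPD

cal <- calibrate(rates, mort, baseline,
                 targets[targets$stratum == "SPD", ], births = births)
write_calibration_json(cal, "results/calibration.json")

message(sprintf("calibration %s: SSE %.4g after %d objective evaluations",
                cal$message, cal$sse, cal$evaluations))
print(cal$factors)
if (!cal$converged) quit(status = 1)
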