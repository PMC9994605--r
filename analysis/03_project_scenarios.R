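#!/usr/bin/env Rscript
# Project both strata from 1997 to 2100 under the Status Quo, No Initiation
# and MPRPM scenarios, and tabulate the annual outcome series (prevalence,
# smoking-attributable deaths and fraction, years of life lost, cumulative
# totals from 2023).
#
# Reads results/inputs/ and results/calibration.json; writes
# results/outcomes.csv and results/life_tables.csv.

library(spdsmoke)

inputs <- "results/inputs"
cfgj <- jsonlite::read_json(file.path(inputs, "config.json"),
                            simplifyVector = TRUE)
rates <- read_rates_csv(file.path(inputs, "rates.csv"))
mort <- read_baseline_csv(file.path(inputs, "baseline_mortality.csv"),
                          hr_current = matrix(cfgj$hr_current, 5, 2),
                          hr_spd = cfgj$hr_spd, lambda = cfgj$lambda)
if (!file.exists("results/calibration.json"))
  stop("missing results/calibration.json (run 02_calibrate.R first)",
       call. = FALSE)
factors <- list(SPD = read_calibration_json("results/calibration.json"),
                NoSPD = scaling_factors())
baseline <- list(
  SPD = read_population_csv(file.path(inputs, "population_spd.csv")),
  NoSPD = read_population_csv(file.path(inputs, "population_nospd.csv"))
)
births <- synthetic_births(synthetic_config(seed = cfgj$seed))

scenarios <- list(status_quo = scenario_status_quo(),
                  no_initiation = scenario_no_initiation(),
                  mprpm = scenario_mprpm())

all_outcomes <- list()
for (stratum in c("SPD", "NoSPD")) {
  r <- apply_scaling(rates, factors[[stratum]])
  for (nm in names(scenarios)) {
    traj <- project(baseline[[stratum]], r, mort, scenarios[[nm]],
                    end_year = 2100, births = births[[stratum]])
    all_outcomes[[paste(stratum, nm)]] <-
      outcome_series(traj, mort, scenario_name = nm)
    message(sprintf("%-6s %-14s adult prevalence 2023 %5.1f%% -> 2100 %5.1f%%",
                    stratum, nm,
                    100 * smoking_prevalence(traj[["2023"]]),
                    100 * smoking_prevalence(traj[["2100"]])))
  }
}
outcomes <- do.call(rbind, all_outcomes)
write_outcomes_csv(outcomes, "results/outcomes.csv")

lt <- rbind(
  within(as.data.frame(as.table(
    build_life_table(mort, "SPD", 2023)$e_ns)), stratum <- "SPD"),
  within(as.data.frame(as.table(
    build_life_table(mort, "NoSPD", 2023)$e_ns)), stratum <- "NoSPD")
)
names(lt)[1:3] <- c("age", "gender", "e_ns")
utils::write.csv(lt, "results/life_tables.csv", row.names = FALSE)

sq <- outcomes[outcomes$scenario == "status_quo" & outcomes$gender == "all" &
                 outcomes$stratum == "SPD" & outcomes$year == 2100, ]
message("Status Quo cumulative SPD burden 2023-2100: ",
        format_burden_text(sq$cum_sad, sq$cum_yll))
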