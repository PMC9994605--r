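#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates inputs, calibrates the SPD stratum's scaling factors to the
#' survey targets (the no-SPD stratum keeps factors fixed at 1), projects
#' both strata to `end_year` under the Status Quo, No Initiation and MPRPM
#' scenarios, and assembles outcome series, the disparity report and the
#' cessation-vs-initiation decomposition tables.
#'
#' @param config A [synthetic_config()].
#' @param true_factors Generating SPD factors for the synthetic survey
#'   targets.
#' @param run_calibration If `FALSE`, skip the optimizer and use
#'   `true_factors` directly for the SPD projection (useful for fast
#'   smoke runs).
#' @param end_year Projection horizon (default 2100).
#' @param milestones Years reported in the disparity and decomposition
#'   tables.
#' @param scenarios Named list of [scenario_spec()] objects (defaults to the
#'   three study scenarios).
#' @param ... Passed on to [calibrate()] (e.g. `max_eval`).
#' @return List with elements `config`, `rates`, `mort`, `baseline`,
#'   `targets`, `calibration` (or `NULL`), `factors` (per stratum),
#'   `trajectories` (`[stratum]][[scenario]]`), `outcomes` (row-bound
#'   [outcome_series()]), `disparity` ([disparity_report()], Status Quo),
#'   and `decomposition` (per stratum, [decomposition_table()]).
#' @export
run_pipeline <- function(config = synthetic_config(),
                         true_factors = spd_true_factors(),
                         run_calibration = TRUE,
                         end_year = 2100,
                         milestones = c(2023, 2040, 2060, 2080, 2100),
                         scenarios = NULL, ...) {
  rates <- make_rate_surfaces(config)
  mort <- make_mortality_model(config)
  baseline <- make_baseline_population(config, true_factors)
  births <- synthetic_births(config)
  tg <- make_survey_targets(config, true_factors)

  if (run_calibration) {
    cal <- calibrate(rates, mort, baseline$SPD,
                     tg$targets[tg$targets$stratum == "SPD", ],
                     births = births$SPD, ...)
    spd_factors <- cal$factors
  } else {
    cal <- NULL
    spd_factors <- true_factors
  }
  factors <- list(SPD = spd_factors, NoSPD = scaling_factors())

  if (is.null(scenarios))
    scenarios <- list(status_quo = scenario_status_quo(),
                      no_initiation = scenario_no_initiation(),
                      mprpm = scenario_mprpm())

  trajectories <- list()
  outcomes <- list()
  for (stratum in STRATA) {
    r <- apply_scaling(rates, factors[[stratum]])
    trajectories[[stratum]] <- lapply(scenarios, function(sc)
      project(baseline[[stratum]], r, mort, sc, end_year = end_year,
              births = births[[stratum]]))
    outcomes[[stratum]] <- lapply(names(scenarios), function(nm)
      outcome_series(trajectories[[stratum]][[nm]], mort, scenario_name = nm))
    names(outcomes[[stratum]]) <- names(scenarios)
  }

  disparity <- disparity_report(trajectories$SPD$status_quo,
                                trajectories$NoSPD$status_quo,
                                years = milestones)
  decomposition <- lapply(STRATA, function(stratum)
    decomposition_table(outcomes[[stratum]]$status_quo,
                        outcomes[[stratum]]$no_initiation,
                        outcomes[[stratum]]$mprpm,
                        years = setdiff(milestones, config$base_year)))
  names(decomposition) <- STRATA

  list(config = config, rates = rates, mort = mort, baseline = baseline,
       targets = tg, calibration = cal, factors = factors,
       trajectories = trajectories,
       outcomes = do.call(rbind, unlist(outcomes, recursive = FALSE)),
       disparity = disparity, decomposition = decomposition)
}
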