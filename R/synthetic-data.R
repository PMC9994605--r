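#' Synthetic-data configuration
#'
#' Parameters for the synthetic input generator, which emulates the
#' statistical structure of the real inputs (CISNET-style age-cohort
#' initiation/cessation surfaces, Gompertz-Makeham baseline mortality,
#' multiplicative hazard ratios, SPD population proportions, and noisy
#' survey prevalence targets) without reproducing any real file.
#'
#' Initiation is unimodal in age (log-normal-shaped curve peaking at
#' `init_peak_age`, zero below 10 and at 35+) with a peak height that
#' declines across birth cohorts (logistic from `init_peak_early` to
#' `init_peak_late` centred at `init_cohort_mid`). Cessation rises
#' logistically with age from 18 and rises across cohorts (multiplier from
#' `cess_cohort_lo` to `cess_cohort_hi`). The defaults were chosen once so
#' that the Status Quo forward model tracks the broad historical course of US adult
#' smoking (roughly a quarter of no-SPD adults smoking in 1997, about 14%
#' by 2018) and, with the default SPD scaling factors, an SPD-to-no-SPD
#' prevalence ratio of about 2.5-3 in the 2010s.
#'
#' @param seed Integer seed; the only entropy source (used for target
#'   noise). Fixed seed implies bit-identical outputs.
#' @param pop_size Total base-year population across ages, genders and
#'   strata.
#' @param base_year First simulated year (default 1997).
#' @param calib_end Last survey year for calibration targets (default 2018).
#' @param cohorts Birth cohorts covered by the rate surfaces.
#' @param init_peak_age,init_age_spread Age location/spread of the
#'   initiation curve.
#' @param init_peak_early,init_peak_late,init_cohort_mid,init_cohort_scale
#'   Cohort trend of the initiation peak height (declining).
#' @param init_male_mult Male-to-female multiplier on initiation.
#' @param cess_base,cess_max,cess_age_mid,cess_age_scale Age profile of
#'   cessation.
#' @param cess_cohort_lo,cess_cohort_hi,cess_cohort_mid,cess_cohort_scale
#'   Cohort multiplier on cessation (rising).
#' @param gompertz_a Gompertz level by gender (named vector female/male).
#' @param gompertz_b Gompertz slope (per year of age).
#' @param makeham_c Age-independent background mortality.
#' @param hr_current Hazard ratio current-vs-never by age band (recycled
#'   over genders).
#' @param hr_spd SPD-vs-no-SPD hazard ratio.
#' @param lambda Former-smoker excess-risk decay rate per year since quit
#'   (default halves every ~5 years).
#' @param spd_prop `5 x 2` matrix of SPD population proportions by age band
#'   and gender; defaults to the published survey proportions.
#' @param noise_sd Gaussian noise SD added to survey prevalence targets.
#' @return An object of class `spd_synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             pop_size = 1e6,
                             base_year = 1997L,
                             calib_end = 2018L,
                             cohorts = 1890:2020,
                             init_peak_age = 17,
                             init_age_spread = 0.55,
                             init_peak_early = 0.14,
                             init_peak_late = 0.002,
                             init_cohort_mid = 1985,
                             init_cohort_scale = 5,
                             init_male_mult = 1.12,
                             cess_base = 0.015,
                             cess_max = 0.10,
                             cess_age_mid = 45,
                             cess_age_scale = 12,
                             cess_cohort_lo = 0.7,
                             cess_cohort_hi = 2.2,
                             cess_cohort_mid = 1960,
                             cess_cohort_scale = 20,
                             gompertz_a = c(female = 1.6e-5, male = 2.6e-5),
                             gompertz_b = 0.095,
                             makeham_c = 5e-4,
                             hr_current = c(2.8, 2.8, 2.6, 2.2, 1.7),
                             hr_spd = 1.3,
                             lambda = log(2) / 5,
                             spd_prop = NULL,
                             noise_sd = 0.01) {
  if (is.null(spd_prop)) {
    spd_prop <- cbind(
      female = c(0.033, 0.044, 0.046, 0.029, 0.028),
      male   = c(0.021, 0.029, 0.032, 0.019, 0.019)
    )
    rownames(spd_prop) <- AGE_BAND_NAMES
  }
  spd_prop <- as.matrix(spd_prop)
  if (!identical(dim(spd_prop), c(5L, 2L)))
    stop("`spd_prop` must be a 5 x 2 matrix (age band x gender)",
         call. = FALSE)
  if (any(spd_prop <= 0 | spd_prop >= 1))
    stop("`spd_prop` proportions must lie in (0, 1)", call. = FALSE)
  if (init_peak_early < init_peak_late)
    stop("initiation peak must decline across cohorts", call. = FALSE)
  if (cess_cohort_hi < cess_cohort_lo)
    stop("cessation cohort multiplier must rise across cohorts",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  cfg <- list(seed = as.integer(seed), pop_size = pop_size,
              base_year = as.integer(base_year),
              calib_end = as.integer(calib_end),
              cohorts = as.integer(cohorts),
              init_peak_age = init_peak_age,
              init_age_spread = init_age_spread,
              init_peak_early = init_peak_early,
              init_peak_late = init_peak_late,
              init_cohort_mid = init_cohort_mid,
              init_cohort_scale = init_cohort_scale,
              init_male_mult = init_male_mult,
              cess_base = cess_base, cess_max = cess_max,
              cess_age_mid = cess_age_mid, cess_age_scale = cess_age_scale,
              cess_cohort_lo = cess_cohort_lo,
              cess_cohort_hi = cess_cohort_hi,
              cess_cohort_mid = cess_cohort_mid,
              cess_cohort_scale = cess_cohort_scale,
              gompertz_a = gompertz_a, gompertz_b = gompertz_b,
              makeham_c = makeham_c,
              hr_current = hr_current, hr_spd = hr_spd, lambda = lambda,
              spd_prop = spd_prop, noise_sd = noise_sd)
  class(cfg) <- "spd_synthetic_config"
  cfg
}

#' Default generating truth for the SPD stratum
#'
#' Scaling factors used to generate the SPD stratum's synthetic data:
#' higher initiation and lower cessation than the no-SPD schedule, sized so
#' the SPD adult prevalence runs about 2.5-3 times the no-SPD prevalence in
#' the 2010s.
#'
#' @return A [scaling_factors()] object.
#' @export
spd_true_factors <- function() {
  scaling_factors(
    init_scale = matrix(c(2.2, 1, 1, 1, 1), 5, 2),
    cess_scale = matrix(0.45, 5, 2)
  )
}

#' Generate synthetic initiation/cessation rate surfaces
#'
#' @param config A [synthetic_config()].
#' @return A [rate_schedule()].
#' @export
make_rate_surfaces <- function(config) {
  ck <- config$cohorts
  n_cohort <- length(ck)
  ## age shape of initiation: log-normal-like bump peaking at init_peak_age
  age_shape <- numeric(N_AGE)
  ia <- AGES >= MIN_INITIATION_AGE & AGES <= MAX_INITIATION_AGE
  off <- AGES[ia] - (MIN_INITIATION_AGE - 1L)
  peak_off <- config$init_peak_age - (MIN_INITIATION_AGE - 1L)
  age_shape[ia] <- exp(-((log(off) - log(peak_off))^2) /
                         (2 * config$init_age_spread^2))
  ## cohort trend: peak height declines logistically across cohorts
  peak <- config$init_peak_late +
    (config$init_peak_early - config$init_peak_late) /
    (1 + exp((ck - config$init_cohort_mid) / config$init_cohort_scale))
  init <- array(0, c(N_AGE, N_GENDER, n_cohort))
  for (j in seq_len(n_cohort)) {
    init[, 1, j] <- age_shape * peak[j]
    init[, 2, j] <- pmin(age_shape * peak[j] * config$init_male_mult, 1)
  }
  ## cessation: logistic rise in age from 18, cohort multiplier rising
  cess_age <- numeric(N_AGE)
  ca <- AGES >= MIN_CESSATION_AGE
  cess_age[ca] <- config$cess_base +
    (config$cess_max - config$cess_base) /
    (1 + exp(-(AGES[ca] - config$cess_age_mid) / config$cess_age_scale))
  cmult <- config$cess_cohort_lo +
    (config$cess_cohort_hi - config$cess_cohort_lo) /
    (1 + exp(-(ck - config$cess_cohort_mid) / config$cess_cohort_scale))
  cess <- array(0, c(N_AGE, N_GENDER, n_cohort))
  for (j in seq_len(n_cohort)) {
    cess[, 1, j] <- pmin(cess_age * cmult[j], 1)
    cess[, 2, j] <- pmin(cess_age * cmult[j], 1)
  }
  rate_schedule(init, cess, ck)
}

#' Generate the synthetic mortality model
#'
#' Gompertz-Makeham baseline `m0(a) = A exp(B a) + C` by gender, constant
#' over calendar years, with the configured hazard ratios.
#'
#' @param config A [synthetic_config()].
#' @return A [mortality_model()].
#' @export
make_mortality_model <- function(config) {
  m0 <- array(0, c(N_AGE, N_GENDER, 1L))
  for (g in seq_len(N_GENDER))
    m0[, g, 1] <- pmin(config$gompertz_a[[GENDERS[g]]] *
                         exp(config$gompertz_b * AGES) + config$makeham_c, 1)
  mortality_model(m0, years = config$base_year,
                  hr_current = matrix(config$hr_current, 5, 2),
                  hr_spd = config$hr_spd, lambda = config$lambda)
}

## SPD share for every single year of age (ages < 18 read the youngest band)
spd_share_by_age <- function(config) {
  config$spd_prop[age_band_index(AGES), , drop = FALSE]
}

#' Annual birth inflow implied by the stationary synthetic population
#'
#' Constant annual birth counts per gender and stratum, sized so the
#' stationary age pyramid used by [make_baseline_population()] is
#' replenished, and split between strata by the youngest age band's SPD
#' proportion.
#'
#' @param config A [synthetic_config()].
#' @return List with numeric length-2 vectors `SPD` and `NoSPD`.
#' @export
synthetic_births <- function(config) {
  mort <- make_mortality_model(config)
  lt_l <- survivorship(mort, config$base_year)
  per_gender <- (config$pop_size / 2) / colSums(lt_l)
  share0 <- spd_share_by_age(config)[1, ]
  list(SPD = per_gender * share0, NoSPD = per_gender * (1 - share0))
}

## survivorship l(a) per gender from the no-SPD never-smoker baseline
survivorship <- function(mort, year) {
  m0 <- baseline_for_year(mort, year)
  apply(m0, 2, function(q) cumprod(c(1, 1 - q[-N_AGE])))
}

#' Generate the base-year population for both strata
#'
#' Builds a stationary age pyramid from the baseline survivorship, splits it
#' between the SPD and no-SPD strata by the configured age-band
#' proportions, and assigns each cohort a smoking-state mix (never /
#' current / former by ysq) by replaying that cohort's initiation and
#' cessation schedule up to its base-year age (differential mortality by
#' smoking state is ignored in this replay; the pyramid carries the overall
#' mortality structure).
#'
#' @param config A [synthetic_config()].
#' @param spd_factors [scaling_factors()] applied to the SPD stratum's
#'   schedule (default [spd_true_factors()]).
#' @return List with [population_state()] elements `SPD` and `NoSPD`.
#' @export
make_baseline_population <- function(config, spd_factors = spd_true_factors()) {
  rates <- make_rate_surfaces(config)
  mort <- make_mortality_model(config)
  l <- survivorship(mort, config$base_year)
  pyramid <- sweep(l, 2, (config$pop_size / 2) / colSums(l), `*`)
  share <- spd_share_by_age(config)
  out <- list()
  for (stratum in STRATA) {
    r <- if (stratum == "SPD") apply_scaling(rates, spd_factors) else rates
    w <- if (stratum == "SPD") share else 1 - share
    cnt <- array(0, c(N_AGE, N_GENDER, N_STATE))
    for (g in seq_len(N_GENDER)) {
      for (a in AGES) {
        mix <- cohort_smoking_mix(r, config$base_year - a, a, g)
        cnt[a + 1L, g, ] <- pyramid[a + 1L, g] * w[a + 1L, g] * mix
      }
    }
    out[[stratum]] <- population_state(config$base_year, cnt, stratum)
  }
  out
}

## Smoking-state mix (length N_STATE, sums to 1) of a cohort at a given age,
## obtained by replaying the cohort's transition schedule from birth using
## the engine's conventions (transitions at age x feed the state at x + 1;
## ysq increments before new quitters enter ysq = 1).
cohort_smoking_mix <- function(rates, cohort, age, gender_idx) {
  mix <- numeric(N_STATE)
  mix[1] <- 1
  if (age == 0L) return(mix)
  j <- match(cohort, rates$cohorts)
  if (is.na(j))
    stop("missing rate entry for birth cohort ", cohort, call. = FALSE)
  for (x in 0:(age - 1L)) {
    p_i <- rates$initiation[x + 1L, gender_idx, j]
    p_c <- rates$cessation[x + 1L, gender_idx, j]
    starts <- mix[1] * p_i
    quits <- mix[2] * p_c
    former <- mix[3:N_STATE]
    mix[3:N_STATE] <- c(quits, former[1:(YSQ_MAX - 2L)],
                        former[YSQ_MAX - 1L] + former[YSQ_MAX])
    mix[1] <- mix[1] - starts
    mix[2] <- mix[2] - quits + starts
  }
  mix
}

#' Generate noisy survey prevalence targets from a known truth
#'
#' Runs the forward model from the base year with the true SPD scaling
#' factors applied, samples adult current-smoking prevalence for every
#' survey year, gender and stratum (by age band when `by_band = TRUE`), and
#' adds independent Gaussian noise truncated to (0, 1). The generating
#' truth is returned alongside the targets for recovery experiments.
#'
#' @param config A [synthetic_config()].
#' @param true_factors [scaling_factors()] generating the SPD stratum
#'   (default [spd_true_factors()]).
#' @param by_band Resolve targets by adult age band (default `TRUE`).
#' @param strata Which strata to emit targets for (default SPD only, the
#'   stratum that gets calibrated).
#' @return List with `targets` (a [prevalence_targets()] data frame),
#'   `truth` (the generating factors), and `noiseless` (the pre-noise
#'   model prevalences, same row order).
#' @export
make_survey_targets <- function(config, true_factors = spd_true_factors(),
                                by_band = TRUE, strata = "SPD") {
  rates <- make_rate_surfaces(config)
  mort <- make_mortality_model(config)
  base <- make_baseline_population(config, true_factors)
  births <- synthetic_births(config)
  years <- config$base_year:config$calib_end
  bands <- if (by_band) AGE_BAND_NAMES else NA_character_
  band_rng <- age_bands()
  rows <- list()
  for (stratum in strata) {
    r <- if (stratum == "SPD") apply_scaling(rates, true_factors) else rates
    traj <- project(base[[stratum]], r, mort, scenario_status_quo(),
                    end_year = config$calib_end, births = births[[stratum]])
    for (g in GENDERS) for (b in bands) {
      rng <- if (is.na(b)) c(18L, 99L) else range(band_rng[[b]])
      prev <- vapply(years, function(y)
        smoking_prevalence(traj[[as.character(y)]], g, rng[1], rng[2]),
        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        year = years, gender = g, stratum = stratum, age_band = b,
        prevalence = prev)
    }
  }
  df <- do.call(rbind, rows)
  noiseless <- df$prevalence
  if (config$noise_sd > 0) {
    set.seed(config$seed)
    df$prevalence <- pmin(pmax(
      df$prevalence + stats::rnorm(nrow(df), 0, config$noise_sd),
      1e-4), 1 - 1e-4)
  }
  list(targets = prevalence_targets(df), truth = true_factors,
       noiseless = noiseless)
}

#' Write the full synthetic input bundle to a directory
#'
#' Emits `rates.csv`, `baseline_mortality.csv`, `hazard_ratios.csv`,
#' `population_spd.csv`, `population_nospd.csv`, `targets.csv` and a
#' `config.json` echo of the generator settings.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @param true_factors Generating SPD factors.
#' @return The directory path, invisibly.
#' @export
generate_fixtures <- function(dir, config = synthetic_config(),
                              true_factors = spd_true_factors()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rates <- make_rate_surfaces(config)
  mort <- make_mortality_model(config)
  base <- make_baseline_population(config, true_factors)
  tg <- make_survey_targets(config, true_factors)
  write_rates_csv(rates, file.path(dir, "rates.csv"))
  write_baseline_csv(mort, file.path(dir, "baseline_mortality.csv"))
  utils::write.csv(
    data.frame(gender = rep(GENDERS, each = 5),
               age_band = rep(AGE_BAND_NAMES, 2),
               hr_current = as.vector(mort$hr_current)),
    file.path(dir, "hazard_ratios.csv"), row.names = FALSE)
  write_population_csv(base$SPD, file.path(dir, "population_spd.csv"))
  write_population_csv(base$NoSPD, file.path(dir, "population_nospd.csv"))
  write_targets_csv(tg$targets, file.path(dir, "targets.csv"))
  echo <- config
  class(echo) <- NULL
  echo$spd_prop <- as.data.frame(as.table(config$spd_prop),
                                 stringsAsFactors = FALSE)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
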