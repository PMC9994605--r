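#' Scenario specification
#'
#' Named counterfactual switches applied on top of the rate schedule:
#' `rate_freeze_year` (all later years read the frozen age profile),
#' `initiation_shutoff_year` (initiation is zero in every transition year
#' `>= initiation_shutoff_year`), and `forced_cessation_year` (every current
#' smoker quits, at all ages, so that the state *in* that calendar year and
#' all later years has zero current smokers).
#'
#' @param name One of `"status_quo"`, `"no_initiation"`, `"mprpm"`.
#' @param rate_freeze_year Year whose age-specific probabilities are carried
#'   forward (default 2018).
#' @param initiation_shutoff_year First year with no new initiation, or
#'   `NULL`.
#' @param forced_cessation_year First year in which no current smokers
#'   remain, or `NULL`.
#' @return An object of class `spd_scenario`.
#' @export
scenario_spec <- function(name = c("status_quo", "no_initiation", "mprpm"),
                          rate_freeze_year = 2018,
                          initiation_shutoff_year = NULL,
                          forced_cessation_year = NULL) {
  name <- match.arg(name)
  if (!is.null(initiation_shutoff_year) &&
      initiation_shutoff_year < rate_freeze_year)
    stop("initiation shutoff must not precede the rate freeze", call. = FALSE)
  if (!is.null(forced_cessation_year) &&
      forced_cessation_year < rate_freeze_year)
    stop("forced cessation must not precede the rate freeze", call. = FALSE)
  if (name == "mprpm" &&
      (is.null(initiation_shutoff_year) || is.null(forced_cessation_year)))
    stop("mprpm requires both initiation shutoff and forced cessation years",
         call. = FALSE)
  structure(list(name = name,
                 rate_freeze_year = as.integer(rate_freeze_year),
                 initiation_shutoff_year =
                   if (!is.null(initiation_shutoff_year))
                     as.integer(initiation_shutoff_year),
                 forced_cessation_year =
                   if (!is.null(forced_cessation_year))
                     as.integer(forced_cessation_year)),
            class = "spd_scenario")
}

#' @rdname scenario_spec
#' @export
scenario_status_quo <- function(rate_freeze_year = 2018)
  scenario_spec("status_quo", rate_freeze_year)

#' @rdname scenario_spec
#' @param shutoff_year First year with no new initiation (default 2023).
#' @export
scenario_no_initiation <- function(shutoff_year = 2023, rate_freeze_year = 2018)
  scenario_spec("no_initiation", rate_freeze_year,
                initiation_shutoff_year = shutoff_year)

#' @rdname scenario_spec
#' @param cessation_year Year in which all smokers have quit (default 2024).
#' @export
scenario_mprpm <- function(shutoff_year = 2023, cessation_year = 2024,
                           rate_freeze_year = 2018)
  scenario_spec("mprpm", rate_freeze_year,
                initiation_shutoff_year = shutoff_year,
                forced_cessation_year = cessation_year)

#' @export
print.spd_scenario <- function(x, ...) {
  cat(sprintf("<spd_scenario> %s (freeze %d, shutoff %s, forced cessation %s)\n",
              x$name, x$rate_freeze_year,
              x$initiation_shutoff_year %||% "-",
              x$forced_cessation_year %||% "-"))
  invisible(x)
}

#' Advance a population state by one calendar year
#'
#' Applies, in order: (1) stratum- and smoking-state-specific mortality;
#' (2) initiation (never to current) and cessation (current to former, ysq 1)
#' with cohort-appropriate probabilities, zeroed or forced per scenario;
#' (3) increment of years-since-quit for those already former at the start
#' of the year, merging into the terminal 20+ bin; (4) aging by one year with
#' age-99 survivors exiting; (5) the new age-0 birth cohort entering as never
#' smokers. Deaths and age-99 exits are attached as attributes `deaths` and
#' `exits` so conservation can be audited: persons in = persons out + deaths
#' + exits - births.
#'
#' @param state A [population_state()] at year `t`.
#' @param rates A [rate_schedule()].
#' @param mort A [mortality_model()].
#' @param scenario A [scenario_spec()].
#' @param births Numeric length-2 vector (female, male) of newborns entering
#'   at age 0, or a `function(year)` returning one.
#' @return The [population_state()] at year `t + 1`.
#' @export
advance_year <- function(state, rates, mort, scenario = scenario_status_quo(),
                         births = c(0, 0)) {
  t <- state$year
  b <- if (is.function(births)) births(t + 1L) else births
  b <- rep_len(as.numeric(b), N_GENDER)
  if (any(b < 0)) stop("births must be nonnegative", call. = FALSE)

  ## (1) mortality
  q <- mortality_rate_array(mort, year = t, stratum = state$stratum)
  surv <- state$counts * (1 - q)
  deaths_total <- sum(state$counts) - sum(surv)

  ## (2) initiation / cessation at age attained in year t
  rt <- rates_for_year(rates, year = t, freeze_year = scenario$rate_freeze_year)
  p_init <- rt$initiation
  p_cess <- rt$cessation
  if (!is.null(scenario$initiation_shutoff_year) &&
      t >= scenario$initiation_shutoff_year)
    p_init[] <- 0
  if (!is.null(scenario$forced_cessation_year) &&
      (t + 1L) >= scenario$forced_cessation_year)
    p_cess[] <- 1 # all ages: everyone still smoking quits this year

  never <- surv[, , 1L]
  current <- surv[, , 2L]
  starts <- never * p_init
  quits <- current * p_cess

  ## (3) ysq increment for pre-existing former smokers (block shift into the
  ## terminal bin); new quitters enter ysq = 1
  post <- array(0, dim = c(N_AGE, N_GENDER, N_STATE))
  post[, , 1L] <- never - starts
  post[, , 2L] <- current - quits + starts
  post[, , 3L] <- quits
  post[, , 4:N_STATE] <- surv[, , 3:(N_STATE - 1L)]
  post[, , N_STATE] <- post[, , N_STATE] + surv[, , N_STATE]

  ## (4) aging; age-99 survivors exit
  nxt <- array(0, dim = c(N_AGE, N_GENDER, N_STATE))
  nxt[2:N_AGE, , ] <- post[1:(N_AGE - 1L), , ]
  exits <- sum(post[N_AGE, , ])

  ## (5) births
  nxt[1, , 1] <- b

  lo <- min(nxt)
  if (lo < 0) {
    if (lo < -1e-12 * max(sum(state$counts), 1))
      stop("internal invariant violation: negative counts after step",
           call. = FALSE)
    nxt[nxt < 0] <- 0 # scrub floating-point dust only
  }

  dimnames(nxt) <- list(age = AGES, gender = GENDERS, state = SMOKING_STATES)
  out <- structure(list(year = t + 1L, stratum = state$stratum, counts = nxt),
                   class = "spd_population")
  attr(out, "deaths") <- deaths_total
  attr(out, "exits") <- exits
  out
}

#' Project a population over a range of calendar years
#'
#' Repeatedly applies [advance_year()]; deterministic, one state per year
#' inclusive of both endpoints.
#'
#' @inheritParams advance_year
#' @param initial Initial [population_state()]; its `year` is the start.
#' @param end_year Final calendar year (`>= initial$year`).
#' @return An object of class `spd_trajectory`: list of states named by year.
#' @export
project <- function(initial, rates, mort, scenario = scenario_status_quo(),
                    end_year, births = c(0, 0)) {
  if (end_year < initial$year)
    stop("`end_year` must be >= the initial year", call. = FALSE)
  years <- initial$year:end_year
  out <- vector("list", length(years))
  names(out) <- years
  out[[1]] <- initial
  if (length(years) > 1L)
    for (i in 2:length(years))
      out[[i]] <- advance_year(out[[i - 1L]], rates, mort, scenario, births)
  structure(out, class = "spd_trajectory")
}

#' @export
print.spd_trajectory <- function(x, ...) {
  yrs <- as.integer(names(x))
  cat(sprintf("<spd_trajectory> %s, %d-%d (%d states)\n",
              x[[1]]$stratum, min(yrs), max(yrs), length(x)))
  invisible(x)
}

#' Adult current-smoking prevalence along a trajectory
#'
#' @param trajectory A [project()] result.
#' @inheritParams smoking_prevalence
#' @return Named numeric vector, one prevalence per year.
#' @export
prevalence_series <- function(trajectory, gender = NULL, age_lo = 18,
                              age_hi = 99) {
  vapply(trajectory, smoking_prevalence, numeric(1),
         gender = gender, age_lo = age_lo, age_hi = age_hi)
}
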