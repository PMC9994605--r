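#' Smoking-attributable deaths by age and gender
#'
#' Evaluates, cell by cell over age and gender,
#' `P * (prev_cs * (mu_cs - mu_ns) + sum_ysq prev_fs(ysq) * (mu_fs(ysq) -
#' mu_ns))` -- equivalently, excess mortality applied directly to the
#' current- and former-smoker counts, with the former term resolved by
#' years-since-quit bin.
#'
#' @param state A [population_state()].
#' @param mort A [mortality_model()].
#' @return `sad_by_age()`: `100 x 2` matrix of attributable deaths.
#'   `smoking_attributable_deaths()`: named vector `female`, `male`, `all`.
#' @export
sad_by_age <- function(state, mort) {
  q <- mortality_rate_array(mort, state$year, state$stratum)
  excess <- q[, , -1, drop = FALSE] - as.vector(q[, , "never"])
  sad <- matrix(0, N_AGE, N_GENDER, dimnames = list(age = AGES, gender = GENDERS))
  for (s in seq_len(N_STATE - 1L))
    sad <- sad + state$counts[, , s + 1L] * excess[, , s]
  sad
}

#' @rdname sad_by_age
#' @export
smoking_attributable_deaths <- function(state, mort) {
  sad <- sad_by_age(state, mort)
  c(colSums(sad), all = sum(sad))
}

#' Total deaths expected in a state-year
#'
#' Sum over all smoking states of count times death probability; the
#' denominator of the smoking-attributable fraction.
#'
#' @inheritParams sad_by_age
#' @param gender `"female"`, `"male"`, or `NULL` for both.
#' @return Scalar.
#' @export
total_deaths <- function(state, mort, gender = NULL) {
  q <- mortality_rate_array(mort, state$year, state$stratum)
  g <- if (is.null(gender)) GENDERS else match.arg(gender, GENDERS)
  sum(state$counts[, g, ] * q[, g, ])
}

#' Smoking-attributable fraction of deaths
#'
#' SAD divided by total deaths of the same stratum, gender and year.
#'
#' @inheritParams total_deaths
#' @return Fraction in `[0, 1]` (when hazard ratios are >= 1).
#' @export
smoking_attributable_fraction <- function(state, mort, gender = NULL) {
  td <- total_deaths(state, mort, gender)
  if (td <= 0)
    stop("smoking-attributable fraction undefined: no deaths in stratum-year",
         call. = FALSE)
  sad <- sad_by_age(state, mort)
  g <- if (is.null(gender)) GENDERS else gender
  sum(sad[, g]) / td
}

#' Years of life lost
#'
#' Applies the never-smoker remaining life expectancy to each
#' smoking-attributable death: `YLL = sum_{a,g} e_ns(a,g) * SAD(a,g)`.
#'
#' @param sad `100 x 2` matrix of attributable deaths by age and gender
#'   (from [sad_by_age()]).
#' @param life_table A [build_life_table()] result for the same stratum.
#' @return Scalar years of life lost.
#' @export
years_of_life_lost <- function(sad, life_table) {
  if (!identical(dim(sad), dim(life_table$e_ns)))
    stop("SAD matrix and life table are misaligned", call. = FALSE)
  sum(life_table$e_ns * sad)
}

#' Annual outcome series for a projected trajectory
#'
#' Per calendar year and gender (plus the `all` total): current- and
#' former-smoking prevalence, smoking-attributable deaths (SAD), the
#' smoking-attributable fraction (SAF), years of life lost (YLL), and
#' cumulative SAD / YLL from `cum_start` onward (years before `cum_start`
#' carry zero cumulative totals).
#'
#' @param trajectory A [project()] result.
#' @param mort A [mortality_model()].
#' @param scenario_name Label recorded in the output.
#' @param cum_start First year included in the cumulative sums (default
#'   2023).
#' @return Data frame classed `spd_outcomes` with columns `year`, `gender`,
#'   `stratum`, `scenario`, `prev_cs`, `prev_fs`, `sad`, `saf`, `yll`,
#'   `cum_sad`, `cum_yll`.
#' @export
outcome_series <- function(trajectory, mort, scenario_name = "status_quo",
                           cum_start = 2023) {
  stratum <- trajectory[[1]]$stratum
  years <- as.integer(names(trajectory))
  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    st <- trajectory[[i]]
    sad <- sad_by_age(st, mort)
    lt <- build_life_table(mort, stratum, st$year)
    q <- mortality_rate_array(mort, st$year, stratum)
    per_g <- lapply(c(GENDERS, all = "all"), function(g) {
      gg <- if (identical(g, "all")) GENDERS else g
      sad_g <- sum(sad[, gg])
      td <- sum(st$counts[, gg, ] * q[, gg, ])
      data.frame(
        year = years[i],
        gender = if (identical(g, "all")) "all" else g,
        stratum = stratum,
        prev_cs = smoking_prevalence(st, if (identical(g, "all")) NULL else g),
        prev_fs = former_prevalence(st, if (identical(g, "all")) NULL else g),
        sad = sad_g,
        saf = if (td > 0) sad_g / td else NA_real_,
        yll = sum(lt$e_ns[, gg] * sad[, gg])
      )
    })
    rows[[i]] <- do.call(rbind, per_g)
  }
  out <- do.call(rbind, rows)
  out$scenario <- scenario_name
  out <- out[order(out$gender, out$year), ]
  out$cum_sad <- stats::ave(ifelse(out$year >= cum_start, out$sad, 0),
                            out$gender, FUN = cumsum)
  out$cum_yll <- stats::ave(ifelse(out$year >= cum_start, out$yll, 0),
                            out$gender, FUN = cumsum)
  rownames(out) <- NULL
  out <- out[, c("year", "gender", "stratum", "scenario", "prev_cs",
                 "prev_fs", "sad", "saf", "yll", "cum_sad", "cum_yll")]
  class(out) <- c("spd_outcomes", class(out))
  out
}

#' Cumulative deaths averted and life-years gained
#'
#' Difference in cumulative SAD and YLL between a reference series (Status
#' Quo) and a counterfactual (intervention) series through a horizon year,
#' accumulated from the series' cumulative-start year (2023 by default in
#' [outcome_series()]).
#'
#' @param reference,counterfactual [outcome_series()] data frames for the
#'   same stratum.
#' @param through_year Horizon (inclusive).
#' @param gender Row subset (default `"all"`).
#' @return List with `deaths_averted` and `life_years_gained`.
#' @export
deaths_averted <- function(reference, counterfactual, through_year,
                           gender = "all") {
  if (!identical(unique(reference$stratum), unique(counterfactual$stratum)))
    stop("reference and counterfactual strata differ", call. = FALSE)
  pick <- function(s) {
    r <- s[s$gender == gender & s$year == through_year, ]
    if (nrow(r) != 1L)
      stop("series does not cover year ", through_year, call. = FALSE)
    r
  }
  ref <- pick(reference)
  cf <- pick(counterfactual)
  list(deaths_averted = ref$cum_sad - cf$cum_sad,
       life_years_gained = ref$cum_yll - cf$cum_yll)
}

#' Decompose averted deaths into initiation and cessation contributions
#'
#' The net contribution of complete cessation to the MPRPM benchmark is the
#' difference between the MPRPM and No Initiation scenarios:
#' `cessation = mprpm - no_init`, `pct_no_init = no_init / mprpm * 100`,
#' `pct_cessation = 100 - pct_no_init` (percentages reported to 2 decimals,
#' reconciled so they sum to exactly 100).
#'
#' @param no_init_averted Cumulative quantity averted under No Initiation.
#' @param mprpm_averted Cumulative quantity averted under MPRPM
#'   (`>= no_init_averted`).
#' @return List with `cessation_contribution`, `pct_no_init`,
#'   `pct_cessation` (percentages `NA` when `mprpm_averted` is 0).
#' @export
decompose_cessation_vs_initiation <- function(no_init_averted, mprpm_averted) {
  if (mprpm_averted == 0)
    return(list(cessation_contribution = 0,
                pct_no_init = NA_real_, pct_cessation = NA_real_))
  pct_ni <- round(no_init_averted / mprpm_averted * 100, 2)
  list(cessation_contribution = mprpm_averted - no_init_averted,
       pct_no_init = pct_ni,
       pct_cessation = round(100 - pct_ni, 2))
}

#' Table of averted deaths and life-years with decomposition at milestones
#'
#' One row per milestone year: cumulative deaths averted and life-years
#' gained under the No Initiation and MPRPM scenarios (relative to the
#' Status Quo), their difference (complete cessation), and the percentage
#' split.
#'
#' @param status_quo,no_initiation,mprpm [outcome_series()] data frames for
#'   one stratum.
#' @param years Milestone years.
#' @param gender Row subset (default `"all"`).
#' @return Data frame, one row per milestone year.
#' @export
decomposition_table <- function(status_quo, no_initiation, mprpm,
                                years = seq(2030, 2100, by = 10),
                                gender = "all") {
  rows <- lapply(years, function(y) {
    ni <- deaths_averted(status_quo, no_initiation, y, gender)
    mp <- deaths_averted(status_quo, mprpm, y, gender)
    dd <- decompose_cessation_vs_initiation(ni$deaths_averted,
                                            mp$deaths_averted)
    dy <- decompose_cessation_vs_initiation(ni$life_years_gained,
                                            mp$life_years_gained)
    data.frame(
      year = y,
      deaths_averted_no_init = ni$deaths_averted,
      deaths_averted_mprpm = mp$deaths_averted,
      deaths_cessation = dd$cessation_contribution,
      deaths_pct_no_init = dd$pct_no_init,
      deaths_pct_cessation = dd$pct_cessation,
      lyg_no_init = ni$life_years_gained,
      lyg_mprpm = mp$life_years_gained,
      lyg_cessation = dy$cessation_contribution,
      lyg_pct_no_init = dy$pct_no_init,
      lyg_pct_cessation = dy$pct_cessation
    )
  })
  do.call(rbind, rows)
}

#' Write an outcome series as CSV
#'
#' Columns `year, gender, stratum, scenario, prev_cs, prev_fs, sad, saf,
#' yll, cum_sad, cum_yll`.
#'
#' @param outcomes An [outcome_series()] data frame (or several row-bound).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(as.data.frame(outcomes), path, row.names = FALSE)
  invisible(path)
}

#' Round deaths for text reporting
#'
#' Deaths are reported to the nearest thousand in running text and
#' life-years in millions.
#'
#' @param deaths,life_years Raw totals.
#' @return Character summary, e.g. `"609,000 deaths; 8.0 million life-years"`.
#' @export
format_burden_text <- function(deaths, life_years) {
  sprintf("%s deaths; %.1f million life-years",
          format(round(deaths / 1000) * 1000, big.mark = ","),
          life_years / 1e6)
}
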