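#' Construct a rate schedule
#'
#' Annual smoking initiation and cessation probabilities indexed by single
#' year of age, gender, and birth cohort (in the style of the CISNET
#' age-period-cohort transition inputs). Structural zeros are enforced:
#' initiation is zero at ages 35+ and below age 10, cessation is zero below
#' age 18.
#'
#' @param initiation,cessation Numeric arrays `100 x 2 x n_cohort`
#'   (age 0-99, gender female/male, birth cohort) of annual transition
#'   probabilities in `[0, 1]`.
#' @param cohorts Integer vector of birth cohort years, matching the third
#'   dimension.
#' @return An object of class `spd_rates`.
#' @export
rate_schedule <- function(initiation, cessation, cohorts) {
  cohorts <- as.integer(cohorts)
  dims <- c(N_AGE, N_GENDER, length(cohorts))
  for (nm in c("initiation", "cessation")) {
    x <- get(nm)
    if (!is.numeric(x) || !identical(dim(x), dims))
      stop("`", nm, "` must be a numeric 100 x 2 x ", length(cohorts),
           " array", call. = FALSE)
    if (any(x < 0 | x > 1))
      stop("`", nm, "` probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(initiation[AGES > MAX_INITIATION_AGE | AGES < MIN_INITIATION_AGE, , ] != 0))
    stop("initiation must be 0 outside ages ", MIN_INITIATION_AGE, "-",
         MAX_INITIATION_AGE, call. = FALSE)
  if (any(cessation[AGES < MIN_CESSATION_AGE, , ] != 0))
    stop("cessation must be 0 below age ", MIN_CESSATION_AGE, call. = FALSE)
  dn <- list(age = AGES, gender = GENDERS, cohort = cohorts)
  dimnames(initiation) <- dn
  dimnames(cessation) <- dn
  structure(list(initiation = initiation, cessation = cessation,
                 cohorts = cohorts),
            class = "spd_rates")
}

#' @export
print.spd_rates <- function(x, ...) {
  cat(sprintf("<spd_rates> cohorts %d-%d, peak initiation %.3f, max cessation %.3f\n",
              min(x$cohorts), max(x$cohorts),
              max(x$initiation), max(x$cessation)))
  invisible(x)
}

#' Look up period rates for one calendar year
#'
#' Resolves the cohort-indexed schedule into age-by-gender initiation and
#' cessation probability matrices for the transitions of calendar year
#' `year`. The cohort for age `a` is `min(year, freeze_year) - a`: after the
#' freeze year every age keeps reading its frozen age-specific probability,
#' so new cohorts inherit the youngest frozen cohort's schedule.
#'
#' @param rates A [rate_schedule()].
#' @param year Calendar year of the transition.
#' @param freeze_year Rates are frozen at this year's age profile for all
#'   later years (default 2018).
#' @return List with `initiation` and `cessation`, each a `100 x 2` matrix.
#' @export
rates_for_year <- function(rates, year, freeze_year = 2018) {
  yr <- min(year, freeze_year)
  cohort <- yr - AGES
  idx <- match(cohort, rates$cohorts)
  live <- !is.na(idx)
  if (!any(live))
    stop("no rate entry for any cohort in year ", year, call. = FALSE)
  ## ages whose cohort predates the schedule can only matter if they still
  ## have nonzero transition probabilities; both are zero above the
  ## initiation cap only for initiation, so missing cohorts are an error.
  if (any(!live))
    stop("missing rate entry for birth cohort(s) ",
         paste(range(cohort[!live]), collapse = "-"), " in year ", year,
         call. = FALSE)
  flat <- cbind(rep(seq_len(N_AGE), N_GENDER),
                rep(seq_len(N_GENDER), each = N_AGE),
                rep(idx, N_GENDER))
  list(
    initiation = matrix(rates$initiation[flat], N_AGE, N_GENDER,
                        dimnames = list(age = AGES, gender = GENDERS)),
    cessation = matrix(rates$cessation[flat], N_AGE, N_GENDER,
                       dimnames = list(age = AGES, gender = GENDERS))
  )
}

#' Write / read a rate schedule as CSV
#'
#' Long format with columns `gender, birth_cohort, age, initiation_prob,
#' cessation_prob`, UTF-8, '.' decimal separator.
#'
#' @param rates A [rate_schedule()].
#' @param path File path.
#' @return `write_rates_csv()` returns `path` invisibly; `read_rates_csv()`
#'   returns a [rate_schedule()].
#' @export
write_rates_csv <- function(rates, path) {
  grid <- expand.grid(age = AGES, gender = GENDERS, birth_cohort = rates$cohorts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    gender = grid$gender, birth_cohort = grid$birth_cohort, age = grid$age,
    initiation_prob = as.vector(rates$initiation),
    cessation_prob = as.vector(rates$cessation)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gender", "birth_cohort", "age", "initiation_prob", "cessation_prob")
  if (!all(need %in% names(df)))
    stop("rates CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cohorts <- sort(unique(df$birth_cohort))
  dims <- c(N_AGE, N_GENDER, length(cohorts))
  init <- array(0, dims)
  cess <- array(0, dims)
  idx <- cbind(match(df$age, AGES), match(df$gender, GENDERS),
               match(df$birth_cohort, cohorts))
  init[idx] <- df$initiation_prob
  cess[idx] <- df$cessation_prob
  rate_schedule(init, cess, cohorts)
}
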