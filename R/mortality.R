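#' Construct a mortality model
#'
#' Combines baseline all-cause death probabilities with multiplicative hazard
#' ratios for current smoking and SPD status. Former-smoker mortality is
#' interpolated exponentially between the never- and current-smoker rates as
#' a function of years since quitting (ysq):
#'
#'   mu_fs(ysq) = mu_ns + (mu_cs - mu_ns) * exp(-lambda * ysq)
#'
#' so former smokers' excess risk decays towards the never-smoker rate, and
#' always lies between mu_ns and mu_cs. All derived probabilities are capped
#' at 1 (with a warning when the cap binds).
#'
#' @param baseline Numeric array `100 x 2 x n_year` (age, gender, calendar
#'   year) of annual all-cause death probabilities for the reference
#'   (never-smoker, no-SPD) population, in `[0, 1]`. A single-year array
#'   gives a time-constant baseline.
#' @param years Integer vector of calendar years matching the third
#'   dimension. Years outside the range are clamped to the nearest covered
#'   year.
#' @param hr_current Hazard ratio of current vs never smokers, a `5 x 2`
#'   matrix (age band 18-34/35-54/55-64/65-74/75+ by gender), all `>= 1`.
#'   Ages below 18 use the youngest band.
#' @param hr_spd Hazard ratio of SPD vs no-SPD, scalar `>= 1`, applied
#'   multiplicatively to every smoking state.
#' @param lambda Per-year exponential decay constant for former-smoker excess
#'   risk, `> 0`.
#' @return An object of class `spd_mortality`.
#' @export
mortality_model <- function(baseline, years, hr_current, hr_spd = 1.3,
                            lambda = log(2) / 5) {
  years <- as.integer(years)
  if (!is.numeric(baseline) ||
      !identical(dim(baseline), c(N_AGE, N_GENDER, length(years))))
    stop("`baseline` must be a numeric 100 x 2 x ", length(years), " array",
         call. = FALSE)
  if (any(baseline < 0 | baseline > 1))
    stop("baseline death probabilities must lie in [0, 1]", call. = FALSE)
  hr_current <- as.matrix(hr_current)
  if (!identical(dim(hr_current), c(5L, 2L)))
    stop("`hr_current` must be a 5 x 2 matrix (age band x gender)",
         call. = FALSE)
  if (any(hr_current < 1)) stop("`hr_current` must be >= 1", call. = FALSE)
  if (hr_spd < 1) stop("`hr_spd` must be >= 1", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  dimnames(baseline) <- list(age = AGES, gender = GENDERS, year = years)
  dimnames(hr_current) <- list(age_band = AGE_BAND_NAMES, gender = GENDERS)
  structure(list(baseline = baseline, years = years, hr_current = hr_current,
                 hr_spd = hr_spd, lambda = lambda, cache = new.env()),
            class = "spd_mortality")
}

#' @export
print.spd_mortality <- function(x, ...) {
  cat(sprintf(
    "<spd_mortality> years %d-%d, hr_current %.2f-%.2f, hr_spd %.2f, lambda %.3f\n",
    min(x$years), max(x$years), min(x$hr_current), max(x$hr_current),
    x$hr_spd, x$lambda))
  invisible(x)
}

baseline_for_year <- function(mort, year) {
  yr <- min(max(year, min(mort$years)), max(mort$years))
  mort$baseline[, , as.character(yr)]
}

#' Death probability by smoking state
#'
#' Evaluates the mortality model for one smoking state:
#' never: `m0 * hr_spd^[SPD]`; current: `m0 * hr_current * hr_spd^[SPD]`;
#' former: `mu_ns + (mu_cs - mu_ns) * exp(-lambda * ysq)`. Vectorised over
#' `age`.
#'
#' @param mort A [mortality_model()].
#' @param smoking_state `"never"`, `"current"`, or `"former"`.
#' @param ysq Years since quit (required for former smokers; values above the
#'   terminal bin are allowed and simply decay further).
#' @param age Age(s) 0-99.
#' @param gender `"female"` or `"male"`.
#' @param year Calendar year.
#' @param stratum `"SPD"` or `"NoSPD"`.
#' @return Death probability/ies in `[0, 1]`.
#' @export
mu <- function(mort, smoking_state = c("never", "current", "former"),
               ysq = NULL, age, gender, year, stratum = "NoSPD") {
  smoking_state <- match.arg(smoking_state)
  gender <- match.arg(gender, GENDERS)
  stratum <- match.arg(stratum, STRATA)
  if (any(age < 0 | age > 99)) stop("age out of range 0-99", call. = FALSE)
  m0 <- baseline_for_year(mort, year)[as.character(age), gender]
  spd_mult <- if (stratum == "SPD") mort$hr_spd else 1
  mu_ns <- m0 * spd_mult
  hr <- mort$hr_current[age_band_index(age), gender]
  mu_cs <- m0 * hr * spd_mult
  out <- switch(smoking_state,
    never = mu_ns,
    current = mu_cs,
    former = {
      if (is.null(ysq)) stop("`ysq` required for former smokers", call. = FALSE)
      mu_ns + (mu_cs - mu_ns) * exp(-mort$lambda * ysq)
    })
  cap_probability(out)
}

cap_probability <- function(p) {
  if (any(p > 1)) {
    warning("death probability capped at 1 after hazard-ratio multiplication",
            call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}

## Full death-probability array [age, gender, smoking state] for one
## stratum-year; the engine's hot path, memoized per clamped year and
## stratum (the array is a pure function of both). The terminal former bin
## uses ysq = YSQ_MAX.
mortality_rate_array <- function(mort, year, stratum) {
  yr <- min(max(year, min(mort$years)), max(mort$years))
  key <- paste0(yr, ".", stratum)
  cached <- mort$cache[[key]]
  if (!is.null(cached)) return(cached)
  m0 <- baseline_for_year(mort, year)
  spd_mult <- if (stratum == "SPD") mort$hr_spd else 1
  mu_ns <- m0 * spd_mult
  hr <- mort$hr_current[age_band_index(AGES), , drop = FALSE]
  mu_cs <- m0 * hr * spd_mult
  q <- array(0, dim = c(N_AGE, N_GENDER, N_STATE),
             dimnames = list(age = AGES, gender = GENDERS, state = SMOKING_STATES))
  q[, , "never"] <- mu_ns
  q[, , "current"] <- mu_cs
  decay <- exp(-mort$lambda * seq_len(YSQ_MAX))
  excess <- mu_cs - mu_ns
  for (k in seq_len(YSQ_MAX))
    q[, , 2L + k] <- mu_ns + excess * decay[k]
  if (any(q > 1)) {
    warning("death probability capped at 1 after hazard-ratio multiplication",
            call. = FALSE)
    q <- pmin(q, 1)
  }
  mort$cache[[key]] <- q
  q
}

#' Build a never-smoker period life table
#'
#' Standard period life table from never-smoker death probabilities for one
#' stratum and year, both genders. Person-years use the half-year convention
#' `L(a) = l(a) - 0.5 d(a)` and the table is closed at age 99 (everyone
#' alive at 99 dies in that year). Remaining life expectancy is
#' `e(a) = T(a) / l(a)` with `T(a)` the tail sum of `L`.
#'
#' @param mort A [mortality_model()].
#' @param stratum `"SPD"` or `"NoSPD"`.
#' @param year Calendar year.
#' @return An object of class `spd_life_table`: list with `e_ns` (remaining
#'   life expectancy, `100 x 2` matrix), `stratum`, `year`.
#' @export
build_life_table <- function(mort, stratum = "NoSPD", year) {
  stratum <- match.arg(stratum, STRATA)
  yr_c <- min(max(year, min(mort$years)), max(mort$years))
  key <- paste0("lt.", yr_c, ".", stratum)
  cached <- mort$cache[[key]]
  if (!is.null(cached)) {
    cached$year <- as.integer(year)
    return(cached)
  }
  m0 <- baseline_for_year(mort, year)
  spd_mult <- if (stratum == "SPD") mort$hr_spd else 1
  q <- cap_probability(m0 * spd_mult)
  if (any(q < 0 | q > 1))
    stop("death probabilities outside [0, 1]", call. = FALSE)
  q[N_AGE, ] <- 1 # closure: all remaining die at 99
  e <- matrix(0, N_AGE, N_GENDER, dimnames = list(age = AGES, gender = GENDERS))
  for (g in seq_len(N_GENDER)) {
    l <- cumprod(c(1, 1 - q[-N_AGE, g]))
    d <- l * q[, g]
    L <- l - 0.5 * d
    Tt <- rev(cumsum(rev(L)))
    e[, g] <- ifelse(l > 0, Tt / l, 0)
  }
  out <- structure(list(e_ns = e, stratum = stratum, year = as.integer(year)),
                   class = "spd_life_table")
  mort$cache[[key]] <- out
  out
}

#' @export
print.spd_life_table <- function(x, ...) {
  cat(sprintf("<spd_life_table> %s, year %d, e0 = %.1f (f) / %.1f (m)\n",
              x$stratum, x$year, x$e_ns[1, "female"], x$e_ns[1, "male"]))
  invisible(x)
}

#' Write a life table as CSV
#'
#' Columns `stratum, gender, age, e_ns`.
#'
#' @param lt A [build_life_table()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_life_table_csv <- function(lt, path) {
  out <- data.frame(
    stratum = lt$stratum,
    gender = rep(GENDERS, each = N_AGE),
    age = rep(AGES, N_GENDER),
    e_ns = as.vector(lt$e_ns)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a baseline-mortality table as CSV
#'
#' Columns `year, age, gender, m0`. Reading reconstructs a
#' [mortality_model()] given hazard-ratio settings.
#'
#' @param mort A [mortality_model()].
#' @param path File path.
#' @param hr_current,hr_spd,lambda Passed to [mortality_model()] on read.
#' @return `write_baseline_csv()` returns `path` invisibly;
#'   `read_baseline_csv()` returns a [mortality_model()].
#' @export
write_baseline_csv <- function(mort, path) {
  grid <- expand.grid(age = AGES, gender = GENDERS, year = mort$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(year = grid$year, age = grid$age, gender = grid$gender,
                    m0 = as.vector(mort$baseline))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline_csv
#' @export
read_baseline_csv <- function(path, hr_current, hr_spd = 1.3,
                              lambda = log(2) / 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "age", "gender", "m0")
  if (!all(need %in% names(df)))
    stop("baseline CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  years <- sort(unique(df$year))
  base <- array(0, c(N_AGE, N_GENDER, length(years)))
  idx <- cbind(match(df$age, AGES), match(df$gender, GENDERS),
               match(df$year, years))
  base[idx] <- df$m0
  mortality_model(base, years, hr_current, hr_spd, lambda)
}
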