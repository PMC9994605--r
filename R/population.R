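#' Construct a population state
#'
#' A population state holds real-valued compartment counts for one stratum
#' (SPD or no-SPD) in one calendar year, indexed by single year of age 0-99,
#' gender, and smoking state. Former smokers are binned by years since
#' quitting (ysq), single-year bins 1..19 plus an open terminal 20+ bin.
#'
#' @param year Calendar year of the snapshot.
#' @param counts Numeric array `100 x 2 x 22` (age 0-99, gender
#'   female/male, smoking state never/current/former1..former20), or `NULL`
#'   for an empty (all-zero) population. Dimnames, if present, are replaced by
#'   the canonical ones.
#' @param stratum `"SPD"` or `"NoSPD"`.
#' @return An object of class `spd_population`.
#' @export
population_state <- function(year, counts = NULL, stratum = "NoSPD") {
  stratum <- match.arg(stratum, STRATA)
  if (is.null(counts)) {
    counts <- array(0, dim = c(N_AGE, N_GENDER, N_STATE))
  }
  if (!is.numeric(counts) || !identical(dim(counts), c(N_AGE, N_GENDER, N_STATE)))
    stop("`counts` must be a numeric array of dim 100 x 2 x 22", call. = FALSE)
  dimnames(counts) <- list(age = AGES, gender = GENDERS, state = SMOKING_STATES)
  state <- structure(
    list(year = as.integer(year), stratum = stratum, counts = counts),
    class = "spd_population"
  )
  validate_population(state)
  state
}

#' @export
print.spd_population <- function(x, ...) {
  cat(sprintf(
    "<spd_population> year %d, stratum %s, %.0f persons (adult current smoking %.1f%%)\n",
    x$year, x$stratum, sum(x$counts),
    100 * tryCatch(smoking_prevalence(x), error = function(e) NA_real_)
  ))
  invisible(x)
}

validate_population <- function(state) {
  cnt <- state$counts
  if (any(cnt < 0))
    stop("invariant violation: negative compartment counts", call. = FALSE)
  ## former-smoker mass is structurally impossible below age
  ## MIN_INITIATION_AGE + 1: one cannot have quit without having initiated
  ## (earliest age 10) and ysq >= 1. The tighter under-19 floor implied by
  ## the ordinary cessation rule holds only when no forced-cessation
  ## scenario (which makes smokers of every age quit) is in play, so it is
  ## not enforced here.
  young <- AGES <= MIN_INITIATION_AGE
  if (any(cnt[young, , FORMER_STATES] != 0))
    stop("invariant violation: former-smoker mass below age ",
         MIN_INITIATION_AGE + 1L, call. = FALSE)
  invisible(state)
}

#' Current-smoking prevalence in an age/gender range
#'
#' Current-smoker count divided by total count in the requested range. The
#' default range 18-99 gives adult prevalence.
#'
#' @param state A [population_state()].
#' @param gender `"female"`, `"male"`, or `NULL` for both combined.
#' @param age_lo,age_hi Inclusive age range.
#' @return Fraction in `[0, 1]`.
#' @export
smoking_prevalence <- function(state, gender = NULL, age_lo = 18, age_hi = 99) {
  state_count_fraction(state, "current", gender, age_lo, age_hi)
}

#' Former-smoking prevalence in an age/gender range
#'
#' Total former-smoker count (all ysq bins) over total count in the range.
#'
#' @inheritParams smoking_prevalence
#' @return Fraction in `[0, 1]`.
#' @export
former_prevalence <- function(state, gender = NULL, age_lo = 18, age_hi = 99) {
  state_count_fraction(state, FORMER_STATES, gender, age_lo, age_hi)
}

state_count_fraction <- function(state, states, gender, age_lo, age_hi) {
  if (age_lo > age_hi) stop("`age_lo` must be <= `age_hi`", call. = FALSE)
  g <- if (is.null(gender)) GENDERS else match.arg(gender, GENDERS)
  rows <- AGES >= age_lo & AGES <= age_hi
  denom <- sum(state$counts[rows, g, ])
  if (denom <= 0)
    stop("prevalence undefined: no population in the requested range",
         call. = FALSE)
  sum(state$counts[rows, g, states]) / denom
}

#' Write / read a population snapshot as CSV
#'
#' Long format with columns `year, age, gender, stratum, smoking_state, ysq,
#' count`; `ysq` is empty for never and current smokers and `20` denotes the
#' terminal 20+ bin. Zero-count cells are omitted on write and implied zero on
#' read.
#'
#' @param state A [population_state()].
#' @param path File path.
#' @return `write_population_csv()` returns `path` invisibly;
#'   `read_population_csv()` returns a [population_state()].
#' @export
write_population_csv <- function(state, path) {
  cnt <- state$counts
  df <- expand.grid(age = AGES, gender = GENDERS, state = SMOKING_STATES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- as.vector(cnt)
  df <- df[df$count != 0, , drop = FALSE]
  ysq <- rep(NA_integer_, nrow(df))
  fs <- startsWith(df$state, "former")
  ysq[fs] <- as.integer(sub("former", "", df$state[fs]))
  out <- data.frame(
    year = state$year, age = df$age, gender = df$gender,
    stratum = state$stratum,
    smoking_state = ifelse(fs, "former", df$state),
    ysq = ysq, count = df$count
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "age", "gender", "stratum", "smoking_state", "ysq", "count")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  year <- unique(df$year)
  stratum <- unique(df$stratum)
  if (length(year) != 1L || length(stratum) != 1L)
    stop("population CSV must contain a single year and stratum", call. = FALSE)
  st <- ifelse(df$smoking_state == "former",
               paste0("former", pmin(df$ysq, YSQ_MAX)), df$smoking_state)
  bad <- !st %in% SMOKING_STATES
  if (any(bad)) stop("unknown smoking state: ", st[bad][1], call. = FALSE)
  cnt <- array(0, dim = c(N_AGE, N_GENDER, N_STATE))
  idx <- cbind(match(df$age, AGES), match(df$gender, GENDERS),
               match(st, SMOKING_STATES))
  for (i in seq_len(nrow(idx))) cnt[idx[i, 1], idx[i, 2], idx[i, 3]] <-
    cnt[idx[i, 1], idx[i, 2], idx[i, 3]] + df$count[i]
  population_state(year, cnt, stratum)
}
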