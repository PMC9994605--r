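#' @keywords internal
"_PACKAGE"

## Shared model dimensions.
##
## The state space is fixed: single-year ages 0-99 (exit at 99), two genders,
## and 22 smoking states -- never, current, and former smokers in single-year
## years-since-quit (ysq) bins 1..19 plus an open terminal 20+ bin.

AGES <- 0:99
N_AGE <- length(AGES)
GENDERS <- c("female", "male")
N_GENDER <- 2L
YSQ_MAX <- 20L
FORMER_STATES <- paste0("former", seq_len(YSQ_MAX))
SMOKING_STATES <- c("never", "current", FORMER_STATES)
N_STATE <- length(SMOKING_STATES)

MAX_INITIATION_AGE <- 34L # no initiation at 35 or older
MIN_INITIATION_AGE <- 10L
MIN_CESSATION_AGE <- 18L

#' Age bands used for stratum proportions, hazard ratios and scaling factors
#'
#' Adult age bands 18-34, 35-54, 55-64, 65-74 and 75+ (75-99). Ages below 18
#' are mapped onto the youngest band wherever a band-level quantity must be
#' evaluated for a minor (e.g. the initiation scaling factor for ages 10-17).
#'
#' @return Named list of integer age vectors.
#' @export
age_bands <- function() {
  list(
    "18-34" = 18:34,
    "35-54" = 35:54,
    "55-64" = 55:64,
    "65-74" = 65:74,
    "75+"   = 75:99
  )
}

AGE_BAND_NAMES <- c("18-34", "35-54", "55-64", "65-74", "75+")

## band index for every single year of age (ages < 18 -> youngest band)
age_band_index <- function(ages = AGES) {
  idx <- integer(length(ages))
  idx[ages < 35] <- 1L
  idx[ages >= 35 & ages < 55] <- 2L
  idx[ages >= 55 & ages < 65] <- 3L
  idx[ages >= 65 & ages < 75] <- 4L
  idx[ages >= 75] <- 5L
  idx
}

STRATA <- c("SPD", "NoSPD")

`%||%` <- function(a, b) if (is.null(a)) b else a
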