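#' Scaling factor set
#'
#' Positive multipliers applied to initiation and cessation probabilities,
#' one per gender and adult age band (18-34, 35-54, 55-64, 65-74, 75+).
#' Ages below 18 read the youngest band's factor (only relevant for
#' initiation, which runs from age 10). Scaled probabilities are clipped to
#' `[0, 1]`; structural zeros (initiation at 35+, cessation below 18) are
#' preserved because multiplication cannot create mass where the schedule
#' has none.
#'
#' @param init_scale,cess_scale `5 x 2` numeric matrices (age band x
#'   gender) of positive multipliers, or a single scalar recycled to all
#'   cells. Default 1 (identity).
#' @return An object of class `spd_factors`.
#' @export
scaling_factors <- function(init_scale = 1, cess_scale = 1) {
  expand <- function(x, nm) {
    if (length(x) == 1L) x <- matrix(x, 5, 2)
    x <- as.matrix(x)
    if (!identical(dim(x), c(5L, 2L)))
      stop("`", nm, "` must be scalar or a 5 x 2 matrix", call. = FALSE)
    if (any(x <= 0)) stop("`", nm, "` factors must be > 0", call. = FALSE)
    dimnames(x) <- list(age_band = AGE_BAND_NAMES, gender = GENDERS)
    x
  }
  structure(list(init_scale = expand(init_scale, "init_scale"),
                 cess_scale = expand(cess_scale, "cess_scale")),
            class = "spd_factors")
}

#' @export
print.spd_factors <- function(x, ...) {
  cat("<spd_factors>\n  initiation:\n")
  print(round(x$init_scale, 4))
  cat("  cessation:\n")
  print(round(x$cess_scale, 4))
  invisible(x)
}

#' Apply scaling factors to a rate schedule
#'
#' Multiplies every initiation / cessation probability by the factor of its
#' age band and gender, then clips to `[0, 1]`.
#'
#' @param rates A [rate_schedule()].
#' @param factors A [scaling_factors()].
#' @return A new [rate_schedule()].
#' @export
apply_scaling <- function(rates, factors) {
  bi <- age_band_index(AGES)
  n_cohort <- length(rates$cohorts)
  scale_one <- function(x, f) {
    mult <- f[bi, ] # 100 x 2, recycled over cohorts
    pmin(as.vector(mult) * x, 1)
  }
  init <- array(scale_one(rates$initiation, factors$init_scale),
                dim = dim(rates$initiation))
  cess <- array(scale_one(rates$cessation, factors$cess_scale),
                dim = dim(rates$cessation))
  rate_schedule(init, cess, rates$cohorts)
}

#' Prevalence targets
#'
#' Observed adult current-smoking prevalence by survey year, gender and
#' stratum, optionally resolved by adult age band (`age_band = NA` denotes
#' the whole 18-99 range).
#'
#' @param df Data frame with columns `year`, `gender`, `stratum`,
#'   `prevalence`, and optionally `age_band`.
#' @return The validated data frame, classed `spd_targets`.
#' @export
prevalence_targets <- function(df) {
  need <- c("year", "gender", "stratum", "prevalence")
  if (!all(need %in% names(df)))
    stop("targets need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!"age_band" %in% names(df)) df$age_band <- NA_character_
  if (any(df$prevalence <= 0 | df$prevalence >= 1))
    stop("target prevalences must lie in (0, 1)", call. = FALSE)
  if (length(unique(df$year)) < 2L)
    stop("targets must span at least 2 survey years", call. = FALSE)
  bad <- !is.na(df$age_band) & !df$age_band %in% AGE_BAND_NAMES
  if (any(bad)) stop("unknown age band: ", df$age_band[bad][1], call. = FALSE)
  class(df) <- c("spd_targets", class(df))
  df
}

## model prevalence for each target row, given a simulated trajectory;
## grouped by year with direct numeric indexing (calibration hot path)
model_prevalence_for_targets <- function(trajectory, targets) {
  bands <- c(age_bands(), list(adult = 18:99))
  years <- as.integer(names(trajectory))
  band_key <- ifelse(is.na(targets$age_band), "adult", targets$age_band)
  g_idx <- match(targets$gender, GENDERS)
  out <- numeric(nrow(targets))
  for (y in unique(targets$year)) {
    iy <- match(y, years)
    if (is.na(iy)) stop("trajectory does not cover target year ", y,
                        call. = FALSE)
    cnt <- trajectory[[iy]]$counts
    cur <- cnt[, , 2L]
    tot <- rowSums(cnt, dims = 2L)
    rows <- which(targets$year == y)
    for (i in rows) {
      a <- bands[[band_key[i]]] + 1L
      denom <- sum(tot[a, g_idx[i]])
      if (denom <= 0)
        stop("prevalence undefined: no population in the requested range",
             call. = FALSE)
      out[i] <- sum(cur[a, g_idx[i]]) / denom
    }
  }
  out
}

#' Calibration objective: sum of squared prevalence differences
#'
#' Simulates the stratum forward from `baseline` with the scaled rates and
#' returns the unweighted sum over target rows of
#' (model prevalence - target prevalence)^2.
#'
#' @param factors A [scaling_factors()].
#' @param rates Unscaled [rate_schedule()].
#' @param mort A [mortality_model()].
#' @param baseline Baseline [population_state()] (held fixed; factors scale
#'   only the forward transitions).
#' @param targets A [prevalence_targets()] data frame for one stratum.
#' @param scenario A [scenario_spec()] (default Status Quo).
#' @param births As in [advance_year()].
#' @return Nonnegative scalar.
#' @export
calibration_objective <- function(factors, rates, mort, baseline, targets,
                                  scenario = scenario_status_quo(),
                                  births = c(0, 0)) {
  scaled <- apply_scaling(rates, factors)
  traj <- project(baseline, scaled, mort, scenario,
                  end_year = max(targets$year), births = births)
  sum((model_prevalence_for_targets(traj, targets) - targets$prevalence)^2)
}

## Default free-parameter layout: initiation is structurally zero at ages
## 35+, so only the 18-34 initiation factors are identifiable; cessation
## factors are free in every band. Cells not in the free set stay at 1.
default_free_cells <- function() {
  rbind(
    data.frame(mechanism = "init", age_band = "18-34",
               gender = rep(GENDERS, each = 1)),
    expand.grid(mechanism = "cess", age_band = AGE_BAND_NAMES,
                gender = GENDERS, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  )
}

factors_from_theta <- function(theta, free) {
  f <- scaling_factors()
  v <- exp(theta)
  for (i in seq_len(nrow(free))) {
    slot <- if (free$mechanism[i] == "init") "init_scale" else "cess_scale"
    f[[slot]][free$age_band[i], free$gender[i]] <- v[i]
  }
  f
}

theta_from_factors <- function(factors, free) {
  log(vapply(seq_len(nrow(free)), function(i) {
    slot <- if (free$mechanism[i] == "init") "init_scale" else "cess_scale"
    factors[[slot]][free$age_band[i], free$gender[i]]
  }, numeric(1)))
}

#' Calibrate scaling factors to prevalence targets
#'
#' Minimises [calibration_objective()] over the free factor cells in
#' log-factor space (positivity by construction): a Nelder-Mead search
#' followed by a quasi-Newton (BFGS) polish with numerical gradients.
#' Non-convergence is flagged in the result, not raised.
#'
#' @inheritParams calibration_objective
#' @param free Data frame of free cells (`mechanism` "init"/"cess",
#'   `age_band`, `gender`); default [default_free_cells()].
#' @param start A [scaling_factors()] starting point (default all 1).
#' @param max_eval Evaluation budget for the Nelder-Mead stage.
#' @param reltol Relative convergence tolerance.
#' @param polish Run the BFGS refinement stage (default `TRUE`).
#' @return An object of class `spd_calibration`: list with `factors`
#'   ([scaling_factors()]), `sse`, `evaluations`, `converged`, `message`,
#'   `free`.
#' @export
calibrate <- function(rates, mort, baseline, targets,
                      scenario = scenario_status_quo(), births = c(0, 0),
                      free = default_free_cells(),
                      start = scaling_factors(),
                      max_eval = 2000, reltol = 1e-8, polish = TRUE) {
  targets <- prevalence_targets(as.data.frame(targets))
  if (stats::sd(targets$prevalence) == 0)
    warning("degenerate targets: constant prevalence", call. = FALSE)
  n_eval <- 0L
  fn <- function(theta) {
    n_eval <<- n_eval + 1L
    calibration_objective(factors_from_theta(theta, free), rates, mort,
                          baseline, targets, scenario, births)
  }
  theta0 <- theta_from_factors(start, free)
  f0 <- fn(theta0)
  if (f0 < reltol^2) {
    ## already at the optimum (e.g. started from the generating truth)
    return(structure(list(factors = factors_from_theta(theta0, free),
                          sse = f0, evaluations = n_eval, converged = TRUE,
                          message = "start already optimal", free = free),
                     class = "spd_calibration"))
  }
  ## Nelder-Mead locates the basin; the quasi-Newton stage converges it.
  nm_budget <- if (polish) min(500, max_eval) else max_eval
  nm <- stats::optim(theta0, fn, method = "Nelder-Mead",
                     control = list(maxit = nm_budget, reltol = reltol))
  best <- nm
  if (polish) {
    bf <- tryCatch(
      stats::optim(nm$par, fn, method = "BFGS",
                   control = list(maxit = 200, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(bf) && bf$value <= best$value) best <- bf
  }
  structure(list(factors = factors_from_theta(best$par, free),
                 sse = best$value, evaluations = n_eval,
                 converged = best$convergence == 0,
                 message = if (best$convergence == 0) "converged"
                           else paste("optimizer code", best$convergence),
                 free = free),
            class = "spd_calibration")
}

#' @export
print.spd_calibration <- function(x, ...) {
  cat(sprintf("<spd_calibration> SSE %.3g after %d evaluations (%s)\n",
              x$sse, x$evaluations, x$message))
  print(x$factors)
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' Factors, final SSE, evaluation count and convergence metadata.
#'
#' @param cal A [calibrate()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  out <- list(
    init_scale = as.data.frame(as.table(cal$factors$init_scale),
                               stringsAsFactors = FALSE),
    cess_scale = as.data.frame(as.table(cal$factors$cess_scale),
                               stringsAsFactors = FALSE),
    sse = cal$sse, evaluations = cal$evaluations,
    converged = cal$converged, message = cal$message
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @return `read_calibration_json()` returns the [scaling_factors()] stored
#'   in a calibration report.
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(df) {
    m <- matrix(1, 5, 2, dimnames = list(AGE_BAND_NAMES, GENDERS))
    m[cbind(match(df$age_band, AGE_BAND_NAMES),
            match(df$gender, GENDERS))] <- df$Freq
    m
  }
  scaling_factors(init_scale = unpack(x$init_scale),
                  cess_scale = unpack(x$cess_scale))
}

#' Write / read prevalence targets as CSV
#'
#' Columns `year, gender, stratum, age_band, prevalence` (`age_band` empty
#' for whole-adult targets).
#'
#' @param targets A [prevalence_targets()] data frame.
#' @param path File path.
#' @return `write_targets_csv()` returns `path` invisibly;
#'   `read_targets_csv()` returns a [prevalence_targets()] data frame.
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(as.data.frame(targets)[
    , c("year", "gender", "stratum", "age_band", "prevalence")],
    path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_targets_csv
#' @export
read_targets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(age_band = "character"))
  df$age_band[df$age_band == ""] <- NA_character_
  prevalence_targets(df)
}
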