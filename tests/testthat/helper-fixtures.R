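# Shared fixtures, built in code. Small problem sizes keep the default run
# fast; the statistical structure matches the full-scale generator.

small_config <- function(...) {
  synthetic_config(pop_size = 2e5, ...)
}

# memoised standard inputs at default settings (built once per test run)
.fixture_env <- new.env()

std_inputs <- function() {
  if (is.null(.fixture_env$std)) {
    cfg <- small_config()
    rates <- make_rate_surfaces(cfg)
    mort <- make_mortality_model(cfg)
    truth <- spd_true_factors()
    base <- make_baseline_population(cfg, truth)
    .fixture_env$std <- list(cfg = cfg, rates = rates, mort = mort,
                             truth = truth, base = base,
                             births = synthetic_births(cfg))
  }
  .fixture_env$std
}

# a zero-mortality model (for conservation-free transition checks)
zero_mortality <- function() {
  mortality_model(array(0, c(100, 2, 1)), years = 2000,
                  hr_current = matrix(1, 5, 2), hr_spd = 1, lambda = 0.1)
}

# population with a single occupied cell
single_cell_state <- function(year = 2000, age = 20, gender = 2,
                              state = 1, n = 1000, stratum = "NoSPD") {
  cnt <- array(0, c(100, 2, 22))
  cnt[age + 1, gender, state] <- n
  population_state(year, cnt, stratum)
}

# rate schedule with flat initiation/cessation inside the legal age ranges
flat_rates <- function(init = 0.02, cess = 0.05, cohorts = 1900:2020) {
  ages <- 0:99
  i <- array(0, c(100, 2, length(cohorts)))
  c_ <- array(0, c(100, 2, length(cohorts)))
  i[ages >= 10 & ages <= 34, , ] <- init
  c_[ages >= 18, , ] <- cess
  rate_schedule(i, c_, cohorts)
}
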