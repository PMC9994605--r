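# Mortality accounting: SAD, SAF, YLL, averted deaths, decomposition.

test_that("SAD is zero without smokers or without excess risk", {
  inp <- std_inputs()
  never_only <- population_state(2000, {
    a <- array(0, c(100, 2, 22)); a[, , 1] <- 50; a
  }, "NoSPD")
  expect_equal(unname(smoking_attributable_deaths(never_only, inp$mort)),
               c(0, 0, 0))
  # hr_current = 1 (no excess risk): SAD = 0 even with smokers
  flat <- mortality_model(array(0.02, c(100, 2, 1)), 2000, matrix(1, 5, 2),
                          hr_spd = 1, lambda = 0.1)
  smokers <- single_cell_state(age = 50, gender = 1, state = 2, n = 1000)
  expect_equal(unname(smoking_attributable_deaths(smokers, flat)), c(0, 0, 0))
})

test_that("single-cell SAD matches the printed formula by hand", {
  # P = 1000, prev_cs = 0.3, mu_cs = 0.02, mu_ns = 0.01 -> SAD = 3
  cnt <- array(0, c(100, 2, 22))
  cnt[51, 2, 1] <- 700
  cnt[51, 2, 2] <- 300
  st <- population_state(2000, cnt, "NoSPD")
  mort <- mortality_model(array(0.01, c(100, 2, 1)), 2000, matrix(2, 5, 2),
                          hr_spd = 1, lambda = 0.1)
  sad <- smoking_attributable_deaths(st, mort)
  expect_equal(unname(sad["male"]), 1000 * 0.3 * (0.02 - 0.01))
  expect_equal(unname(sad["all"]), 3)
})

test_that("vectorized SAD equals a scalar triple-loop oracle on random states", {
  inp <- std_inputs()
  set.seed(7)
  for (rep in 1:5) {
    cnt <- array(stats::runif(100 * 2 * 22, 0, 100), c(100, 2, 22))
    cnt[1:11, , 3:22] <- 0 # keep the structural invariant
    st <- population_state(2011, cnt, sample(c("SPD", "NoSPD"), 1))
    fast <- sad_by_age(st, inp$mort)
    # scalar oracle: evaluate the summation formula cell by cell via mu()
    slow <- matrix(0, 100, 2)
    for (a in 0:99) for (g in 1:2) {
      gn <- c("female", "male")[g]
      ns <- mu(inp$mort, "never", age = a, gender = gn, year = 2011,
               stratum = st$stratum)
      cs <- mu(inp$mort, "current", age = a, gender = gn, year = 2011,
               stratum = st$stratum)
      acc <- cnt[a + 1, g, 2] * (cs - ns)
      for (k in 1:20) {
        fs <- mu(inp$mort, "former", ysq = k, age = a, gender = gn,
                 year = 2011, stratum = st$stratum)
        acc <- acc + cnt[a + 1, g, 2 + k] * (fs - ns)
      }
      slow[a + 1, g] <- acc
    }
    expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-9)
  }
})

test_that("SAF matches its closed form for an all-current population", {
  # everyone smokes, mu_cs = 2 mu_ns -> SAF = (mu_cs - mu_ns)/mu_cs = 0.5
  st <- single_cell_state(age = 60, gender = 1, state = 2, n = 5000)
  mort <- mortality_model(array(0.01, c(100, 2, 1)), 2000, matrix(2, 5, 2),
                          hr_spd = 1, lambda = 0.1)
  expect_equal(smoking_attributable_fraction(st, mort), 0.5)
  never <- single_cell_state(age = 60, gender = 1, state = 1, n = 5000)
  expect_equal(smoking_attributable_fraction(never, mort), 0)
  empty <- population_state(2000)
  expect_error(smoking_attributable_fraction(empty, mort), "undefined")
})

test_that("YLL is expectancy-weighted SAD and matches a recount", {
  inp <- std_inputs()
  lt <- build_life_table(inp$mort, "NoSPD", 2000)
  sad <- matrix(0, 100, 2)
  sad[41, 1] <- 10
  expect_equal(years_of_life_lost(sad, lt), 10 * lt$e_ns[41, 1])
  # random SAD matrix vs per-cell loop
  set.seed(11)
  sad2 <- matrix(stats::runif(200), 100, 2)
  brute <- 0
  for (a in 1:100) for (g in 1:2) brute <- brute + sad2[a, g] * lt$e_ns[a, g]
  expect_equal(years_of_life_lost(sad2, lt), brute)
  expect_error(years_of_life_lost(sad2[1:50, ], lt), "misaligned")
})

test_that("outcome series: cumulative sums start at 2023 and never decrease", {
  inp <- std_inputs()
  traj <- project(inp$base$SPD, apply_scaling(inp$rates, inp$truth),
                  inp$mort, scenario_status_quo(), 2040, inp$births$SPD)
  oc <- outcome_series(traj, inp$mort)
  all_rows <- oc[oc$gender == "all", ]
  expect_equal(all_rows$cum_sad[all_rows$year < 2023],
               rep(0, sum(all_rows$year < 2023)))
  expect_true(all(diff(all_rows$cum_sad) >= 0))
  expect_true(all(diff(all_rows$cum_yll) >= 0))
  expect_true(all(all_rows$sad >= 0))
  expect_true(all(all_rows$saf >= 0 & all_rows$saf <= 1))
  expect_equal(all_rows$cum_sad[all_rows$year == 2040],
               sum(all_rows$sad[all_rows$year >= 2023]))
  # gender rows add up to the total
  y30 <- oc[oc$year == 2030, ]
  expect_equal(y30$sad[y30$gender == "all"],
               sum(y30$sad[y30$gender != "all"]))
})

test_that("identical scenarios avert nothing; MPRPM dominates No Initiation", {
  inp <- std_inputs()
  r_spd <- apply_scaling(inp$rates, inp$truth)
  sq <- outcome_series(project(inp$base$SPD, r_spd, inp$mort,
                               scenario_status_quo(), 2060,
                               inp$births$SPD), inp$mort)
  expect_equal(deaths_averted(sq, sq, 2050)$deaths_averted, 0)
  ni <- outcome_series(project(inp$base$SPD, r_spd, inp$mort,
                               scenario_no_initiation(), 2060,
                               inp$births$SPD), inp$mort, "no_initiation")
  mp <- outcome_series(project(inp$base$SPD, r_spd, inp$mort,
                               scenario_mprpm(), 2060,
                               inp$births$SPD), inp$mort, "mprpm")
  prev_ni <- 0; prev_mp <- 0
  for (y in seq(2025, 2060, by = 5)) {
    a_ni <- deaths_averted(sq, ni, y)
    a_mp <- deaths_averted(sq, mp, y)
    expect_gte(a_mp$deaths_averted, a_ni$deaths_averted)
    expect_gte(a_mp$life_years_gained, a_ni$life_years_gained)
    # cumulative averted quantities are non-decreasing in the horizon
    expect_gte(a_ni$deaths_averted, prev_ni)
    expect_gte(a_mp$deaths_averted, prev_mp)
    prev_ni <- a_ni$deaths_averted; prev_mp <- a_mp$deaths_averted
  }
  # under MPRPM annual SAD stays positive for decades (former-smoker risk)
  expect_true(all(mp$sad[mp$gender == "all" & mp$year %in% 2025:2060] > 0))
  expect_error(deaths_averted(sq, outcome_series(
    project(inp$base$NoSPD, inp$rates, inp$mort, scenario_status_quo(),
            2060, inp$births$NoSPD), inp$mort), 2050), "strata")
})

test_that("cessation-vs-initiation decomposition reproduces printed splits", {
  # printed 2100 SPD row: 69,868 and 385,513 averted
  d <- decompose_cessation_vs_initiation(69868, 385513)
  expect_equal(d$cessation_contribution, 315645)
  expect_equal(d$pct_no_init, 18.12)
  expect_equal(d$pct_cessation, 81.88)
  # life-years side of the same row: 1,178,656 and 4,927,790
  dl <- decompose_cessation_vs_initiation(1178656, 4927790)
  expect_equal(dl$cessation_contribution, 3749134)
  expect_equal(dl$pct_no_init, 23.92)
  expect_equal(dl$pct_cessation, 76.08)
  # early-horizon rows: zero initiation benefit -> 100% cessation
  d0 <- decompose_cessation_vs_initiation(0, 22209)
  expect_equal(d0$pct_no_init, 0)
  expect_equal(d0$pct_cessation, 100)
  # boundary and degenerate cases
  expect_equal(decompose_cessation_vs_initiation(5, 5)$pct_no_init, 100)
  expect_true(is.na(decompose_cessation_vs_initiation(0, 0)$pct_no_init))
  # percentages always reconcile to exactly 100
  for (x in c(1, 7, 1234, 69867.5))
    expect_equal(sum(unlist(decompose_cessation_vs_initiation(x, 385513)[
      c("pct_no_init", "pct_cessation")])), 100)
})
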