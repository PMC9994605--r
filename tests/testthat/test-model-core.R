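# Compartmental engine: single transitions, projection, conservation.

test_that("empty population stays empty apart from births", {
  st <- population_state(2000, stratum = "NoSPD")
  nxt <- advance_year(st, flat_rates(), zero_mortality(),
                      births = c(10, 12))
  expect_equal(sum(nxt$counts), 22)
  expect_equal(nxt$counts[1, , "never"], c(female = 10, male = 12))
  expect_equal(nxt$year, 2001L)
})

test_that("single initiation transition matches hand computation", {
  # 1000 never smokers aged 20, initiation 0.02, zero mortality
  st <- single_cell_state(age = 20, gender = 2, state = 1, n = 1000)
  nxt <- advance_year(st, flat_rates(init = 0.02, cess = 0), zero_mortality())
  expect_equal(nxt$counts[22, 2, "never"], 980)
  expect_equal(nxt$counts[22, 2, "current"], 20)
  expect_equal(sum(nxt$counts), 1000)
})

test_that("newly quit smokers appear at ysq = 1 and shift thereafter", {
  st <- single_cell_state(age = 30, gender = 1, state = 2, n = 100)
  r <- flat_rates(init = 0, cess = 0.4)
  n1 <- advance_year(st, r, zero_mortality())
  expect_equal(n1$counts[32, 1, "former1"], 40)
  expect_equal(n1$counts[32, 1, "current"], 60)
  n2 <- advance_year(n1, r, zero_mortality())
  expect_equal(n2$counts[33, 1, "former2"], 40) # last year's quitters moved up
  expect_equal(n2$counts[33, 1, "former1"], 24) # 60 * 0.4
})

test_that("terminal ysq bin absorbs and retains long-quit former smokers", {
  cnt <- array(0, c(100, 2, 22))
  cnt[51, 1, 21] <- 5 # former, ysq 19
  cnt[51, 1, 22] <- 7 # terminal 20+ bin
  st <- population_state(2000, cnt, "NoSPD")
  nxt <- advance_year(st, flat_rates(), zero_mortality())
  expect_equal(nxt$counts[52, 1, "former20"], 12)
  expect_equal(sum(nxt$counts[, , "former19"]), 0)
})

test_that("conservation holds at every step: in = out + deaths + exits - births", {
  inp <- std_inputs()
  st <- inp$base$NoSPD
  b <- inp$births$NoSPD
  for (i in 1:25) {
    nxt <- advance_year(st, inp$rates, inp$mort, scenario_status_quo(), b)
    inflow <- sum(st$counts) + sum(b)
    outflow <- sum(nxt$counts) + attr(nxt, "deaths") + attr(nxt, "exits")
    expect_lt(abs(inflow - outflow) / inflow, 1e-9)
    st <- nxt
  }
})

test_that("no relapse: former-smoker mass only grows under zero mortality", {
  inp <- std_inputs()
  st <- inp$base$SPD
  prev_former <- sum(st$counts[, , 3:22])
  for (i in 1:10) {
    st <- advance_year(st, inp$rates, zero_mortality(),
                       scenario_status_quo(), c(0, 0))
    f <- sum(st$counts[, , 3:22])
    expect_gte(f + 1e-9, prev_former)
    prev_former <- f
  }
})

test_that("former smokers never appear below age 19 without forced cessation", {
  inp <- std_inputs()
  traj <- project(inp$base$NoSPD, inp$rates, inp$mort, scenario_status_quo(),
                  inp$cfg$base_year + 30, inp$births$NoSPD)
  for (st in traj)
    expect_equal(sum(st$counts[1:19, , 3:22]), 0)
})

test_that("projection over zero years returns the initial state", {
  inp <- std_inputs()
  traj <- project(inp$base$NoSPD, inp$rates, inp$mort,
                  end_year = inp$cfg$base_year)
  expect_length(traj, 1)
  expect_identical(traj[[1]], inp$base$NoSPD)
  expect_error(project(inp$base$NoSPD, inp$rates, inp$mort,
                       end_year = inp$cfg$base_year - 1),
               "end_year")
})

test_that("projection is deterministic", {
  inp <- std_inputs()
  t1 <- project(inp$base$SPD, inp$rates, inp$mort, scenario_status_quo(),
                2010, inp$births$SPD)
  t2 <- project(inp$base$SPD, inp$rates, inp$mort, scenario_status_quo(),
                2010, inp$births$SPD)
  expect_identical(t1[[length(t1)]]$counts, t2[[length(t2)]]$counts)
})

test_that("missing cohort rates raise an explicit error", {
  inp <- std_inputs()
  narrow <- rate_schedule(inp$rates$initiation[, , 60:131, drop = FALSE],
                          inp$rates$cessation[, , 60:131, drop = FALSE],
                          inp$cfg$cohorts[60:131])
  expect_error(advance_year(inp$base$NoSPD, narrow, inp$mort),
               "missing rate entry")
})

test_that("smoking prevalence equals a brute-force recount", {
  inp <- std_inputs()
  traj <- project(inp$base$SPD, apply_scaling(inp$rates, inp$truth),
                  inp$mort, scenario_status_quo(), 2005, inp$births$SPD)
  st <- traj[["2005"]]
  for (g in c("female", "male")) {
    # brute-force loop over compartments
    cur <- 0; tot <- 0
    gi <- match(g, c("female", "male"))
    for (a in 18:99) for (s in 1:22) {
      v <- st$counts[a + 1, gi, s]
      tot <- tot + v
      if (s == 2) cur <- cur + v
    }
    expect_equal(smoking_prevalence(st, g), cur / tot)
  }
  expect_error(smoking_prevalence(population_state(2000), "male"),
               "undefined")
  expect_error(smoking_prevalence(st, "male", age_lo = 50, age_hi = 40),
               "age_lo")
})

test_that("three-age toy trajectory matches an independent scalar stepper", {
  # Independent implementation: explicit per-person-group arithmetic for a
  # toy world with ages 20-22 occupied, two years, constant rates.
  init_p <- 0.03; cess_p <- 0.1; q_never <- 0.01; hr <- 2
  cnt <- array(0, c(100, 2, 22))
  cnt[21, 1, 1] <- 500  # age 20 never
  cnt[21, 1, 2] <- 100  # age 20 current
  cnt[22, 1, 2] <- 80   # age 21 current
  cnt[23, 1, 3] <- 30   # age 22 former, ysq 1
  st <- population_state(2000, cnt, "NoSPD")

  base <- array(q_never, c(100, 2, 1))
  mort <- mortality_model(base, 2000, matrix(hr, 5, 2), hr_spd = 1,
                          lambda = 0.5)
  rates <- flat_rates(init = init_p, cess = cess_p)

  # scalar oracle, one year
  q_cur <- q_never * hr
  q_fs1 <- q_never + (q_cur - q_never) * exp(-0.5 * 1)
  nv20 <- 500 * (1 - q_never); cu20 <- 100 * (1 - q_cur)
  cu21 <- 80 * (1 - q_cur); fo22 <- 30 * (1 - q_fs1)
  exp21_never <- nv20 * (1 - init_p)
  exp21_cur <- cu20 * (1 - cess_p) + nv20 * init_p
  exp21_fs1 <- cu20 * cess_p
  exp22_cur <- cu21 * (1 - cess_p)
  exp22_fs1 <- cu21 * cess_p
  exp23_fs2 <- fo22

  nxt <- advance_year(st, rates, mort)
  expect_equal(nxt$counts[22, 1, 1], exp21_never)
  expect_equal(nxt$counts[22, 1, 2], exp21_cur)
  expect_equal(nxt$counts[22, 1, 3], exp21_fs1)
  expect_equal(nxt$counts[23, 1, 2], exp22_cur)
  expect_equal(nxt$counts[23, 1, 3], exp22_fs1)
  expect_equal(nxt$counts[24, 1, 4], exp23_fs2)

  # second year: ysq-1 bin shifts to ysq-2, new quitters behind them
  nxt2 <- advance_year(nxt, rates, mort)
  expect_equal(nxt2$counts[23, 1, 4], exp21_fs1 * (1 - q_fs1))
  expect_equal(nxt2$counts[23, 1, 3],
               exp21_cur * (1 - q_cur) * cess_p)
})
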