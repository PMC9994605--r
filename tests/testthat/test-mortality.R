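# Mortality model: hazard-ratio composition, ysq decay, life tables.

test_that("mu composes baseline and hazard ratios as specified", {
  base <- array(0.01, c(100, 2, 1))
  mort <- mortality_model(base, 2000, matrix(2, 5, 2), hr_spd = 1,
                          lambda = 0.15)
  expect_equal(mu(mort, "never", age = 40, gender = "male", year = 2000),
               0.01, ignore_attr = TRUE)
  expect_equal(mu(mort, "current", age = 40, gender = "male", year = 2000),
               0.02, ignore_attr = TRUE)
  # mu_fs = mu_ns + (mu_cs - mu_ns) exp(-lambda ysq) at ysq = 5
  expect_equal(mu(mort, "former", ysq = 5, age = 40, gender = "male",
                  year = 2000),
               0.01 + 0.01 * exp(-0.75), ignore_attr = TRUE)
  # interpolation anchors: ysq = 0 gives mu_cs; ysq -> Inf gives mu_ns
  expect_equal(mu(mort, "former", ysq = 0, age = 40, gender = "male",
                  year = 2000), 0.02, ignore_attr = TRUE)
  expect_equal(mu(mort, "former", ysq = 1e6, age = 40, gender = "male",
                  year = 2000), 0.01, ignore_attr = TRUE)
  expect_error(mu(mort, "never", age = 120, gender = "male", year = 2000),
               "age")
})

test_that("SPD hazard ratio multiplies every smoking state", {
  base <- array(0.01, c(100, 2, 1))
  mort <- mortality_model(base, 2000, matrix(2, 5, 2), hr_spd = 1.3,
                          lambda = 0.15)
  for (s in c("never", "current")) {
    no <- mu(mort, s, age = 50, gender = "female", year = 2000,
             stratum = "NoSPD")
    yes <- mu(mort, s, age = 50, gender = "female", year = 2000,
              stratum = "SPD")
    expect_equal(yes, no * 1.3, ignore_attr = TRUE)
  }
})

test_that("former-smoker mortality is monotone in ysq and bounded", {
  inp <- std_inputs()
  mort <- inp$mort
  for (age in c(25, 45, 60, 75, 90)) for (g in c("female", "male")) {
    ns <- mu(mort, "never", age = age, gender = g, year = 2010,
             stratum = "SPD")
    cs <- mu(mort, "current", age = age, gender = g, year = 2010,
             stratum = "SPD")
    fs <- vapply(1:25, function(k)
      mu(mort, "former", ysq = k, age = age, gender = g, year = 2010,
         stratum = "SPD"), numeric(1))
    expect_true(all(diff(fs) <= 0))
    expect_true(all(fs >= ns - 1e-15 & fs <= cs + 1e-15))
  }
})

test_that("probabilities are capped at 1 with a warning", {
  base <- array(0.6, c(100, 2, 1))
  mort <- mortality_model(base, 2000, matrix(2, 5, 2), hr_spd = 1,
                          lambda = 0.15)
  expect_warning(
    v <- mu(mort, "current", age = 40, gender = "male", year = 2000),
    "capped")
  expect_equal(v, 1, ignore_attr = TRUE)
})

test_that("zero-mortality life table gives e(a) = 99.5 - a", {
  mort <- zero_mortality()
  lt <- build_life_table(mort, "NoSPD", 2000)
  expect_equal(lt$e_ns[, "female"], 99.5 - 0:99, ignore_attr = TRUE)
  expect_equal(lt$e_ns[, "male"], 99.5 - 0:99, ignore_attr = TRUE)
})

test_that("constant-q life table matches a brute-force cohort extinction", {
  q <- 0.05
  mort <- mortality_model(array(q, c(100, 2, 1)), 2000, matrix(1, 5, 2),
                          hr_spd = 1, lambda = 0.1)
  lt <- build_life_table(mort, "NoSPD", 2000)
  # deterministic cohort extinction with half-year credit in the death year
  alive <- 1
  py <- 0
  for (a in 0:98) {
    py <- py + alive - 0.5 * alive * q
    alive <- alive * (1 - q)
  }
  py <- py + 0.5 * alive # closure at 99: all remaining die
  expect_equal(lt$e_ns[1, "male"], py, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hr_spd = 1 makes SPD and no-SPD life tables identical", {
  base <- array(0, c(100, 2, 1))
  base[, 1, 1] <- pmin(2e-5 * exp(0.09 * 0:99) + 4e-4, 1)
  base[, 2, 1] <- pmin(3e-5 * exp(0.09 * 0:99) + 5e-4, 1)
  mort1 <- mortality_model(base, 2000, matrix(2, 5, 2), hr_spd = 1,
                           lambda = 0.1)
  expect_equal(build_life_table(mort1, "SPD", 2000)$e_ns,
               build_life_table(mort1, "NoSPD", 2000)$e_ns)
  # and hr_spd > 1 shortens SPD never-smoker life expectancy at every age
  mort2 <- mortality_model(base, 2000, matrix(2, 5, 2), hr_spd = 1.4,
                           lambda = 0.1)
  # strict at every age below the closure (e(99) = 0.5 under any hazard)
  expect_true(all(build_life_table(mort2, "SPD", 2000)$e_ns[1:99, ] <
                    build_life_table(mort2, "NoSPD", 2000)$e_ns[1:99, ]))
})

test_that("uniformly higher death probabilities lower life expectancy", {
  inp <- std_inputs()
  lt0 <- build_life_table(inp$mort, "NoSPD", 2000)
  bumped <- mortality_model(pmin(inp$mort$baseline + 0.01, 1),
                            inp$mort$years, inp$mort$hr_current,
                            inp$mort$hr_spd, inp$mort$lambda)
  lt1 <- build_life_table(bumped, "NoSPD", 2000)
  expect_true(all(lt1$e_ns[1:99, ] < lt0$e_ns[1:99, ]))
})

test_that("life-table consistency: e(a) < e(a-1) + 1", {
  inp <- std_inputs()
  lt <- build_life_table(inp$mort, "SPD", 2010)
  for (g in 1:2)
    expect_true(all(diff(lt$e_ns[, g]) < 1))
})
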