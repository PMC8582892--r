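test_that("station placement is seeded, in-bounds, and seed-sensitive", {
  cfg <- sim_config(n_stations = 5, seed = 1)
  s1 <- generate_stations(cfg)
  s2 <- generate_stations(cfg)
  expect_identical(s1, s2)
  expect_false(any(duplicated(s1$station_id)))
  b <- cfg$bounds
  expect_true(all(s1$lon >= b[1] & s1$lon <= b[2]))
  expect_true(all(s1$lat >= b[3] & s1$lat <= b[4]))
  one <- generate_stations(sim_config(n_stations = 1, seed = 2))
  expect_equal(nrow(one), 1)
  expect_true(one$lon >= b[1] && one$lon <= b[2])
  s20a <- generate_stations(sim_config(n_stations = 20, seed = 1))
  s20b <- generate_stations(sim_config(n_stations = 20, seed = 2))
  expect_false(isTRUE(all.equal(s20a$lon, s20b$lon)))
  expect_error(sim_config(n_stations = 0), "n_stations")
})

test_that("noise-free plume-free measurements equal the pollutant baseline and are never negative", {
  cfg <- sim_config(n_stations = 3, n_days = 10, n_plumes = 0, rho = 0,
                    noise_sd = 0, missing_rate = 0, seed = 1)
  st <- generate_stations(cfg)
  m <- simulate_measurements(st, cfg)
  for (pol in cfg$pollutants)
    expect_true(all(m$value[m$pollutant == pol] == cfg$baseline[[pol]]))
  # non-negativity for a noisy seeded run
  cfg2 <- sim_config(n_stations = 4, n_days = 30, noise_sd = 1.5, seed = 3,
                     missing_rate = 0)
  m2 <- simulate_measurements(generate_stations(cfg2), cfg2)
  expect_true(all(m2$value >= 0))
  # one row per (station, day, pollutant)
  expect_false(any(duplicated(m2[c("station_id", "day", "pollutant")])))
  expect_error(sim_config(rho = 1), "rho")
})

test_that("MCAR missingness recovers the configured rate over 10,000 cells", {
  # 10 stations x 200 days x 5 pollutants = 10,000 cells
  cfg <- sim_config(n_stations = 10, n_days = 200, missing_rate = 0.3,
                    missing_mechanism = "MCAR", seed = 4)
  m <- simulate_measurements(generate_stations(cfg), cfg)
  expect_equal(nrow(m), 10000)
  expect_equal(mean(is.na(m$value)), 0.3, tolerance = 0.02 / 0.3)
})

test_that("MAR missingness removes high values preferentially at the configured overall rate", {
  cfg <- sim_config(n_stations = 10, n_days = 200, missing_rate = 0.25,
                    missing_mechanism = "MAR", seed = 5)
  cfg0 <- cfg; cfg0$missing_rate <- 0
  st <- generate_stations(cfg)
  m <- simulate_measurements(st, cfg)
  full <- simulate_measurements(st, cfg0)  # same values, no missingness
  expect_equal(mean(is.na(m$value)), 0.25, tolerance = 0.03 / 0.25)
  miss <- is.na(m$value)
  expect_gt(mean(full$value[miss]), mean(full$value[!miss]))
})

test_that("cohort ages are right-skewed, clipped, and categorized per the study bins", {
  cfg <- sim_config(n_patients = 5000, seed = 6)
  co <- generate_cohort(cfg)
  expect_true(all(co$age >= 1 / 3 & co$age <= 86))
  expect_gt(mean(co$age) - median(co$age), 0)  # right skew
  expect_equal(co$age_category, categorize_age(co$age))
  expect_false(any(duplicated(co$id)))
  # configured male proportion recovered within binomial tolerance
  expect_equal(mean(co$gender == "male"), 0.53, tolerance = 0.02 / 0.53)
  expect_true(all(co$day > cfg$lag))
})

test_that("age categories match the study's coding at the boundaries", {
  expect_equal(categorize_age(0.33), 1L)  # four-month-old infant
  expect_equal(categorize_age(0.5), 1L)
  expect_equal(categorize_age(70), 5L)
  expect_equal(categorize_age(86), 5L)    # eldest patient
  expect_equal(categorize_age(65), 4L)    # elderly is strictly over 65
  expect_equal(categorize_age(65.01), 5L)
  expect_equal(categorize_age(c(1, 2, 9, 9.5, 19, 20)), c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(categorize_age(-1), "invalid age")
})

test_that("the outcome model hits the intercept-implied prevalence and responds to coefficients", {
  cfg <- sim_config(n_patients = 10000, beta = zero_beta(qlogis(0.19)), seed = 7)
  co <- generate_cohort(cfg)
  set.seed(70)
  expo <- data.frame(id = co$id, NO2 = runif(10000), SO2 = runif(10000),
                     PM10 = runif(10000), CO = runif(10000), O3 = runif(10000))
  out <- assign_outcomes(co, expo, cfg)
  expect_equal(mean(out$outcome), 0.19, tolerance = 0.02 / 0.19)
  # intercept -> -Inf gives no cases
  cfg0 <- cfg; cfg0$beta["intercept"] <- -Inf
  expect_true(all(assign_outcomes(co, expo, cfg0)$outcome == 0))
  # a strong SO2 effect raises SO2 among cases
  cfgb <- cfg
  cfgb$beta["intercept"] <- 0
  cfgb$beta["SO2"] <- 3
  outb <- assign_outcomes(co, expo, cfgb)
  expect_gt(mean(expo$SO2[outb$outcome == 1]), mean(expo$SO2[outb$outcome == 0]))
  # incomplete exposures are a precondition failure
  expo_na <- expo; expo_na$SO2[1] <- NA
  expect_error(assign_outcomes(co, expo_na, cfg), "complete")
})

test_that("a full synthetic study is reproducible byte-for-byte from its seed", {
  cfg <- sim_config(n_stations = 4, n_patients = 60, n_days = 40, seed = 8)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  d1 <- tempfile(); d2 <- tempfile()
  write_study_csvs(s1, d1); write_study_csvs(s2, d2)
  for (f in c("stations.csv", "measurements.csv", "cohort.csv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # round trip through CSV preserves the tables
  back <- read_study_csvs(d1, start_date = cfg$start_date)
  expect_equal(back$stations$lon, s1$stations$lon, tolerance = 1e-12)
  expect_equal(back$measurements$day, s1$measurements$day)
  expect_equal(back$cohort$outcome, s1$cohort$outcome)
  unlink(c(d1, d2), recursive = TRUE)
})
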