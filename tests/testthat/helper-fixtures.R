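# shared fixture builders; everything seeded, nothing stored on disk

# two Gaussian clusters in d dimensions separated by `sep` sd along the
# first axis, labels 0/1 by cluster
make_cluster_data <- function(n, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * d), n, d)
  x[, 1] <- x[, 1] + sep * y
  list(x = x, y = y)
}

# all-zero outcome coefficients with a chosen intercept
zero_beta <- function(intercept = 0) {
  c(intercept = intercept, NO2 = 0, SO2 = 0, PM10 = 0, CO = 0, O3 = 0,
    age = 0, male = 0, gender_missing = 0, race_1 = 0, race_2 = 0, race_3 = 0)
}

# tiny complete station/measurement/cohort triple for exposure tests
make_mini_study <- function(n_stations = 3, n_days = 12, n_patients = 10,
                            seed = 1) {
  cfg <- sim_config(n_stations = n_stations, n_patients = n_patients,
                    n_days = n_days, missing_rate = 0, seed = seed)
  stations <- generate_stations(cfg)
  measurements <- simulate_measurements(stations, cfg)
  cohort <- generate_cohort(cfg)
  list(cfg = cfg, stations = stations, measurements = measurements,
       cohort = cohort)
}
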