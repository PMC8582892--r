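#' Configuration for the synthetic study generator
#'
#' The generator emulates the structure of a two-city exposure study: a
#' sparse network of air-quality monitoring stations reporting daily
#' pollutant concentrations with missingness, and a patient cohort with
#' demographics, geocoded coordinates, a presentation date, and a binary
#' outcome (1 = asthma, 0 = non-asthma) driven by lagged exposures and
#' demographics.
#'
#' Pollutant surfaces are a per-pollutant baseline plus isotropic Gaussian
#' source plumes, modulated in time by a log-AR(1) factor with
#' autocorrelation `rho`, with multiplicative lognormal observation noise
#' (unit mean), truncated at zero. Ages are gamma-distributed
#' (right-skewed), clipped to 4 months – 86 years. The outcome model is
#' logistic in the standardized lagged exposures, a centered age category, a
#' male indicator and race indicators; the default coefficients make SO2 the
#' strongest pollutant effect (|b_SO2| > |b_PM10| >= |b_NO2|), age positive,
#' and the intercept targets roughly 19% prevalence.
#'
#' @param n_stations,n_patients,n_days network, cohort and series sizes.
#' @param bounds region bounding box, `c(lon_min, lon_max, lat_min, lat_max)`
#'   in degrees.
#' @param pollutants pollutant names; NO2, SO2 and PM10 are required
#'   downstream, CO and O3 optional.
#' @param baseline named per-pollutant baseline concentration (ug/m3).
#' @param n_plumes number of Gaussian source plumes per pollutant.
#' @param plume_amp,plume_sd plume amplitude (ug/m3) and spatial scale
#'   (degrees).
#' @param rho temporal autocorrelation of the log daily factor, in `[0, 1)`.
#' @param noise_sd standard deviation of both the AR(1) log innovations and
#'   the lognormal observation noise; 0 gives noise-free series.
#' @param missing_rate fraction of station-day-pollutant cells set missing.
#' @param missing_mechanism `"MCAR"` (uniform) or `"MAR"` (probability
#'   increasing with the value's rank, so high concentrations are more often
#'   missing).
#' @param male_prop,missing_gender_prop gender mix of the cohort.
#' @param race_props probabilities of race categories 0 (African or Black),
#'   1 (White), 2 (Indian), 3 (Other).
#' @param age_shape,age_scale gamma parameters of the age distribution in
#'   years.
#' @param start_date first day of the measurement series (ISO date string).
#' @param lag exposure lag in days (2 = exposure two days before clinical
#'   presentation, allowing for the inflammatory delay).
#' @param beta named outcome coefficients on the logit scale: `intercept`
#'   plus one per pollutant (standardized exposure), `age` (centered age
#'   category), `male`, `gender_missing`, and `race_1`..`race_3` (race 0 is
#'   the reference).
#' @param seed integer seed fixing all randomness end-to-end.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 8L, n_patients = 483L, n_days = 365L,
                       bounds = c(27.8, 28.4, -26.4, -25.6),
                       pollutants = c("NO2", "SO2", "PM10", "CO", "O3"),
                       baseline = c(NO2 = 30, SO2 = 15, PM10 = 45, CO = 800, O3 = 40),
                       n_plumes = 3L, plume_amp = 0.6, plume_sd = 0.12,
                       rho = 0.6, noise_sd = 0.25,
                       missing_rate = 0.2,
                       missing_mechanism = c("MCAR", "MAR"),
                       male_prop = 0.53, missing_gender_prop = 0.015,
                       race_props = c(0.74, 0.13, 0.05, 0.08),
                       age_shape = 2, age_scale = 18,
                       start_date = "2017-01-01", lag = 2L,
                       beta = NULL, seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  if (n_stations < 1) stop("invalid config: n_stations must be >= 1")
  if (n_patients < 1) stop("invalid config: n_patients must be >= 1")
  if (n_days < 1) stop("invalid config: n_days must be >= 1")
  if (length(bounds) != 4L || bounds[1] >= bounds[2] || bounds[3] >= bounds[4])
    stop("invalid config: degenerate region bounds")
  if (rho < 0 || rho >= 1) stop("invalid config: rho must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("invalid config: missing_rate must be in [0, 1)")
  if (male_prop < 0 || male_prop + missing_gender_prop > 1)
    stop("invalid config: gender proportions out of range")
  if (abs(sum(race_props) - 1) > 1e-8)
    stop("invalid config: race_props must sum to 1")
  if (!all(c("NO2", "SO2", "PM10") %in% pollutants))
    stop("invalid config: NO2, SO2 and PM10 are required pollutants")
  if (is.null(beta)) {
    # intercept carries the logit-normal correction sqrt(1 + 0.346 * var(eta))
    # for the default slopes (var(eta) ~= 0.57), so the marginal prevalence
    # stays ~0.19 when the slopes are active; with all slopes zero the
    # prevalence is plogis(intercept) exactly
    beta <- c(intercept = qlogis(0.19) * sqrt(1 + 0.346 * 0.567),
              NO2 = 0.15, SO2 = 0.60, PM10 = 0.30, CO = 0.05, O3 = 0.05,
              age = 0.35, male = 0.10, gender_missing = 0,
              race_1 = -0.10, race_2 = -0.05, race_3 = 0)
    beta <- beta[c("intercept", pollutants, "age", "male", "gender_missing",
                   "race_1", "race_2", "race_3")]
  }
  structure(list(
    n_stations = as.integer(n_stations), n_patients = as.integer(n_patients),
    n_days = as.integer(n_days), bounds = bounds, pollutants = pollutants,
    baseline = baseline[pollutants], n_plumes = as.integer(n_plumes),
    plume_amp = plume_amp, plume_sd = plume_sd, rho = rho,
    noise_sd = noise_sd, missing_rate = missing_rate,
    missing_mechanism = missing_mechanism, male_prop = male_prop,
    missing_gender_prop = missing_gender_prop, race_props = race_props,
    age_shape = age_shape, age_scale = age_scale,
    start_date = start_date, lag = as.integer(lag),
    beta = beta, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Place monitoring stations in the study region
#'
#' Stations are placed quasi-uniformly: on a regular grid covering the
#' bounding box, jittered within each cell, so the network covers the region
#' without being artificially regular.
#'
#' @param config a [sim_config()].
#' @return data frame `stations` with columns `station_id`, `lon`, `lat`.
#' @export
generate_stations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_stations
  b <- config$bounds
  set.seed(config$seed)
  ncol_g <- ceiling(sqrt(n)); nrow_g <- ceiling(n / ncol_g)
  cells <- expand.grid(i = seq_len(ncol_g), j = seq_len(nrow_g))[seq_len(n), ]
  dx <- (b[2] - b[1]) / ncol_g; dy <- (b[4] - b[3]) / nrow_g
  lon <- b[1] + (cells$i - runif(n)) * dx
  lat <- b[3] + (cells$j - runif(n)) * dy
  data.frame(station_id = sprintf("S%02d", seq_len(n)),
             lon = lon, lat = lat, stringsAsFactors = FALSE)
}

# deterministic per-pollutant plume field: amplitude relative to baseline
pollutant_field <- function(config, pollutant, lon, lat) {
  base <- config$baseline[[pollutant]]
  if (config$n_plumes == 0L) return(rep(base, length(lon)))
  # plume centers derived from the config seed, offset per pollutant so
  # pollutants have distinct (but fixed) spatial structure
  set.seed(config$seed + 1000L + match(pollutant, config$pollutants))
  b <- config$bounds
  cx <- runif(config$n_plumes, b[1], b[2])
  cy <- runif(config$n_plumes, b[3], b[4])
  f <- rep(base, length(lon))
  for (m in seq_len(config$n_plumes)) {
    d2 <- (lon - cx[m])^2 + (lat - cy[m])^2
    f <- f + base * config$plume_amp * exp(-d2 / (2 * config$plume_sd^2))
  }
  f
}

#' Simulate daily pollutant measurements at the stations
#'
#' For each pollutant, a station's value on day d is the spatial field at
#' the station (baseline + Gaussian plumes), times a shared log-AR(1) daily
#' factor with autocorrelation `rho`, times unit-mean lognormal observation
#' noise, truncated at zero. Missingness is then applied cell-wise at the
#' configured rate (MCAR: uniform; MAR: probability proportional to the
#' value's rank within its pollutant, mean equal to the rate).
#'
#' @param stations data frame from [generate_stations()].
#' @param config a [sim_config()].
#' @return data frame `measurements` with columns `station_id`, `day`
#'   (integer index, 1 = `start_date`), `pollutant`, `value` (NA when
#'   missing).
#' @export
simulate_measurements <- function(stations, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(stations) < 1L) stop("no stations")
  if (config$rho >= 1) stop("invalid config: rho must be < 1")
  n_s <- nrow(stations); n_d <- config$n_days
  set.seed(config$seed + 1L)
  out <- vector("list", length(config$pollutants))
  for (pi in seq_along(config$pollutants)) {
    pol <- config$pollutants[pi]
    field <- pollutant_field(config, pol, stations$lon, stations$lat)
    # shared temporal factor, lognormal AR(1); ==1 when noise_sd == 0
    e <- rnorm(n_d, 0, config$noise_sd)
    logT <- numeric(n_d)
    logT[1L] <- e[1L]
    if (n_d > 1L)
      for (d in 2:n_d) logT[d] <- config$rho * logT[d - 1L] + e[d]
    tfac <- exp(logT)
    # station x day values with unit-mean lognormal observation noise
    s2 <- config$noise_sd^2
    noise <- matrix(exp(rnorm(n_s * n_d, -s2 / 2, config$noise_sd)), n_s, n_d)
    vals <- pmax(outer(field, tfac) * noise, 0)
    df <- data.frame(
      station_id = rep(stations$station_id, times = n_d),
      day = rep(seq_len(n_d), each = n_s),
      pollutant = pol,
      value = as.numeric(vals),
      stringsAsFactors = FALSE
    )
    # uniforms drawn unconditionally so the value stream is identical for
    # any missing_rate under the same seed (used by simulate_study)
    n_cells <- nrow(df)
    u <- runif(n_cells)
    if (config$missing_rate > 0) {
      if (config$missing_mechanism == "MCAR") {
        miss <- u < config$missing_rate
      } else {
        p <- config$missing_rate * 2 * rank(df$value, ties.method = "first") /
          (n_cells + 1)
        miss <- u < pmin(p, 1)
      }
      df$value[miss] <- NA_real_
    }
    out[[pi]] <- df
  }
  do.call(rbind, out)
}

#' Bin age in years into the study's five categories
#'
#' Category 1: infants, birth to 1 year; 2: children, through 9 years;
#' 3: adolescents, through 19 years; 4: adults, through 65 years;
#' 5: elderly, over 65. The printed labels leave ages in (1, 2) years
#' unlabelled; they fall in category 2, the only gap-free completion.
#'
#' @param age age(s) in years, >= 0.
#' @return integer category 1..5.
#' @examples
#' categorize_age(c(0.33, 5, 15, 40, 86))  # 1 2 3 4 5
#' @export
categorize_age <- function(age) {
  if (any(age < 0)) stop("invalid age: must be >= 0")
  findInterval(age, c(-Inf, 1, 9, 19, 65), left.open = TRUE)
}

#' Generate a patient cohort (without outcomes)
#'
#' Ages are gamma-distributed (right-skewed) and clipped to 4 months – 86
#' years; gender and race follow the configured proportions (including a
#' small missing-gender fraction); coordinates are uniform in the region;
#' presentation days are uniform in `[lag + 1, n_days]` so every patient has
#' a lagged exposure day inside the measurement series.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `id`, `age`, `age_category`, `gender`
#'   (`"male"`, `"female"`, `"missing"`), `race` (0..3), `lon`, `lat`,
#'   `day` (presentation day index).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  b <- config$bounds
  set.seed(config$seed + 2L)
  age <- pmin(pmax(rgamma(n, shape = config$age_shape, scale = config$age_scale),
                   1 / 3), 86)
  gender <- sample(c("male", "female", "missing"), n, replace = TRUE,
                   prob = c(config$male_prop,
                            1 - config$male_prop - config$missing_gender_prop,
                            config$missing_gender_prop))
  race <- sample(0:3, n, replace = TRUE, prob = config$race_props)
  day <- sample(seq(config$lag + 1L, config$n_days), n, replace = TRUE)
  data.frame(
    id = sprintf("P%04d", seq_len(n)),
    age = age,
    age_category = categorize_age(age),
    gender = gender,
    race = race,
    lon = runif(n, b[1], b[2]),
    lat = runif(n, b[3], b[4]),
    day = day,
    stringsAsFactors = FALSE
  )
}

#' Assign binary outcomes from lagged exposures and demographics
#'
#' The outcome (1 = asthma) is a Bernoulli draw with
#' `P(1) = plogis(b0 + sum_j b_j x_j)` where the `x_j` are the standardized
#' per-patient lagged pollutant exposures, the centered age category, a male
#' indicator, a missing-gender indicator, and race indicators (race 0 is the
#' reference). With all slope coefficients zero the prevalence is
#' `plogis(intercept)` exactly in expectation.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param exposures data frame with column `id` plus one complete numeric
#'   column per pollutant named in `config$beta`.
#' @param config a [sim_config()]; `config$beta` holds the coefficients.
#' @param seed seed for the Bernoulli draw; defaults to `config$seed + 3`.
#' @return the cohort with an added integer `outcome` column.
#' @export
assign_outcomes <- function(cohort, exposures, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  beta <- config$beta
  pols <- intersect(names(beta), config$pollutants)
  ex <- exposures[match(cohort$id, exposures$id), , drop = FALSE]
  if (any(is.na(ex$id)) || any(!pols %in% names(ex)) ||
      any(is.na(as.matrix(ex[pols]))))
    stop("exposure vector must be complete for every patient")
  zs <- scale(as.matrix(ex[pols]))
  zs[is.nan(zs)] <- 0  # constant exposure column carries no signal
  eta <- beta[["intercept"]] +
    as.numeric(zs %*% beta[pols]) +
    beta[["age"]] * (cohort$age_category - mean(cohort$age_category)) +
    beta[["male"]] * (cohort$gender == "male") +
    beta[["gender_missing"]] * (cohort$gender == "missing") +
    beta[["race_1"]] * (cohort$race == 1) +
    beta[["race_2"]] * (cohort$race == 2) +
    beta[["race_3"]] * (cohort$race == 3)
  if (is.null(seed)) seed <- config$seed + 3L
  set.seed(seed)
  cohort$outcome <- rbinom(nrow(cohort), 1L, plogis(eta))
  cohort
}

#' Generate a complete synthetic study
#'
#' Runs [generate_stations()], [simulate_measurements()],
#' [generate_cohort()], computes lagged exposures at the true (noise-free
#' missingness-free) measurement values for outcome assignment, and
#' [assign_outcomes()]. Outcomes are driven by exposures interpolated from
#' the complete series, so downstream imputation and interpolation are
#' recovering a real signal.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study`: `stations`, `measurements` (with
#'   missingness), `cohort` (with outcomes), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stations <- generate_stations(config)
  measurements <- simulate_measurements(stations, config)
  cohort <- generate_cohort(config)
  # complete (pre-missingness) series for the outcome model: regenerate with
  # missing_rate 0 under the same seed, so observed values agree cell-wise
  cfg0 <- config; cfg0$missing_rate <- 0
  complete <- simulate_measurements(stations, cfg0)
  expo <- build_exposure_profiles(cohort, stations, complete,
                                  lag = config$lag, power = 2,
                                  pollutants = config$pollutants)
  cohort <- assign_outcomes(cohort, expo$profiles, config)
  structure(list(stations = stations, measurements = measurements,
                 cohort = cohort, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d stations, %d days, %d patients\n",
              nrow(x$stations), x$config$n_days, nrow(x$cohort)))
  cat(sprintf("  pollutants: %s; missing fraction %.3f (%s)\n",
              paste(x$config$pollutants, collapse = ", "),
              mean(is.na(x$measurements$value)), x$config$missing_mechanism))
  cat(sprintf("  outcome prevalence: %.3f\n", mean(x$cohort$outcome)))
  invisible(x)
}

#' Write or read a synthetic study as CSV files
#'
#' `stations.csv` (station_id, lon, lat), `measurements.csv` (station_id,
#' date, pollutant, value; empty field = missing) and `cohort.csv` (id, age,
#' age_category, gender, race, lon, lat, date, outcome). Dates are integer
#' day indices internally and ISO-8601 in the files.
#'
#' @param study a `sim_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `write_study_csvs()`: the directory, invisibly;
#'   `read_study_csvs()`: a list with `stations`, `measurements`, `cohort`
#'   (days as integer indices relative to `start_date`).
#' @param start_date origin used to convert ISO dates back to day indices.
#' @export
write_study_csvs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  origin <- as.Date(study$config$start_date)
  m <- study$measurements
  m$date <- format(origin + m$day - 1L)
  co <- study$cohort
  co$date <- format(origin + co$day - 1L)
  write.csv(study$stations, file.path(dir, "stations.csv"), row.names = FALSE)
  write.csv(m[c("station_id", "date", "pollutant", "value")],
            file.path(dir, "measurements.csv"), row.names = FALSE, na = "")
  write.csv(co[c("id", "age", "age_category", "gender", "race",
                 "lon", "lat", "date", "outcome")],
            file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study_csvs
#' @export
read_study_csvs <- function(dir, start_date = "2017-01-01") {
  stations <- read.csv(file.path(dir, "stations.csv"), stringsAsFactors = FALSE)
  m <- read.csv(file.path(dir, "measurements.csv"), stringsAsFactors = FALSE)
  co <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  for (col in c("station_id", "date", "pollutant", "value"))
    if (!col %in% names(m))
      stop(sprintf("measurements.csv is missing required column '%s'", col))
  origin <- as.Date(start_date)
  m$day <- as.integer(as.Date(m$date) - origin) + 1L
  co$day <- as.integer(as.Date(co$date) - origin) + 1L
  list(stations = stations,
       measurements = m[c("station_id", "day", "pollutant", "value")],
       cohort = co[setdiff(names(co), "date")])
}
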