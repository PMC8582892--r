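test_that("chained imputation returns complete tables untouched and never alters observed cells", {
  set.seed(1)
  x <- as.data.frame(matrix(rnorm(200), 50, 4))
  expect_identical(impute_chained(x), x)
  xm <- x
  holes <- cbind(sample(50, 12), sample(4, 12, replace = TRUE))
  xm[holes] <- NA
  done <- impute_chained(xm, n_sweeps = 5, seed = 2)
  expect_false(any(is.na(done)))
  obs <- !is.na(xm)
  expect_identical(as.matrix(done)[obs], as.matrix(xm)[obs])
  # seed determinism
  expect_identical(done, impute_chained(xm, n_sweeps = 5, seed = 2))
  expect_false(identical(done, impute_chained(xm, n_sweeps = 5, seed = 3)))
})

test_that("imputation recovers a perfect linear relation between collinear columns", {
  set.seed(4)
  x <- rnorm(100)
  tab <- data.frame(x = x, y = 2 * x)
  miss <- sample(100, 20)
  tab$y[miss] <- NA
  done <- impute_chained(tab, n_sweeps = 10, seed = 5)
  # residual sd of the generating line is 0; allow numerical noise only
  expect_equal(done$y[miss], 2 * x[miss], tolerance = 1e-6)
  expect_error(impute_chained(data.frame(a = c(NA, NA), b = c(1, 2))),
               "unimputable|at least 2")
})

test_that("measurement imputation fills all cells non-negatively and preserves observations", {
  cfg <- sim_config(n_stations = 5, n_days = 80, missing_rate = 0.25, seed = 6)
  m <- simulate_measurements(generate_stations(cfg), cfg)
  done <- impute_measurements(m, seed = 7)
  expect_false(any(is.na(done$value)))
  obs <- !is.na(m$value)
  expect_identical(done$value[obs], m$value[obs])
  expect_true(all(done$value >= 0))
})

test_that("z-scoring is exact, reusable on new data, and invertible", {
  sc <- scale_features(data.frame(a = c(1, 2, 3), b = c(0, 10, 50)))
  expect_equal(unname(colMeans(sc$scaled)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(sc$scaled, 2, sd)), c(1, 1), tolerance = 1e-8)
  # applying the stored scaler to the training data reproduces the output
  expect_equal(apply_scaler(sc, data.frame(a = c(1, 2, 3), b = c(0, 10, 50))),
               sc$scaled)
  # inverse recovers the input
  set.seed(8)
  x <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("p", "q", "r")))
  sc2 <- scale_features(x)
  expect_equal(invert_scaler(sc2, sc2$scaled), x, tolerance = 1e-10)
  expect_error(scale_features(data.frame(a = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("one-hot coding partitions each variable block and rejects unseen levels", {
  r <- encode_nominal(c(0, 2), 0:3, "race")
  expect_equal(unname(r[1, ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(r[2, ]), c(0L, 0L, 1L, 0L))
  g <- encode_nominal(c("missing", "male"), c("male", "female", "missing"),
                      "gender")
  expect_equal(g[1, "gender_missing"], c(gender_missing = 1L))
  set.seed(9)
  vals <- sample(0:3, 100, replace = TRUE)
  enc <- encode_nominal(vals, 0:3, "race")
  expect_true(all(rowSums(enc) == 1))
  # encoding is invertible
  expect_equal(apply(enc, 1, which.max) - 1L, vals)
  expect_error(encode_nominal(c(0, 9), 0:3, "race"), "unknown level")
})

test_that("the feature table is complete, scaled, and carries column metadata", {
  ms <- make_mini_study(n_stations = 3, n_days = 20, n_patients = 40, seed = 10)
  cohort <- assign_outcomes(
    ms$cohort,
    build_exposure_profiles(ms$cohort, ms$stations, ms$measurements,
                            lag = 2)$profiles,
    ms$cfg)
  prof <- build_exposure_profiles(cohort, ms$stations, ms$measurements,
                                  lag = 2)$profiles
  ft <- build_feature_table(cohort, prof)
  expect_false(any(is.na(ft$x)))
  cont <- ft$columns$column[ft$columns$type == "continuous"]
  expect_true(all(abs(colMeans(ft$x[, cont])) < 1e-8))
  expect_equal(unname(apply(ft$x[, cont], 2, sd)), rep(1, length(cont)),
               tolerance = 1e-8)
  ind <- ft$columns$column[ft$columns$type == "indicator"]
  expect_true(all(ft$x[, ind] %in% c(0, 1)))
  # gender and race blocks each sum to one per row
  expect_true(all(rowSums(ft$x[, grep("^gender_", colnames(ft$x))]) == 1))
  expect_true(all(rowSums(ft$x[, grep("^race_", colnames(ft$x))]) == 1))
  expect_equal(length(ft$y), nrow(ft$x))
})
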