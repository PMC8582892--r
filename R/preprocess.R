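#' Chained-equation imputation of a numeric table
#'
#' Iterative regression imputation: missing cells are initialized at their
#' column means, then for a fixed number of sweeps each column with
#' missingness is regressed (ordinary least squares) on all other columns
#' over its observed rows, and its missing entries are replaced by the
#' regression prediction plus a Gaussian draw from the residual
#' distribution. One completed dataset is returned (m = 1); observed cells
#' are never altered, and the whole procedure is fixed by `seed`.
#'
#' @param x numeric matrix or data frame with NAs; every column needs at
#'   least 2 observed values.
#' @param n_sweeps number of passes over the incomplete columns.
#' @param seed integer seed for the residual draws.
#' @return completed object of the same class and dimensions.
#' @export
impute_chained <- function(x, n_sweeps = 10L, seed = 1L) {
  was_df <- is.data.frame(x)
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  miss <- is.na(xm)
  if (!any(miss)) return(x)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0L))
    stop(sprintf("unimputable column (all missing): %s",
                 paste(colnames(xm)[n_obs == 0L], collapse = ", ")))
  if (any(n_obs < 2L))
    stop("every column needs at least 2 observed values")
  set.seed(seed)
  # initialize at column means
  mu <- colMeans(xm, na.rm = TRUE)
  for (j in which(colSums(miss) > 0L)) xm[miss[, j], j] <- mu[j]
  incomplete <- which(colSums(miss) > 0L)
  for (s in seq_len(n_sweeps)) {
    for (j in incomplete) {
      obs <- !miss[, j]
      X <- cbind(1, xm[, -j, drop = FALSE])
      fit <- tryCatch(qr(X[obs, , drop = FALSE]), error = function(e) NULL)
      if (is.null(fit)) next
      coefs <- qr.coef(fit, xm[obs, j])
      coefs[is.na(coefs)] <- 0  # aliased (collinear) predictors dropped
      res <- xm[obs, j] - as.numeric(X[obs, , drop = FALSE] %*% coefs)
      df <- sum(obs) - fit$rank
      sigma <- if (df > 0) sqrt(sum(res^2) / df) else 0
      pred <- as.numeric(X[!obs, , drop = FALSE] %*% coefs)
      xm[miss[, j], j] <- pred + rnorm(length(pred), 0, sigma)
    }
  }
  if (was_df) {
    out <- as.data.frame(xm)
    names(out) <- names(x)
    rownames(out) <- rownames(x)
    out
  } else xm
}

#' Impute missing station measurements
#'
#' Pivots the long measurement table to a day-by-series matrix (one column
#' per station-pollutant series), runs [impute_chained()], and returns the
#' completed long table. Series with fewer than 2 observed days cannot be
#' imputed and raise an error.
#'
#' @param measurements data frame with `station_id`, `day`, `pollutant`,
#'   `value`.
#' @param n_sweeps,seed passed to [impute_chained()].
#' @return the measurement table with all `value`s filled in.
#' @export
impute_measurements <- function(measurements, n_sweeps = 10L, seed = 1L) {
  col_id <- paste(measurements$station_id, measurements$pollutant, sep = "|")
  days <- sort(unique(measurements$day))
  cols <- sort(unique(col_id))
  wide <- matrix(NA_real_, length(days), length(cols),
                 dimnames = list(NULL, cols))
  wide[cbind(match(measurements$day, days), match(col_id, cols))] <-
    measurements$value
  completed <- impute_chained(wide, n_sweeps = n_sweeps, seed = seed)
  out <- measurements
  out$value <- completed[cbind(match(measurements$day, days),
                               match(col_id, cols))]
  # concentrations are non-negative; regression draws may dip below zero
  out$value[is.na(measurements$value)] <-
    pmax(out$value[is.na(measurements$value)], 0)
  out
}

#' Z-score scaling with stored parameters
#'
#' Centers and scales each column to mean 0, sd 1, and records the
#' per-column parameters so the identical transform can be applied to new
#' data ([apply_scaler()]) or inverted ([invert_scaler()]).
#'
#' @param x numeric matrix or data frame; all columns must have positive
#'   standard deviation.
#' @return list of class `feature_scaler` with `scaled`, `center`, `scale`.
#' @export
scale_features <- function(x) {
  xm <- as.matrix(x)
  ctr <- colMeans(xm)
  scl <- apply(xm, 2L, sd)
  bad <- which(scl == 0)
  if (length(bad) > 0L)
    stop(sprintf("constant column cannot be scaled: %s",
                 paste(colnames(xm)[bad], collapse = ", ")))
  structure(list(
    scaled = sweep(sweep(xm, 2L, ctr, `-`), 2L, scl, `/`),
    center = ctr, scale = scl
  ), class = "feature_scaler")
}

#' @rdname scale_features
#' @param scaler a `feature_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  xm <- as.matrix(x)[, names(scaler$center), drop = FALSE]
  sweep(sweep(xm, 2L, scaler$center, `-`), 2L, scaler$scale, `/`)
}

#' @rdname scale_features
#' @export
invert_scaler <- function(scaler, x) {
  xm <- as.matrix(x)
  sweep(sweep(xm, 2L, scaler$scale, `*`), 2L, scaler$center, `+`)
}

#' One-hot encoding of a nominal variable
#'
#' Full one-hot coding: one 0/1 indicator column per declared level
#' (including a missing-gender level where declared), so each row's
#' indicator block sums to exactly 1. Values outside the declared levels
#' raise an error.
#'
#' @param values vector of nominal values.
#' @param levels the complete set of levels, in column order.
#' @param prefix column-name prefix (`prefix_level`).
#' @return integer 0/1 matrix, one column per level.
#' @examples
#' encode_nominal(c(0, 2), levels = 0:3, prefix = "race")
#' @export
encode_nominal <- function(values, levels, prefix) {
  idx <- match(as.character(values), as.character(levels))
  if (any(is.na(idx)))
    stop(sprintf("unknown level(s) for %s: %s", prefix,
                 paste(unique(values[is.na(idx)]), collapse = ", ")))
  m <- matrix(0L, length(values), length(levels),
              dimnames = list(NULL, paste(prefix, levels, sep = "_")))
  m[cbind(seq_along(values), idx)] <- 1L
  m
}

#' Assemble the model-ready feature table
#'
#' Joins per-patient exposures with cohort demographics and produces the
#' matrix the SOM is trained on: z-scored pollutant exposures, a z-scored
#' ordinal age-category column (a single "age" segment on code plots), and
#' one-hot indicators for gender (male/female/missing) and race (0..3).
#' Scaling parameters are recorded so new patients can be transformed
#' identically.
#'
#' @param cohort data frame with `id`, `age_category`, `gender`, `race` (and
#'   `outcome` if present).
#' @param exposures data frame with `id` plus pollutant columns (from
#'   [build_exposure_profiles()]); patients without a profile are dropped.
#' @return list of class `feature_table`: `x` (numeric matrix), `y` (outcome
#'   vector or NULL), `id`, `scaler`, `columns` (per-column source-variable
#'   metadata).
#' @export
build_feature_table <- function(cohort, exposures) {
  keep <- match(exposures$id, cohort$id)
  if (any(is.na(keep))) stop("exposure ids not found in cohort")
  co <- cohort[keep, , drop = FALSE]
  pols <- setdiff(names(exposures), "id")
  cont <- cbind(as.matrix(exposures[pols]),
                age = as.numeric(co$age_category))
  scaler <- scale_features(cont)
  gender <- encode_nominal(co$gender, c("male", "female", "missing"), "gender")
  race <- encode_nominal(co$race, 0:3, "race")
  x <- cbind(scaler$scaled, gender, race)
  columns <- data.frame(
    column = colnames(x),
    source = c(pols, "age_category",
               rep("gender", ncol(gender)), rep("race", ncol(race))),
    type = c(rep("continuous", ncol(cont)),
             rep("indicator", ncol(gender) + ncol(race))),
    center = c(scaler$center, rep(NA, ncol(gender) + ncol(race))),
    scale = c(scaler$scale, rep(NA, ncol(gender) + ncol(race))),
    stringsAsFactors = FALSE
  )
  structure(list(
    x = x,
    y = if ("outcome" %in% names(co)) as.integer(co$outcome),
    id = exposures$id,
    scaler = scaler,
    columns = columns
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d patients x %d columns (%d continuous, %d indicators)%s\n",
              nrow(x$x), ncol(x$x),
              sum(x$columns$type == "continuous"),
              sum(x$columns$type == "indicator"),
              if (is.null(x$y)) "" else sprintf("; outcome prevalence %.3f",
                                                mean(x$y))))
  invisible(x)
}
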