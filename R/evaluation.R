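#' Binary confusion metrics
#'
#' Standard contingency metrics with class 1 (asthma) as positive:
#' accuracy = (TP+TN)/total, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A metric whose denominator is zero is reported
#' as `NA` (undefined), never as 0.
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return list with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    stop("labels must be binary 0/1")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y_true),
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp))
}

#' Per-node map quality at a distance threshold
#'
#' Map quality is judged by the mean Euclidean distance of the objects
#' mapped to each node from that node's codebook vector: the smaller the
#' distances, the better the codebooks represent the data. Reports how many
#' occupied nodes have mean object distance at or below the threshold
#' (default 0.05, the conventional cut on normalized data); empty nodes are
#' excluded from the count and flagged.
#'
#' @param model a fitted [som()].
#' @param x patterns in rows.
#' @param threshold distance threshold, on the scale of the (scaled)
#'   features.
#' @return list with `n_within`, `n_nodes`, `n_empty`, `threshold`, and
#'   `node_distance` (per-node mean distance, NA for empty nodes).
#' @export
node_quality_summary <- function(model, x, threshold = 0.05) {
  x <- as.matrix(x)
  bmu <- find_bmu(model, x)
  d <- sqrt(rowSums((x - model$codes[bmu, , drop = FALSE])^2))
  node_distance <- rep(NA_real_, model$grid$n_nodes)
  agg <- tapply(d, bmu, mean)
  node_distance[as.integer(names(agg))] <- as.numeric(agg)
  list(n_within = sum(node_distance <= threshold, na.rm = TRUE),
       n_nodes = model$grid$n_nodes,
       n_empty = sum(is.na(node_distance)),
       threshold = threshold,
       node_distance = node_distance)
}

#' End-to-end parameter-recovery experiment
#'
#' Runs the whole pipeline on a synthetic study — simulate, impute the
#' measurement series, interpolate lagged exposures, assemble the feature
#' table, train a supervised SOM on a seeded 70/30 split, predict on the
#' held-out patients — and reports map-quality and classification metrics.
#' When the generating SO2 coefficient is positive, the report also checks
#' that the mean SO2 codebook component over majority-asthma nodes exceeds
#' that over majority-non-asthma nodes, i.e. that the map recovered the
#' direction of the generating effect.
#'
#' @param sim a [sim_config()].
#' @param grid a [som_grid()].
#' @param som_cfg a [som_config()]; its seed also fixes the train/test
#'   split.
#' @param train_frac fraction of patients in the training split.
#' @param threshold node-quality distance threshold.
#' @return list of class `map_report`: quantization error (mean and sum),
#'   topographic error, node-quality summary, in-sample and held-out
#'   confusion metrics, prevalence, SO2 direction check, and the fitted
#'   model.
#' @export
recovery_experiment <- function(sim = sim_config(), grid = som_grid(8, 8),
                                som_cfg = som_config(), train_frac = 0.7,
                                threshold = 0.05) {
  study <- simulate_study(sim)
  meas <- if (any(is.na(study$measurements$value)))
    impute_measurements(study$measurements, seed = sim$seed + 10L)
  else study$measurements
  expo <- build_exposure_profiles(study$cohort, study$stations, meas,
                                  lag = sim$lag, power = 2,
                                  pollutants = sim$pollutants)
  ft <- build_feature_table(study$cohort, expo$profiles)

  n <- nrow(ft$x)
  set.seed(som_cfg$seed + 100L)
  train <- sort(sample.int(n, floor(train_frac * n)))
  test <- setdiff(seq_len(n), train)
  # both classes must appear in the training split
  if (length(unique(ft$y[train])) < 2L)
    stop("degenerate split: one class absent from training data")
  model <- som(ft$x[train, , drop = FALSE], y = ft$y[train],
               grid = grid, config = som_cfg)

  qe <- quantization_error(model, ft$x[train, , drop = FALSE])
  te <- topographic_error(model, ft$x[train, , drop = FALSE])
  quality <- node_quality_summary(model, ft$x[train, , drop = FALSE],
                                  threshold = threshold)
  pred_in <- predict(model, ft$x[train, , drop = FALSE])
  pred_out <- predict(model, ft$x[test, , drop = FALSE])

  so2_check <- NA
  if ("SO2" %in% colnames(model$codes) && !is.na(sim$beta["SO2"]) &&
      sim$beta[["SO2"]] > 0) {
    maj1 <- model$y_codes[, "class1"] > model$y_codes[, "class0"]
    if (any(maj1) && any(!maj1))
      so2_check <- mean(model$codes[maj1, "SO2"]) >
        mean(model$codes[!maj1, "SO2"])
  }

  structure(list(
    qe_mean = qe$mean, qe_sum = qe$sum,
    topographic_error = te,
    node_quality = quality,
    in_sample = confusion_metrics(ft$y[train], pred_in),
    held_out = confusion_metrics(ft$y[test], pred_out),
    prevalence = mean(ft$y),
    n_train = length(train), n_test = length(test),
    n_excluded = length(unique(expo$exclusions$id)),
    so2_direction_recovered = so2_check,
    model = model
  ), class = "map_report")
}

#' @export
print.map_report <- function(x, ...) {
  cat("SOM map report\n")
  cat(sprintf("  patients: %d train / %d test (%d excluded); prevalence %.3f\n",
              x$n_train, x$n_test, x$n_excluded, x$prevalence))
  cat(sprintf("  quantization error: mean %.4g (sum %.4g); topographic error %.4f\n",
              x$qe_mean, x$qe_sum, x$topographic_error))
  q <- x$node_quality
  cat(sprintf("  node quality: %d/%d nodes with mean distance <= %g (%d empty)\n",
              q$n_within, q$n_nodes, q$threshold, q$n_empty))
  fmt <- function(m) sprintf("accuracy %.3f, sensitivity %s, specificity %s",
                             m$accuracy,
                             ifelse(is.na(m$sensitivity), "NA",
                                    sprintf("%.3f", m$sensitivity)),
                             ifelse(is.na(m$specificity), "NA",
                                    sprintf("%.3f", m$specificity)))
  cat("  in-sample:  ", fmt(x$in_sample), "\n", sep = "")
  cat("  held-out:   ", fmt(x$held_out), "\n", sep = "")
  if (!is.na(x$so2_direction_recovered))
    cat(sprintf("  SO2 effect direction recovered on the map: %s\n",
                x$so2_direction_recovered))
  invisible(x)
}
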