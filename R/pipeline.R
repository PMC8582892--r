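#' Serialize a fitted SOM to JSON
#'
#' The document records grid geometry, the X (and Y) codebook vectors in
#' row-major linear node order (node 1 = bottom-left, reading left to right
#' and bottom to top), the resolved training configuration, and the
#' training history, so a fit can be archived or reloaded without R
#' serialization.
#'
#' @param model a fitted [som()].
#' @param path file to write; when NULL the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
som_to_json <- function(model, path = NULL) {
  doc <- list(
    grid = list(nrow = model$grid$nrow, ncol = model$grid$ncol,
                topology = model$grid$topology),
    features = model$feature_names,
    codes = unname(apply(model$codes, 1L, function(r) as.numeric(r),
                         simplify = FALSE)),
    y_codes = if (!is.null(model$y_codes))
      unname(apply(model$y_codes, 1L, function(r) as.numeric(r),
                   simplify = FALSE)),
    config = unclass(model$config),
    history = model$history,
    n_epochs_run = model$n_epochs_run,
    data_range = list(min = as.numeric(model$data_range[1L, ]),
                      max = as.numeric(model$data_range[2L, ]))
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname som_to_json
#' @export
som_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  grid <- som_grid(doc$grid$nrow, doc$grid$ncol, doc$grid$topology)
  codes <- matrix(as.numeric(doc$codes), nrow = grid$n_nodes)
  colnames(codes) <- doc$features
  cfgv <- doc$config
  # +/-Inf round-trip through JSON as strings
  for (f in c("eta0", "tau2", "sigma0", "tau1", "stop_tol", "x_weight"))
    cfgv[[f]] <- as.numeric(cfgv[[f]])
  cfg <- do.call(som_config, cfgv[c("eta0", "tau2", "sigma0", "tau1",
                                    "n_epochs", "stop_tol", "x_weight",
                                    "seed")])
  out <- list(
    codes = codes,
    y_codes = if (!is.null(doc$y_codes)) {
      yc <- matrix(as.numeric(doc$y_codes), nrow = grid$n_nodes)
      colnames(yc) <- c("class0", "class1")
      yc
    },
    grid = grid,
    config = cfg,
    history = doc$history,
    n_epochs_run = doc$n_epochs_run,
    n_presentations = NA_real_,
    data_range = rbind(doc$data_range$min, doc$data_range$max),
    feature_names = doc$features,
    n_patterns = NA_integer_
  )
  class(out) <- if (is.null(out$y_codes)) "som" else c("som_supervised", "som")
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (or load the three input CSVs),
#' impute the measurement series, interpolate lagged exposures to patient
#' coordinates, assemble the feature table, train a supervised SOM on a
#' seeded split, Ward-cluster the codebooks, and evaluate — writing every
#' artifact plus a manifest (stage list, input-file MD5 hashes, seed,
#' package version) to `out_dir`. Re-running with the same configuration
#' reproduces byte-identical artifacts.
#'
#' Artifacts: `stations.csv`, `measurements.csv`, `cohort.csv`,
#' `exposures.csv`, `exclusions.csv`, `clusters.csv`, `umatrix.csv`,
#' `codeplot.csv`, `model.json`, `report.json`, `manifest.json`.
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] (used when `input_dir` is NULL).
#' @param input_dir directory holding `stations.csv`, `measurements.csv`,
#'   `cohort.csv` to analyze instead of simulating; exactly one of the two
#'   input modes is used.
#' @param grid,som_cfg map geometry and training configuration.
#' @param lag,power exposure assembly parameters.
#' @param n_clusters Ward cluster count for the boundary map.
#' @param threshold node-quality distance threshold.
#' @param train_frac training-split fraction.
#' @return the evaluation report (invisibly); artifacts on disk.
#' @export
run_pipeline <- function(out_dir, sim = sim_config(), input_dir = NULL,
                         grid = som_grid(8, 8), som_cfg = som_config(),
                         lag = 2L, power = 2, n_clusters = 4L,
                         threshold = 0.05, train_frac = 0.7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(input_dir)) {
    study <- simulate_study(sim)
    write_study_csvs(study, out_dir)
    stations <- study$stations
    measurements <- study$measurements
    cohort <- study$cohort
    seed <- sim$seed
  } else {
    inp <- read_study_csvs(input_dir)
    stations <- inp$stations
    measurements <- inp$measurements
    cohort <- inp$cohort
    seed <- som_cfg$seed
  }

  meas <- if (any(is.na(measurements$value)))
    impute_measurements(measurements, seed = seed + 10L)
  else measurements
  expo <- build_exposure_profiles(cohort, stations, meas, lag = lag,
                                  power = power)
  write.csv(expo$profiles, file.path(out_dir, "exposures.csv"),
            row.names = FALSE)
  write.csv(expo$exclusions, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)

  ft <- build_feature_table(cohort, expo$profiles)
  n <- nrow(ft$x)
  set.seed(som_cfg$seed + 100L)
  train <- sort(sample.int(n, floor(train_frac * n)))
  test <- setdiff(seq_len(n), train)
  model <- som(ft$x[train, , drop = FALSE], y = ft$y[train],
               grid = grid, config = som_cfg)
  som_to_json(model, file.path(out_dir, "model.json"))

  clusters <- som_ward(model, n_clusters)
  write.csv(data.frame(node = seq_along(clusters), cluster = as.integer(clusters)),
            file.path(out_dir, "clusters.csv"), row.names = FALSE)
  um <- u_matrix(model)
  write.csv(data.frame(node = seq_along(um), u = um),
            file.path(out_dir, "umatrix.csv"), row.names = FALSE)
  write.csv(code_plot_data(model), file.path(out_dir, "codeplot.csv"),
            row.names = FALSE)

  qe <- quantization_error(model, ft$x[train, , drop = FALSE])
  quality <- node_quality_summary(model, ft$x[train, , drop = FALSE],
                                  threshold = threshold)
  report <- list(
    n_patients = n, n_train = length(train), n_test = length(test),
    n_excluded = length(unique(expo$exclusions$id)),
    prevalence = mean(ft$y),
    qe_mean = qe$mean, qe_sum = qe$sum,
    topographic_error = topographic_error(model, ft$x[train, , drop = FALSE]),
    node_quality = quality[c("n_within", "n_nodes", "n_empty", "threshold")],
    in_sample = confusion_metrics(ft$y[train],
                                  predict(model, ft$x[train, , drop = FALSE])),
    held_out = confusion_metrics(ft$y[test],
                                 predict(model, ft$x[test, , drop = FALSE]))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")

  artifacts <- c("stations.csv", "measurements.csv", "cohort.csv",
                 "exposures.csv", "exclusions.csv", "clusters.csv",
                 "umatrix.csv", "codeplot.csv", "model.json", "report.json")
  artifacts <- artifacts[file.exists(file.path(out_dir, artifacts))]
  manifest <- list(
    stages = c(if (is.null(input_dir)) "simulate",
               "impute", "expose", "preprocess", "train", "cluster",
               "evaluate"),
    seed = seed,
    package_version = as.character(utils::packageVersion("somexposure")),
    artifact_md5 = as.list(tools::md5sum(file.path(out_dir, artifacts)))
  )
  names(manifest$artifact_md5) <- artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
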