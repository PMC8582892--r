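#' @export
print.som <- function(x, ...) {
  kind <- if (inherits(x, "som_supervised")) "Supervised" else "Unsupervised"
  cat(sprintf("%s self-organizing map\n", kind))
  cat(sprintf("  grid: %d x %d (%s), %d nodes; %d features\n",
              x$grid$nrow, x$grid$ncol, x$grid$topology, x$grid$n_nodes,
              ncol(x$codes)))
  cat(sprintf("  trained: %d epochs (%g presentations), seed %d\n",
              x$n_epochs_run, x$n_presentations, x$config$seed))
  cat(sprintf("  final quantization error (mean squared): %.6g\n",
              x$history[length(x$history)]))
  invisible(x)
}

#' Summarize a fitted self-organizing map
#'
#' @param object a fitted [som()].
#' @param x patterns to evaluate on; defaults to none, in which case only
#'   training history is summarized.
#' @param threshold per-node mean-distance quality threshold (see
#'   [node_quality_summary()]).
#' @param ... unused.
#' @return an object of class `summary.som`.
#' @export
summary.som <- function(object, x = NULL, threshold = 0.05, ...) {
  out <- list(
    grid = object$grid,
    supervised = inherits(object, "som_supervised"),
    n_epochs_run = object$n_epochs_run,
    history = object$history,
    config = object$config
  )
  if (!is.null(x)) {
    out$qe <- quantization_error(object, x)
    out$te <- topographic_error(object, x)
    out$quality <- node_quality_summary(object, x, threshold = threshold)
  }
  class(out) <- "summary.som"
  out
}

#' @export
print.summary.som <- function(x, ...) {
  cat(sprintf("%s SOM, %d x %d %s grid\n",
              if (x$supervised) "Supervised" else "Unsupervised",
              x$grid$nrow, x$grid$ncol, x$grid$topology))
  cat(sprintf("Epochs run: %d; final training QE (mean squared): %.6g\n",
              x$n_epochs_run, x$history[length(x$history)]))
  if (!is.null(x$qe)) {
    cat(sprintf("Quantization error: mean %.6g (sum %.6g over %d patterns)\n",
                x$qe$mean, x$qe$sum, x$qe$n))
    cat(sprintf("Topographic error: %.4f\n", x$te))
    cat(sprintf("Node quality: %d of %d nodes with mean object distance <= %g (%d empty)\n",
                x$quality$n_within, x$quality$n_nodes, x$quality$threshold,
                x$quality$n_empty))
  }
  invisible(x)
}

#' @export
coef.som <- function(object, ...) object$codes

#' Residuals of a self-organizing map
#'
#' The quantization residual of each pattern: pattern minus the codebook
#' vector of its best-matching unit.
#'
#' @param object a fitted [som()].
#' @param x patterns in rows.
#' @param ... unused.
#' @return matrix of residuals, same shape as `x`.
#' @export
residuals.som <- function(object, x, ...) {
  x <- as.matrix(x)
  bmu <- find_bmu(object, x)
  r <- x - object$codes[bmu, , drop = FALSE]
  rownames(r) <- rownames(x)
  r
}

#' Predict binary outcomes from a supervised SOM
#'
#' The best-matching unit is found on the feature (X) layer only — outcome
#' labels are unknown at prediction time — and the predicted class is the
#' larger component of that node's class-proportion (Y) codebook. Exact ties
#' go to class 0.
#'
#' @param object a supervised [som()] fit.
#' @param newdata patterns in rows, same features as training.
#' @param type `"class"` for 0/1 labels, `"prob"` for the winning node's
#'   class-1 proportion.
#' @param ... unused.
#' @return integer 0/1 vector, or numeric probabilities.
#' @export
predict.som <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$y_codes))
    stop("model has no outcome (Y) layer; fit with y for supervised prediction")
  bmu <- find_bmu(object, newdata)
  p1 <- object$y_codes[bmu, "class1"]
  if (type == "prob") return(unname(p1))
  unname(as.integer(p1 > object$y_codes[bmu, "class0"]))
}

#' Plot a fitted self-organizing map
#'
#' `type = "codes"` draws a code plot: one star/fan per node whose segment
#' lengths are the per-feature fan weights of [code_plot_data()] (codebook
#' components rescaled to `[0, 1]` across the map, per feature), nodes laid
#' out in grid positions with node 1 at the bottom left. `type = "umatrix"`
#' shades nodes by their mean distance to grid-neighbor codebooks;
#' `type = "clusters"` shades nodes by Ward cluster membership;
#' `type = "history"` shows the training quantization-error curve.
#'
#' @param x a fitted [som()].
#' @param type what to draw.
#' @param n_clusters number of Ward clusters for `type = "clusters"`.
#' @param ... passed to the underlying base-graphics calls.
#' @return invisibly, the data behind the plot.
#' @export
plot.som <- function(x, type = c("codes", "umatrix", "clusters", "history"),
                     n_clusters = 2, ...) {
  type <- match.arg(type)
  g <- x$grid
  if (type == "history") {
    graphics::plot(seq_along(x$history), x$history, type = "b",
                   xlab = "epoch", ylab = "mean squared quantization error",
                   main = "Training history", ...)
    return(invisible(x$history))
  }
  if (type == "codes") {
    cp <- code_plot_data(x)
    wt <- matrix(cp$weight, nrow = g$n_nodes,
                 dimnames = list(NULL, unique(cp$feature)))
    graphics::stars(wt, locations = g$coords, len = 0.45,
                    draw.segments = TRUE, labels = NULL,
                    col.segments = grDevices::rainbow(ncol(wt)),
                    main = "Codebook fan plot", ...)
    graphics::text(g$coords[, 1], g$coords[, 2] - 0.48,
                   labels = seq_len(g$n_nodes), cex = 0.6)
    return(invisible(wt))
  }
  val <- if (type == "umatrix") u_matrix(x) else som_ward(x, n_clusters)
  z <- matrix(val, nrow = g$ncol)  # columns vary fastest within a row
  graphics::image(seq_len(g$ncol), seq_len(g$nrow), z,
                  xlab = "column", ylab = "row (1 = bottom)",
                  col = if (type == "umatrix") grDevices::gray.colors(32)
                        else grDevices::rainbow(n_clusters),
                  main = if (type == "umatrix") "U-matrix" else "Ward clusters",
                  ...)
  invisible(val)
}
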