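#' Training configuration for a self-organizing map
#'
#' The map is trained online: patterns are presented one at a time in a
#' seeded shuffled order, and at presentation `t` (counted from 0 over the
#' whole run) every node is pulled toward the pattern by the neighborhood
#' value `h = eta(t) * exp(-d_grid^2 / (2 sigma(t)^2))`, where `d_grid` is the
#' grid distance to the winning node. Both the learning rate
#' `eta(t) = eta0 * exp(-t / tau2)` and the neighborhood radius
#' `sigma(t) = sigma0 * exp(-t / tau1)` decay exponentially.
#'
#' @param eta0 initial learning rate, in (0, 1].
#' @param tau2 learning-rate decay constant in presentations; default
#'   `n_epochs * n_patterns / 4`, resolved at fit time when `NULL`.
#' @param sigma0 initial neighborhood radius in grid units; default
#'   `max(nrow, ncol) / 2`, resolved at fit time when `NULL`. `sigma0 = 0`
#'   collapses the neighborhood to the winning node alone.
#' @param tau1 radius decay constant in presentations; default
#'   `total presentations / log(sigma0)` (total presentations when
#'   `sigma0 <= 1`), resolved at fit time when `NULL`.
#' @param n_epochs maximum number of passes over the data.
#' @param stop_tol training stops early when the relative improvement of the
#'   quantization error over one epoch falls below this value.
#' @param x_weight weight of the feature (X) layer in the supervised
#'   winning-node distance, in (0, 1]; the outcome (Y) layer gets
#'   `1 - x_weight`. With `x_weight = 1` supervised training reduces to
#'   unsupervised training of the X layer.
#' @param seed integer seed fixing initialization and presentation order.
#' @return A list of class `som_config`.
#' @seealso [som()]
#' @export
som_config <- function(eta0 = 0.05, tau2 = NULL, sigma0 = NULL, tau1 = NULL,
                       n_epochs = 100L, stop_tol = 1e-5, x_weight = 0.5,
                       seed = 1L) {
  if (eta0 <= 0 || eta0 > 1) stop("eta0 must be in (0, 1]")
  if (!is.null(tau2) && tau2 <= 0) stop("tau2 must be > 0")
  if (!is.null(tau1) && tau1 <= 0) stop("tau1 must be > 0")
  if (!is.null(sigma0) && sigma0 < 0) stop("sigma0 must be >= 0")
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  if (x_weight <= 0 || x_weight > 1) stop("x_weight must be in (0, 1]")
  structure(list(eta0 = eta0, tau2 = tau2, sigma0 = sigma0, tau1 = tau1,
                 n_epochs = as.integer(n_epochs), stop_tol = stop_tol,
                 x_weight = x_weight, seed = as.integer(seed)),
            class = "som_config")
}

#' Exponentially decaying learning rate
#'
#' `eta(t) = eta0 * exp(-t / tau2)`, strictly decreasing in the presentation
#' counter `t`.
#'
#' @param t presentation counter, >= 0 (vectorized).
#' @param eta0 initial learning rate.
#' @param tau2 decay constant, > 0.
#' @return learning rate(s).
#' @examples
#' learning_rate(0, 0.1, 100)          # 0.1
#' learning_rate(100, 0.1, 100)        # 0.1 / e
#' @export
learning_rate <- function(t, eta0, tau2) {
  stopifnot(all(t >= 0), tau2 > 0)
  eta0 * exp(-t / tau2)
}

#' Gaussian neighborhood value
#'
#' The amount by which a node learns from the pattern won by `bmu` at
#' presentation `t`: `h = eta_t * exp(-d^2 / (2 sigma(t)^2))` with
#' `sigma(t) = sigma0 * exp(-t / tau1)` and `d` the grid distance between the
#' two nodes. At the winning node itself `h = eta_t`. When `sigma(t)`
#' underflows (or `sigma0 = 0`) the neighborhood collapses to the winning
#' node alone; this is documented behavior, not an error.
#'
#' @param bmu,node linear node indices.
#' @param t presentation counter, >= 0.
#' @param sigma0 initial radius in grid units, >= 0.
#' @param tau1 radius decay constant, > 0.
#' @param grid a [som_grid()].
#' @param eta_t learning rate at `t` (multiplied in; pass 1 for the bare
#'   kernel value).
#' @return neighborhood value in `[0, eta_t]`.
#' @export
neighborhood_value <- function(bmu, node, t, sigma0, tau1, grid, eta_t = 1) {
  stopifnot(t >= 0, sigma0 >= 0, tau1 > 0)
  d2 <- sum((grid$coords[bmu, ] - grid$coords[node, ])^2)
  if (d2 == 0) return(eta_t)
  sigma_t <- sigma0 * exp(-t / tau1)
  if (sigma_t == 0) return(0)
  eta_t * exp(-d2 / (2 * sigma_t^2))
}

#' Randomly initialize codebook vectors
#'
#' Each component of each codebook vector is drawn uniformly within the
#' observed range of the corresponding feature. A feature with a degenerate
#' range is initialized to that constant exactly.
#'
#' @param grid a [som_grid()].
#' @param data_range a `2 x p` matrix (rows: min, max) or a numeric matrix of
#'   data from which ranges are taken column-wise.
#' @param seed integer seed.
#' @return an `n_nodes x p` matrix of codebook vectors, rows in linear node
#'   order.
#' @export
initialize_codebooks <- function(grid, data_range, seed = 1L) {
  if (is.matrix(data_range) && nrow(data_range) > 2L)
    data_range <- apply(data_range, 2L, range)
  data_range <- as.matrix(data_range)
  if (nrow(data_range) != 2L) stop("data_range must have rows (min, max)")
  p <- ncol(data_range)
  if (p <= 0) stop("input dimension must be positive")
  if (any(!is.finite(data_range))) stop("data ranges must be finite")
  set.seed(seed)
  w <- matrix(runif(grid$n_nodes * p), grid$n_nodes, p)
  lo <- data_range[1L, ]; hi <- data_range[2L, ]
  w <- sweep(sweep(w, 2L, hi - lo, `*`), 2L, lo, `+`)
  colnames(w) <- colnames(data_range)
  w
}

# bare vectors: one pattern of dimension p, or a column of 1-d patterns
as_patterns <- function(z, p) {
  if (is.null(dim(z))) {
    if (p == 1L) matrix(z, ncol = 1L) else matrix(z, nrow = 1L)
  } else as.matrix(z)
}

#' Best-matching unit
#'
#' The node whose codebook vector is nearest to the pattern in Euclidean
#' distance, ties broken by the lowest linear node index. For a fitted
#' supervised map the match uses the feature (X) layer only.
#'
#' @param object a fitted [som()] model or a codebook matrix.
#' @param z a pattern vector, or a matrix of patterns in rows.
#' @return integer vector of winning linear node indices, one per pattern.
#' @export
find_bmu <- function(object, z) {
  w <- if (inherits(object, "som")) object$codes else as.matrix(object)
  z <- as_patterns(z, ncol(w))
  if (ncol(z) != ncol(w)) stop("pattern dimension does not match codebooks")
  # squared distances pattern x node; which.min takes the lowest index on ties
  d2 <- outer(rowSums(z^2), rep(1, nrow(w))) - 2 * z %*% t(w) +
    outer(rep(1, nrow(z)), rowSums(w^2))
  apply(d2, 1L, which.min)
}

#' One online codebook update
#'
#' Moves every codebook vector toward the pattern by its neighborhood value:
#' `w' = w + h (z - w)`. With `h = 1` the node lands exactly on the pattern;
#' with `h = 0` it is unchanged. Exposed mainly for inspection; [som()] runs
#' the full training loop in compiled code.
#'
#' @param codes codebook matrix (nodes in rows).
#' @param z pattern vector.
#' @param h numeric vector of neighborhood values, one per node (or a
#'   scalar, recycled).
#' @return the updated codebook matrix.
#' @export
update_codebooks <- function(codes, z, h) {
  codes <- as.matrix(codes)
  h <- rep_len(h, nrow(codes))
  codes + h * (matrix(z, nrow(codes), ncol(codes), byrow = TRUE) - codes)
}

#' Fit a self-organizing map
#'
#' Trains a Kohonen map on scaled feature patterns by online competitive
#' learning. When a binary outcome `y` is supplied the map is supervised: a
#' second (Y) codebook layer holds per-node class proportions, the winning
#' node during training minimizes
#' `x_weight * d_X^2 + (1 - x_weight) * d_Y^2` with the outcome one-hot
#' coded, and both layers are updated together. Prediction ([predict.som()])
#' uses the X layer only, so labels are never needed at prediction time.
#'
#' Training runs for at most `config$n_epochs` passes, stopping early when
#' the relative improvement of the (mean squared) quantization error over an
#' epoch drops below `config$stop_tol`. All randomness — codebook
#' initialization and presentation order — is fixed by `config$seed`.
#'
#' @param x numeric matrix or data frame of patterns (rows) by features
#'   (columns); features should be on comparable scales (see
#'   [scale_features()]).
#' @param y optional binary outcome vector (0/1) for supervised training;
#'   both classes must be present.
#' @param grid a [som_grid()].
#' @param config a [som_config()].
#' @return An object of class `som` (and `som_supervised` when `y` is
#'   given): list with `codes` (X codebooks, nodes in rows), `y_codes`
#'   (class-proportion codebooks, or NULL), `grid`, `config` (with resolved
#'   defaults), `history` (per-epoch mean squared quantization error),
#'   `n_epochs_run`, `n_presentations`, `data_range`, and `feature_names`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' m <- som(x, grid = som_grid(3, 3), config = som_config(n_epochs = 20, seed = 1))
#' m
#' quantization_error(m, x)$mean
#' @export
som <- function(x, y = NULL, grid = som_grid(8, 8), config = som_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("patterns must be finite; impute first")
  n <- nrow(x); p <- ncol(x)
  if (n < 1L) stop("no patterns")
  supervised <- !is.null(y)
  if (supervised) {
    y <- as.integer(y)
    if (length(y) != n) stop("y length must match nrow(x)")
    if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
    if (length(unique(y)) < 2L)
      stop("degenerate labels: both classes must be present for supervised training")
  }

  cfg <- config
  if (is.null(cfg$tau2)) cfg$tau2 <- cfg$n_epochs * n / 4
  if (is.null(cfg$sigma0)) cfg$sigma0 <- max(grid$nrow, grid$ncol) / 2
  if (is.null(cfg$tau1)) {
    total <- as.numeric(cfg$n_epochs) * n
    cfg$tau1 <- if (cfg$sigma0 > 1) total / log(cfg$sigma0) else total
  }

  # RNG consumption order: X init, presentation orders, then Y init, so that
  # x_weight = 1 supervised X codebooks match an unsupervised run exactly.
  set.seed(cfg$seed)
  rng <- apply(x, 2L, range)
  wx <- matrix(runif(grid$n_nodes * p), grid$n_nodes, p)
  wx <- sweep(sweep(wx, 2L, rng[2L, ] - rng[1L, ], `*`), 2L, rng[1L, ], `+`)
  orders <- vapply(seq_len(cfg$n_epochs), function(e) sample.int(n),
                   integer(n))
  if (supervised) {
    wy <- matrix(runif(grid$n_nodes * 2L), grid$n_nodes, 2L)
    wy <- wy / rowSums(wy)   # rows on the probability simplex
    ymat <- cbind(1 - y, y)  # one-hot: column 1 = class 0, column 2 = class 1
  } else {
    wy <- matrix(0, 0L, 0L)
    ymat <- matrix(0, 0L, 0L)
  }

  fit <- som_train_cpp(x, ymat, wx, wy, grid_dist2(grid), orders,
                       cfg$eta0, cfg$tau2, cfg$sigma0, cfg$tau1,
                       cfg$x_weight, cfg$n_epochs, cfg$stop_tol,
                       supervised)

  codes <- fit$wx
  colnames(codes) <- colnames(x)
  out <- list(
    codes = codes,
    y_codes = if (supervised) {
      yc <- fit$wy; colnames(yc) <- c("class0", "class1"); yc
    },
    grid = grid,
    config = cfg,
    history = as.numeric(fit$history),
    n_epochs_run = fit$epochs_run,
    n_presentations = fit$presentations,
    data_range = rng,
    feature_names = colnames(x),
    n_patterns = n
  )
  class(out) <- if (supervised) c("som_supervised", "som") else "som"
  out
}

#' Quantization error of a map
#'
#' Aggregate squared Euclidean distance between patterns and their winning
#' nodes' codebook vectors. The headline value is the mean over patterns (a
#' per-object quantity comparable across sample sizes); the raw sum over
#' patterns is also reported.
#'
#' @param model a fitted [som()] (or a codebook matrix).
#' @param x patterns in rows.
#' @return list with `mean`, `sum`, and `n`.
#' @export
quantization_error <- function(model, x) {
  w <- if (inherits(model, "som")) model$codes else as.matrix(model)
  x <- as_patterns(x, ncol(w))
  if (nrow(x) < 1L) stop("quantization error needs at least one pattern")
  bmu <- find_bmu(w, x)
  d2 <- rowSums((x - w[bmu, , drop = FALSE])^2)
  list(mean = mean(d2), sum = sum(d2), n = nrow(x))
}

#' Topographic error of a map
#'
#' The fraction of patterns whose best- and second-best-matching nodes are
#' not adjacent on the grid (unit grid distance: 4-neighborhood on a
#' rectangular lattice, 6-neighborhood on a hexagonal one). Low values mean
#' the map preserves the topology of the input space.
#'
#' @inheritParams quantization_error
#' @return fraction in `[0, 1]`.
#' @export
topographic_error <- function(model, x) {
  w <- if (inherits(model, "som")) model$codes else as.matrix(model)
  grid <- if (inherits(model, "som")) model$grid else
    stop("topographic_error needs a fitted som (grid geometry required)")
  if (grid$n_nodes < 2L) stop("topographic error undefined on a single-node map")
  x <- as_patterns(x, ncol(w))
  adj <- grid_adjacency(grid)
  d2 <- outer(rowSums(x^2), rep(1, nrow(w))) - 2 * x %*% t(w) +
    outer(rep(1, nrow(x)), rowSums(w^2))
  err <- vapply(seq_len(nrow(x)), function(i) {
    o <- order(d2[i, ])[1:2]
    !adj[o[1L], o[2L]]
  }, logical(1))
  mean(err)
}
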