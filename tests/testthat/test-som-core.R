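test_that("learning rate follows the exponential decay schedule", {
  expect_equal(learning_rate(0, 0.1, 100), 0.1)
  expect_equal(learning_rate(100, 0.1, 100), 0.1 * exp(-1))
  # exponential identity eta(2 tau) = eta(tau)^2 / eta(0)
  expect_equal(learning_rate(200, 0.1, 100),
               learning_rate(100, 0.1, 100)^2 / 0.1)
  # strictly decreasing
  t <- seq(0, 500, by = 50)
  expect_true(all(diff(learning_rate(t, 0.05, 123)) < 0))
})

test_that("Gaussian neighborhood value behaves at the BMU, at distance 1, and when collapsed", {
  g <- som_grid(3, 3)
  expect_equal(neighborhood_value(5, 5, t = 10, sigma0 = 2, tau1 = 50,
                                  grid = g, eta_t = 0.7), 0.7)
  # d_grid = 1, sigma(t) = 1, eta = 1 -> exp(-1/2)
  expect_equal(neighborhood_value(5, 6, t = 0, sigma0 = 1, tau1 = 1,
                                  grid = g, eta_t = 1), exp(-0.5))
  # sigma0 = 0 collapses the neighborhood to the BMU
  expect_equal(neighborhood_value(5, 6, t = 0, sigma0 = 0, tau1 = 1,
                                  grid = g), 0)
  expect_equal(neighborhood_value(5, 5, t = 0, sigma0 = 0, tau1 = 1,
                                  grid = g, eta_t = 0.3), 0.3)
})

test_that("codebook initialization covers the grid and respects feature ranges", {
  g4 <- som_grid(4, 4); g8 <- som_grid(8, 8)
  rng <- rbind(c(-1, 0, 5), c(1, 0, 10))
  expect_equal(nrow(initialize_codebooks(g4, rng, seed = 1)), 16)
  w <- initialize_codebooks(g8, rng, seed = 1)
  expect_equal(nrow(w), 64)
  expect_true(all(w[, 1] >= -1 & w[, 1] <= 1))
  expect_true(all(w[, 3] >= 5 & w[, 3] <= 10))
  # degenerate range initializes exactly at the constant
  expect_true(all(w[, 2] == 0))
  expect_error(initialize_codebooks(g4, matrix(numeric(0), 2, 0)), "positive")
})

test_that("find_bmu matches an exhaustive distance scan and breaks ties low", {
  w <- rbind(c(0, 0), c(1, 1))
  expect_equal(find_bmu(w, c(0.1, 0)), 1L)
  expect_equal(find_bmu(w, c(1, 1)), 2L)
  # exact tie -> lowest linear index
  expect_equal(find_bmu(rbind(c(0, 0), c(1, 0)), c(0.5, 0)), 1L)
  set.seed(42)
  w <- matrix(rnorm(25 * 3), 25, 3)
  z <- matrix(rnorm(100 * 3), 100, 3)
  brute <- apply(z, 1, function(p) which.min(colSums((t(w) - p)^2)))
  expect_equal(find_bmu(w, z), brute)
})

test_that("one online update moves codebooks the prescribed fraction toward the pattern", {
  expect_equal(update_codebooks(matrix(0, 1, 1), 1, h = 1)[1, 1], 1)
  w <- matrix(rnorm(6), 3, 2)
  expect_equal(update_codebooks(w, c(5, 5), h = 0), w)
  expect_equal(unname(update_codebooks(matrix(0, 1, 2), c(2, 4), h = 0.5)[1, ]),
               c(1, 2))
  # convexity: each component between old value and the pattern
  z <- c(2, 4)
  h <- runif(3)
  w2 <- update_codebooks(w, z, h)
  for (j in 1:2) {
    lo <- pmin(w[, j], z[j]); hi <- pmax(w[, j], z[j])
    expect_true(all(w2[, j] >= lo - 1e-12 & w2[, j] <= hi + 1e-12))
  }
})

test_that("quantization error equals the mean/sum of squared BMU distances", {
  # one node, codebook 1.0, patterns 0 and 2 -> mean squared distance 1
  qe <- quantization_error(matrix(1, 1, 1), c(0, 2))
  expect_equal(qe$mean, 1)
  expect_equal(qe$sum, 2)
  # patterns equal to codebooks -> zero
  w <- matrix(rnorm(8), 4, 2)
  expect_equal(quantization_error(w, w)$mean, 0)
  # independent recomputation on random data
  set.seed(7)
  w <- matrix(rnorm(9 * 2), 9, 2)
  z <- matrix(rnorm(50 * 2), 50, 2)
  brute <- mean(apply(z, 1, function(p) min(colSums((t(w) - p)^2))))
  expect_equal(quantization_error(w, z)$mean, brute, tolerance = 1e-12)
  expect_error(quantization_error(w, z[0, , drop = FALSE]), "at least one")
})

test_that("topographic error flags non-adjacent first and second matches", {
  g <- som_grid(2, 2)
  m <- list(codes = rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 10)),
            grid = g)
  class(m) <- "som"
  # pattern at node 1's codebook; runner-up (node 2) is adjacent
  expect_equal(topographic_error(m, c(0, 0)), 0)
  # pattern between node 1 (bottom-left) and node 4 (top-right, diagonal)
  m2 <- list(codes = rbind(c(0, 0), c(50, 0), c(0, 50), c(0.1, 0.1)),
             grid = g)
  class(m2) <- "som"
  expect_equal(topographic_error(m2, c(0.05, 0.05)), 1)
  set.seed(1)
  x <- matrix(rnorm(100), 50, 2)
  fit <- som(x, grid = som_grid(3, 3), config = som_config(n_epochs = 5, seed = 1))
  te <- topographic_error(fit, x)
  expect_true(te >= 0 && te <= 1)
  one <- list(codes = matrix(0, 1, 2), grid = som_grid(1, 1))
  class(one) <- "som"
  expect_error(topographic_error(one, c(0, 0)), "single-node")
})

test_that("training is deterministic under a fixed seed and QE improves over the run", {
  set.seed(3); x <- matrix(rnorm(200 * 3), 200, 3)
  cfg <- som_config(n_epochs = 30, stop_tol = -Inf, seed = 9)
  m1 <- som(x, grid = som_grid(4, 4), config = cfg)
  m2 <- som(x, grid = som_grid(4, 4), config = cfg)
  expect_identical(m1$codes, m2$codes)
  expect_identical(m1$history, m2$history)
  expect_equal(length(m1$history), m1$n_epochs_run)
  for (s in 1:5) {
    set.seed(s); xs <- matrix(rnorm(150 * 3), 150, 3)
    ms <- som(xs, grid = som_grid(4, 4),
              config = som_config(n_epochs = 30, stop_tol = -Inf, seed = s))
    expect_lte(ms$history[length(ms$history)], ms$history[1])
  }
})

test_that("a single-node map converges to the data mean", {
  set.seed(7); x <- matrix(runif(200), 200, 1)
  m <- som(x, grid = som_grid(1, 1),
           config = som_config(eta0 = 0.1, n_epochs = 300, tau2 = 300 * 200 / 12,
                               stop_tol = -Inf, seed = 1))
  expect_equal(m$codes[1, 1], mean(x), tolerance = 1e-3)
})

test_that("supervised training keeps Y rows on the simplex and reduces to unsupervised at x_weight 1", {
  dat <- make_cluster_data(300, d = 3, sep = 6, seed = 5)
  cfg <- som_config(n_epochs = 20, seed = 5)
  ms <- som(dat$x, dat$y, grid = som_grid(4, 4), config = cfg)
  expect_true(all(abs(rowSums(ms$y_codes) - 1) < 1e-8))
  cfg1 <- som_config(n_epochs = 20, x_weight = 1, stop_tol = -Inf, seed = 5)
  msup <- som(dat$x, dat$y, grid = som_grid(4, 4), config = cfg1)
  muns <- som(dat$x, grid = som_grid(4, 4),
              config = som_config(n_epochs = 20, x_weight = 1, stop_tol = -Inf,
                                  seed = 5))
  expect_identical(msup$codes, muns$codes)
  expect_error(som(dat$x, rep(1L, nrow(dat$x)), grid = som_grid(2, 2)),
               "degenerate labels")
})

test_that("on well-separated clusters every node's class codebook matches its X side", {
  dat <- make_cluster_data(600, d = 3, sep = 8, seed = 11)
  m <- som(dat$x, dat$y, grid = som_grid(4, 4),
           config = som_config(n_epochs = 50, stop_tol = -Inf, seed = 11))
  node_class <- as.integer(m$y_codes[, "class1"] > m$y_codes[, "class0"])
  x_side <- as.integer(m$codes[, 1] > 4)  # midpoint between cluster means
  # judged on occupied nodes; interpolating nodes between the clusters win
  # no patterns and their class codebook is arbitrary
  occupied <- tabulate(find_bmu(m, dat$x), m$grid$n_nodes) > 0
  expect_equal(node_class[occupied], x_side[occupied])
  # training patterns predict their own labels
  expect_equal(predict(m, dat$x), dat$y)
})

test_that("prediction uses the X layer, breaks ties to class 0, and is permutation-equivariant", {
  dat <- make_cluster_data(300, d = 4, sep = 6, seed = 2)
  m <- som(dat$x, dat$y, grid = som_grid(3, 3),
           config = som_config(n_epochs = 20, seed = 2))
  # tie rule
  mt <- m
  mt$y_codes[] <- 0.5
  expect_true(all(predict(mt, dat$x) == 0L))
  # consistent feature permutation leaves predictions unchanged
  perm <- c(3, 1, 4, 2)
  mp <- m
  mp$codes <- m$codes[, perm]
  expect_equal(predict(mp, dat$x[, perm]), predict(m, dat$x))
  # unsupervised model refuses to predict
  mu <- som(dat$x, grid = som_grid(3, 3), config = som_config(n_epochs = 5, seed = 2))
  expect_error(predict(mu, dat$x), "no outcome")
})

test_that("model JSON serialization round-trips codebooks, grid and predictions", {
  dat <- make_cluster_data(200, d = 3, sep = 6, seed = 4)
  m <- som(dat$x, dat$y, grid = som_grid(3, 4),
           config = som_config(n_epochs = 10, seed = 4))
  path <- tempfile(fileext = ".json")
  som_to_json(m, path)
  m2 <- som_from_json(path)
  expect_equal(m2$codes, m$codes, ignore_attr = TRUE)
  expect_equal(m2$y_codes, m$y_codes, ignore_attr = TRUE)
  expect_equal(m2$grid$n_nodes, 12)
  expect_equal(predict(m2, dat$x), predict(m, dat$x))
})
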