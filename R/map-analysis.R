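#' Ward merge distance between two clusters
#'
#' The merge cost between disjoint clusters r and s with sizes `n_r`, `n_s`
#' and centroids `w_r`, `w_s`:
#' `d_rs = n_r n_s / (n_r + n_s) * ||w_r - w_s||^2`
#' (the increase in total within-cluster sum of squares if they were merged).
#' The squared-norm reading is the standard Ward criterion; set
#' `squared = FALSE` for the unsquared centroid distance variant.
#'
#' @param r,s clusters: lists with `n` (size) and `centroid` (numeric
#'   vector), e.g. from [som_ward()]'s internals, or plain lists you build.
#' @param squared use the squared centroid norm (default) or the plain norm.
#' @return the merge distance.
#' @examples
#' a <- list(n = 1, centroid = c(0, 0), members = 1)
#' b <- list(n = 1, centroid = c(2, 0), members = 2)
#' ward_distance(a, b)   # (1*1/2) * 4 = 2
#' @export
ward_distance <- function(r, s, squared = TRUE) {
  if (is.null(r$n) || is.null(s$n) || r$n < 1 || s$n < 1)
    stop("clusters must be non-empty")
  if (!is.null(r$members) && !is.null(s$members) &&
      length(intersect(r$members, s$members)) > 0L)
    stop("clusters overlap")
  nd <- sqrt(sum((r$centroid - s$centroid)^2))
  d <- if (squared) nd * nd else nd
  (r$n * s$n / (r$n + s$n)) * d
}

#' Ward clustering of SOM codebook vectors
#'
#' A trained map has no cluster boundaries; agglomerative Ward clustering of
#' the codebook vectors draws them. Starting from singleton nodes, the pair
#' of clusters with the smallest [ward_distance()] is merged at each step
#' (ties broken toward the lowest pair of linear node indices); cluster
#' centroids and sizes are updated by the pooled mean. Merging stops when
#' `n_clusters` clusters remain.
#'
#' @param model a fitted [som()] (or a codebook matrix).
#' @param n_clusters number of clusters to keep, between 1 and the node
#'   count.
#' @param squared squared (default, standard Ward) or unsquared centroid
#'   distance in the merge criterion.
#' @return integer vector of cluster labels (1..n_clusters) per node, in
#'   linear node order; labels are numbered by each cluster's lowest member
#'   node. The merge-cost sequence is attached as attribute `"heights"`.
#' @export
som_ward <- function(model, n_clusters, squared = TRUE) {
  w <- if (inherits(model, "som")) model$codes else as.matrix(model)
  m <- nrow(w)
  if (n_clusters < 1 || n_clusters > m)
    stop("n_clusters must be between 1 and the number of nodes")
  # active clusters: sizes, centroids, member lists
  size <- rep(1, m)
  cent <- w
  members <- as.list(seq_len(m))
  active <- rep(TRUE, m)
  heights <- numeric(0)
  n_active <- m
  while (n_active > n_clusters) {
    idx <- which(active)
    best <- Inf; bi <- bj <- NA_integer_
    for (a in seq_along(idx)) {
      i <- idx[a]
      for (b in seq_along(idx)) {
        if (b <= a) next
        j <- idx[b]
        d <- sum((cent[i, ] - cent[j, ])^2)
        if (!squared) d <- sqrt(d)
        d <- size[i] * size[j] / (size[i] + size[j]) * d
        if (d < best) { best <- d; bi <- i; bj <- j }  # ties keep the lower pair
      }
    }
    cent[bi, ] <- (size[bi] * cent[bi, ] + size[bj] * cent[bj, ]) /
      (size[bi] + size[bj])
    size[bi] <- size[bi] + size[bj]
    members[[bi]] <- c(members[[bi]], members[[bj]])
    active[bj] <- FALSE
    heights <- c(heights, best)
    n_active <- n_active - 1L
  }
  labels <- integer(m)
  keep <- which(active)
  keep <- keep[order(vapply(members[keep], min, numeric(1)))]
  for (k in seq_along(keep)) labels[members[[keep[k]]]] <- k
  attr(labels, "heights") <- heights
  labels
}

#' Unified distance matrix (U-matrix)
#'
#' Per-node mean Euclidean distance between the node's codebook vector and
#' the codebooks of its grid neighbors (4-neighborhood on a rectangular
#' lattice, 6-neighborhood on a hexagonal one). Large values mark cluster
#' boundaries on the map.
#'
#' @param model a fitted [som()].
#' @return numeric vector of U-values in linear node order.
#' @export
u_matrix <- function(model) {
  stopifnot(inherits(model, "som"))
  w <- model$codes
  adj <- grid_adjacency(model$grid)
  d <- as.matrix(dist(w))
  vapply(seq_len(nrow(w)), function(i) mean(d[i, adj[i, ]]), numeric(1))
}

#' Code-plot fan weights
#'
#' For a code plot, each node displays one fan segment per feature; the
#' segment's size is the node's codebook component rescaled to `[0, 1]`
#' across the whole map, per feature. A feature that is constant across all
#' codebooks gets the midpoint weight 0.5 everywhere.
#'
#' @param model a fitted [som()].
#' @return data frame with columns `node`, `feature`, `weight`; `weight` in
#'   `[0, 1]`.
#' @export
code_plot_data <- function(model) {
  stopifnot(inherits(model, "som"))
  w <- model$codes
  p <- ncol(w)
  nm <- colnames(w)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  wt <- apply(w, 2L, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) rep(0.5, length(col))
    else (col - rng[1L]) / diff(rng)
  })
  data.frame(
    node = rep(seq_len(nrow(w)), times = p),
    feature = rep(nm, each = nrow(w)),
    weight = as.numeric(wt),
    stringsAsFactors = FALSE
  )
}
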