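#' Define a SOM grid
#'
#' A self-organizing map projects inputs onto a two-dimensional lattice of
#' nodes. The lattice has `nrow` rows and `ncol` columns and either a
#' rectangular or hexagonal layout; the layout determines the inter-node
#' distances used by the neighborhood function, the topographic error and the
#' U-matrix. Nodes are numbered reading from left to right and from the bottom
#' row to the top row, so node 1 is the bottom-left corner and node
#' `nrow * ncol` the top-right corner.
#'
#' @param nrow,ncol number of rows and columns; both >= 1.
#' @param topology `"rectangular"` or `"hexagonal"`. A hexagonal lattice
#'   offsets every second row by half a unit and spaces rows by sqrt(3)/2 so
#'   that each interior node has six neighbors at unit distance. `"linear"`
#'   is recognized but not implemented.
#' @return An object of class `som_grid`: list with `nrow`, `ncol`,
#'   `n_nodes`, `topology`, and `coords`, an `n_nodes x 2` matrix of node
#'   positions in grid units (columns `x`, `y`), in linear-index order.
#' @examples
#' g <- som_grid(4, 4)
#' g$n_nodes           # 16
#' head(g$coords)      # bottom row first
#' @export
som_grid <- function(nrow, ncol, topology = c("rectangular", "hexagonal", "linear")) {
  topology <- match.arg(topology)
  if (topology == "linear")
    stop("linear topology is recognized but not implemented")
  if (length(nrow) != 1L || length(ncol) != 1L || nrow < 1 || ncol < 1 ||
      nrow != round(nrow) || ncol != round(ncol))
    stop("nrow and ncol must be positive integers")
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  k <- rep(seq_len(nrow), each = ncol)   # row index, 1 = bottom
  j <- rep(seq_len(ncol), times = nrow)  # column index, 1 = left
  if (topology == "hexagonal") {
    x <- j + 0.5 * ((k - 1L) %% 2L)
    y <- (k - 1L) * sqrt(3) / 2 + 1
  } else {
    x <- as.numeric(j)
    y <- as.numeric(k)
  }
  structure(list(
    nrow = nrow, ncol = ncol, n_nodes = nrow * ncol,
    topology = topology,
    coords = cbind(x = x, y = y),
    row = k, col = j
  ), class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("SOM grid: %d x %d (%s), %d nodes\n",
              x$nrow, x$ncol, x$topology, x$n_nodes))
  invisible(x)
}

# squared Euclidean distances between node positions (n_nodes x n_nodes)
grid_dist2 <- function(grid) {
  d <- as.matrix(dist(grid$coords))
  d * d
}

# adjacency: nodes at unit grid distance (4-neighborhood on rectangular,
# 6-neighborhood on hexagonal)
grid_adjacency <- function(grid) {
  d <- as.matrix(dist(grid$coords))
  adj <- d <= 1 + 1e-9
  diag(adj) <- FALSE
  adj
}

#' Convert between linear node index and (row, column)
#'
#' Linear indices read the map left to right, bottom row to top row.
#'
#' @param grid a [som_grid()].
#' @param index integer vector of linear node indices.
#' @return `node_rc()`: a matrix with columns `row`, `col`;
#'   `node_index()`: integer vector of linear indices.
#' @export
node_rc <- function(grid, index) {
  stopifnot(all(index >= 1L), all(index <= grid$n_nodes))
  cbind(row = grid$row[index], col = grid$col[index])
}

#' @rdname node_rc
#' @param row,col node row (1 = bottom) and column (1 = left).
#' @export
node_index <- function(grid, row, col) {
  stopifnot(all(row >= 1L), all(row <= grid$nrow),
            all(col >= 1L), all(col <= grid$ncol))
  as.integer((row - 1L) * grid$ncol + col)
}
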