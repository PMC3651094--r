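#' Simple undirected binary graph
#'
#' The package's canonical network container: a simple (no self-loops, no
#' multi-edges), undirected, unweighted graph stored as per-node sorted
#' neighbor lists. This is the adjacency structure \eqn{A} that every
#' downstream metric (degree, clustering, shortest paths, modularity,
#' rewiring) consumes.
#'
#' @param edges two-column integer matrix (or data.frame) of 1-based node
#'   index pairs, one row per undirected edge. Orientation and order are
#'   irrelevant; duplicates and self-loops are rejected.
#' @param n_nodes total node count \eqn{N} (isolated nodes are allowed and
#'   must be covered by `n_nodes`).
#' @return an object of class `binary_graph` with fields `N` (node count),
#'   `M` (edge count), `neighbors` (list of sorted integer vectors) and
#'   `degrees` (integer vector, \eqn{k_i}).
#' @examples
#' g <- binary_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), n_nodes = 4)
#' g$degrees  # 2 2 2 0
#' @export
binary_graph <- function(edges, n_nodes) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("'edges' must be a two-column matrix of node index pairs")
  storage.mode(edges) <- "integer"
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L) stop("'n_nodes' must be a positive integer")
  if (nrow(edges) > 0L) {
    if (anyNA(edges)) stop("edge list contains missing values")
    if (min(edges) < 1L || max(edges) > n_nodes)
      stop("edge endpoint outside 1..n_nodes")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    key <- (a - 1) * as.double(n_nodes) + b
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed")
    edges <- cbind(a, b)
  }
  nbr <- vector("list", n_nodes)
  if (nrow(edges) > 0L) {
    ends <- c(edges[, 1L], edges[, 2L])
    other <- c(edges[, 2L], edges[, 1L])
    nbr_split <- split(other, factor(ends, levels = seq_len(n_nodes)))
    nbr <- unname(lapply(nbr_split, function(v) sort.int(as.integer(v))))
  } else {
    nbr <- replicate(n_nodes, integer(), simplify = FALSE)
  }
  g <- structure(
    list(N = n_nodes,
         M = nrow(edges),
         neighbors = nbr,
         degrees = vapply(nbr, length, integer(1L))),
    class = "binary_graph")
  g
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary_graph: %d nodes, %d edges (sparsity %.4g)\n",
              x$N, x$M, sparsity(x)))
  invisible(x)
}

#' Edge list of a binary graph
#'
#' @param g a `binary_graph`
#' @return integer matrix with columns `i`, `j` (`i < j`), one row per edge,
#'   in lexicographic order.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$M == 0L) return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(g$N), g$degrees)
  j <- unlist(g$neighbors, use.names = FALSE)
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Dense adjacency matrix of a binary graph
#'
#' Intended for small graphs (tests, oracles); memory is \eqn{O(N^2)}.
#' @param x a `binary_graph`
#' @param ... unused
#' @return N x N symmetric 0/1 matrix
#' @export
as.matrix.binary_graph <- function(x, ...) {
  A <- matrix(0, x$N, x$N)
  e <- graph_edges(x)
  if (nrow(e)) {
    A[e] <- 1
    A[e[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Sparse adjacency matrix of a binary graph
#'
#' @param g a `binary_graph`
#' @return a symmetric sparse pattern matrix (`Matrix::nsCMatrix`)
#' @export
graph_adjacency_sparse <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  e <- graph_edges(g)
  m <- Matrix::sparseMatrix(i = e[, 1L], j = e[, 2L], x = rep(1, nrow(e)),
                            dims = c(g$N, g$N), symmetric = TRUE)
  m
}

#' Test whether an edge is present
#' @param g a `binary_graph`
#' @param i,j node indices
#' @return logical
#' @export
has_edge <- function(g, i, j) {
  j %in% g$neighbors[[i]]
}

#' Edge sparsity of a graph
#'
#' Fraction of realized edges among the \eqn{N(N-1)/2} possible node pairs,
#' \eqn{S = 2M / (N(N-1))}; equals mean degree divided by \eqn{N-1}. This is
#' the quantity the correlation threshold sweeps control.
#'
#' @param g a `binary_graph` with at least 2 nodes
#' @return sparsity fraction in [0, 1]
#' @export
sparsity <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$N < 2L) stop("sparsity requires at least 2 nodes")
  2 * g$M / (g$N * (g$N - 1))
}
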