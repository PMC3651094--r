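#' Read a binary graph from Matrix Market or edge-list text
#'
#' `.mtx` files are parsed as Matrix Market sparse matrices (the
#' pattern-symmetric flavor is the package's on-disk convention); any other
#' extension is treated as a whitespace-delimited two-column edge list of
#' 1-based node indices, with optional `#` comment lines. Symmetric closure
#' is applied on read: an edge listed in one direction is present in both.
#' Self-loops and duplicate (after closure) edges are rejected.
#'
#' @param path input file
#' @param n_nodes node count for edge lists; ignored for `.mtx` (taken from
#'   the header). Defaults to the largest index seen.
#' @return a `binary_graph`
#' @export
read_graph <- function(path, n_nodes = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- Matrix::readMM(path)
    if (nrow(m) != ncol(m)) stop("adjacency matrix must be square")
    tm <- as(m, "TsparseMatrix")
    i <- tm@i + 1L
    j <- tm@j + 1L
    n <- nrow(m)
    sym <- methods::is(m, "symmetricMatrix")
    if (any(i == j)) stop("self-loop found in ", path)
    if (!sym) {
      # general storage: require each edge once or symmetric pair; close symmetrically
      a <- pmin(i, j); b <- pmax(i, j)
      key <- paste(a, b)
      dup <- duplicated(key)
      if (any(dup)) {
        # allowed only if listed exactly once per direction
        cnt <- table(key)
        if (any(cnt > 2L)) stop("duplicate edge found in ", path)
        keep <- !dup
        a <- a[keep]; b <- b[keep]
      }
      return(binary_graph(cbind(a, b), n))
    }
    return(binary_graph(cbind(i, j), n))
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("i", "j"))
  e <- as.matrix(tab)
  if (any(e[, 1L] == e[, 2L])) stop("self-loop found in ", path)
  a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
  if (anyDuplicated(paste(a, b))) stop("duplicate edge found in ", path)
  if (is.null(n_nodes)) n_nodes <- max(e)
  binary_graph(cbind(a, b), n_nodes)
}

#' Write a binary graph to Matrix Market or edge-list text
#'
#' `.mtx` paths get Matrix Market "coordinate pattern symmetric" output (one
#' triangle stored, as the format prescribes); other paths get a two-column
#' tab-separated edge list with `i < j`.
#'
#' @param g a `binary_graph`
#' @param path output file
#' @return invisibly, the path
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "binary_graph"))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- graph_adjacency_sparse(g)
    Matrix::writeMM(as(m, "nMatrix"), path)
  } else {
    e <- graph_edges(g)
    utils::write.table(e, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
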