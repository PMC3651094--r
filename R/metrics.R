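#' Nodal degree
#'
#' @param g a `binary_graph`
#' @return integer vector k with `sum(k) == 2 * g$M`
#' @export
degree_vector <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  g$degrees
}

#' Clustering coefficient
#'
#' Per-node clustering \eqn{C_i = 2 T_i / (k_i (k_i - 1))}, where \eqn{T_i}
#' counts triangles through node i; nodes with fewer than two neighbors get
#' \eqn{C_i = 0} by convention. `Cp` is the plain mean over all nodes.
#'
#' @param g a `binary_graph`
#' @return list with `local` (per-node C_i) and `Cp` (network mean)
#' @export
clustering <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  N <- g$N
  nbr <- g$neighbors
  k <- g$degrees
  ci <- numeric(N)
  for (i in seq_len(N)) {
    if (k[i] < 2L) next
    nb <- nbr[[i]]
    # links among neighbors: each neighbor-pair edge counted once per endpoint
    t2 <- 0L
    for (j in nb) {
      t2 <- t2 + sum(nbr[[j]] %in% nb)
    }
    ci[i] <- t2 / (k[i] * (k[i] - 1L))  # t2 = 2 * T_i already
  }
  list(local = ci, Cp = mean(ci))
}
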