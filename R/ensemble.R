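#' Degree-preserving (Maslov-Sneppen) edge rewiring
#'
#' Randomizes topology by repeated double-edge swaps: two distinct edges
#' (a,b) and (c,d) are drawn uniformly (each edge's orientation randomized),
#' and the swap to (a,d), (c,b) is accepted iff it creates no self-loop and
#' no duplicate edge. Every node's degree is exactly preserved and the graph
#' stays simple. Rewiring continues until `swaps_per_edge * M` swaps have
#' been accepted or the proposal cap (`100 * swaps_per_edge * M`) is hit, in
#' which case the current graph is returned with attribute
#' `maslov_saturated = TRUE` and a warning (e.g. a triangle admits no legal
#' swap at all).
#'
#' @param g a `binary_graph` with at least 2 edges
#' @param swaps_per_edge target accepted swaps per edge (default 10)
#' @param seed integer seed
#' @return a rewired `binary_graph` with the same degree sequence
#' @export
maslov_rewire <- function(g, swaps_per_edge = 10, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$M < 2L) stop("rewiring needs at least 2 edges")
  set.seed(as.integer(seed))
  E <- graph_edges(g)
  M <- nrow(E)
  adj <- g$neighbors  # sorted vectors; we keep them as unsorted sets during swaps
  target <- ceiling(swaps_per_edge * M)
  cap <- ceiling(100 * swaps_per_edge * M)
  done <- 0L
  tries <- 0L
  while (done < target && tries < cap) {
    tries <- tries + 1L
    idx <- sample.int(M, 2L)
    e1 <- E[idx[1L], ]; e2 <- E[idx[2L], ]
    # randomize orientation so all pairings are proposable
    if (stats::runif(1) < 0.5) e1 <- rev(e1)
    if (stats::runif(1) < 0.5) e2 <- rev(e2)
    a <- e1[1L]; b <- e1[2L]; c <- e2[1L]; d <- e2[2L]
    # proposed edges (a,d) and (c,b)
    if (a == d || c == b) next
    if (d %in% adj[[a]] || b %in% adj[[c]]) next
    # commit: remove (a,b),(c,d); add (a,d),(c,b)
    adj[[a]] <- c(adj[[a]][adj[[a]] != b], d)
    adj[[b]] <- c(adj[[b]][adj[[b]] != a], c)
    adj[[c]] <- c(adj[[c]][adj[[c]] != d], b)
    adj[[d]] <- c(adj[[d]][adj[[d]] != c], a)
    E[idx[1L], ] <- c(min(a, d), max(a, d))
    E[idx[2L], ] <- c(min(c, b), max(c, b))
    done <- done + 1L
  }
  out <- binary_graph(E, g$N)
  if (done < target) {
    warning(sprintf("rewiring saturated: %d of %d swaps accepted after %d proposals",
                    done, target, tries))
    attr(out, "maslov_saturated") <- TRUE
  }
  out
}

#' Null-ensemble summary of clustering, path length and modularity
#'
#' Generates `n` independent Maslov-rewired copies of `g` (seeds
#' `base_seed + 0 .. n-1`), computes Cp and Lp for each (and Q via spectral
#' division when `with_Q = TRUE`), and returns ensemble means and sample
#' standard deviations — the reference values for the small-world ratios
#' and the modularity z-score.
#'
#' @param g a `binary_graph`
#' @param n ensemble size (default 15)
#' @param base_seed integer; network i uses seed `base_seed + i - 1`
#' @param swaps_per_edge passed to [maslov_rewire()]
#' @param with_Q also compute null modularities (slower)
#' @param engine APSP engine for Lp (`"auto"`, `"bfs"`, `"fw"`)
#' @return object of class `ensemble_summary` with per-network values,
#'   means and sds; with `n = 1` the sds are reported as 0 and flagged
#'   (`sd_degenerate = TRUE`)
#' @export
ensemble_summary <- function(g, n = 15L, base_seed = 1L, swaps_per_edge = 10,
                             with_Q = FALSE, engine = "auto") {
  stopifnot(inherits(g, "binary_graph"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  seeds <- as.integer(base_seed) + seq_len(n) - 1L
  Cp <- Lp <- Q <- numeric(n)
  for (i in seq_len(n)) {
    r <- suppressWarnings(maslov_rewire(g, swaps_per_edge, seed = seeds[i]))
    Cp[i] <- clustering(r)$Cp
    Lp[i] <- characteristic_path_length(apsp(r, engine = engine))
    if (with_Q) Q[i] <- spectral_divide(r, seed = seeds[i])$Q
  }
  degen <- n == 1L
  structure(list(n_networks = n, seeds = seeds,
                 Cp_rand = Cp, Lp_rand = Lp,
                 Q_rand = if (with_Q) Q else NULL,
                 Cp_rand_mean = mean(Cp),
                 Cp_rand_sd = if (degen) 0 else stats::sd(Cp),
                 Lp_rand_mean = mean(Lp),
                 Lp_rand_sd = if (degen) 0 else stats::sd(Lp),
                 sd_degenerate = degen),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d degree-matched null networks\n", x$n_networks))
  cat(sprintf("  Cp_rand = %.4g +/- %.2g\n", x$Cp_rand_mean, x$Cp_rand_sd))
  cat(sprintf("  Lp_rand = %.4g +/- %.2g\n", x$Lp_rand_mean, x$Lp_rand_sd))
  if (!is.null(x$Q_rand))
    cat(sprintf("  Q_rand  = %.4g +/- %.2g\n", mean(x$Q_rand), stats::sd(x$Q_rand)))
  invisible(x)
}
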