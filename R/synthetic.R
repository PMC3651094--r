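#' Planted modular time-series design
#'
#' Describes a multi-node Gaussian time-series generator with block-constant
#' correlation: `within_r` inside each module, `between_r` across modules,
#' unit variance everywhere. The implied covariance is realized exactly by a
#' three-level factor model (global factor, module factor, idiosyncratic
#' noise), which is positive semi-definite precisely when
#' `0 <= between_r <= within_r < 1` — checked at construction. An optional
#' AR(1) coefficient temporally smooths every latent series, approximating
#' the band-limited character of hemodynamic signals without changing the
#' cross-node correlation structure.
#'
#' @param N node count (split as evenly as possible into `n_modules` blocks)
#' @param L time points
#' @param n_modules planted module count
#' @param within_r target within-module correlation
#' @param between_r target between-module correlation
#' @param subject_noise_sd sd of per-subject random offsets added to the
#'   latent factor loadings (0 = identical population structure)
#' @param ar AR(1) coefficient in [0, 1) for temporal smoothing (0 = white)
#' @param seed integer seed
#' @return object of class `planted_design`
#' @export
planted_design <- function(N = 100L, L = 2000L, n_modules = 4L,
                           within_r = 0.9, between_r = 0.0,
                           subject_noise_sd = 0.05, ar = 0, seed = 1L) {
  if (!(between_r >= 0 && between_r <= within_r && within_r < 1))
    stop("need 0 <= between_r <= within_r < 1 (implied covariance must be PSD)")
  if (N < n_modules) stop("need at least one node per module")
  if (L < 3) stop("need at least 3 time points")
  if (ar < 0 || ar >= 1) stop("ar must be in [0, 1)")
  module <- sort(rep_len(seq_len(n_modules), N))
  structure(list(N = as.integer(N), L = as.integer(L),
                 n_modules = as.integer(n_modules),
                 within_r = within_r, between_r = between_r,
                 subject_noise_sd = subject_noise_sd,
                 ar = ar, seed = as.integer(seed),
                 module = module),
            class = "planted_design")
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf(paste0("planted_design: %d nodes x %d time points, %d modules",
                     " (r_within = %.2f, r_between = %.2f, ar = %.2f)\n"),
              x$N, x$L, x$n_modules, x$within_r, x$between_r, x$ar))
  invisible(x)
}

# unit-variance noise series, optionally AR(1) with coefficient phi
.noise_series <- function(L, ncol, phi) {
  x <- matrix(stats::rnorm(L * ncol), L, ncol)
  if (phi > 0) {
    x <- apply(x, 2L, function(v) stats::filter(v, phi, method = "recursive"))
    x <- x * sqrt(1 - phi^2)  # stationary unit variance
  }
  x
}

#' Generate one subject's planted modular time series
#'
#' Samples L draws of N unit-variance Gaussian signals whose population
#' correlation is exactly block-constant: `between_r` for any cross-module
#' pair and `within_r` within a module. Construction: with
#' \eqn{b = between\_r}, \eqn{w = within\_r},
#' \eqn{x_i = \sqrt{b}\, g + \sqrt{w - b}\, f_{m(i)} + \sqrt{1 - w}\,
#' \epsilon_i} for a shared factor g, module factors f and idiosyncratic
#' noise. Deterministic under `seed`.
#'
#' @param design a `planted_design`
#' @param seed overrides the design seed when given
#' @param subject_id label carried on the output
#' @return a `timeseries_set` with the planted module labels in
#'   `attr(, "module")`
#' @export
gen_modular_timeseries <- function(design, seed = design$seed,
                                   subject_id = "sim") {
  stopifnot(inherits(design, "planted_design"))
  set.seed(as.integer(seed))
  L <- design$L; N <- design$N
  b <- design$between_r; w <- design$within_r
  gfac <- .noise_series(L, 1L, design$ar)
  mfac <- .noise_series(L, design$n_modules, design$ar)
  eps <- .noise_series(L, N, design$ar)
  loads <- c(sqrt(b), sqrt(w - b), sqrt(1 - w))
  if (design$subject_noise_sd > 0) {
    jitter <- stats::rnorm(1L, 0, design$subject_noise_sd)
    # mild subject-specific tilt of the shared structure, kept inside PSD range
    wj <- min(max(w + jitter * (1 - w), b), 0.995)
    loads <- c(sqrt(b), sqrt(wj - b), sqrt(1 - wj))
  }
  x <- loads[1L] * gfac[, rep(1L, N)] +
    loads[2L] * mfac[, design$module, drop = FALSE] +
    loads[3L] * eps
  out <- timeseries_set(x, subject_id = subject_id)
  attr(out, "module") <- design$module
  out
}

#' Generate a multi-subject set of planted time series
#'
#' Independent subjects share the design's population structure; subject i
#' uses seed `design$seed + i`. As `n_subjects * L` grows the group-averaged
#' correlation matrix converges to the design correlations.
#'
#' @param design a `planted_design`
#' @param n_subjects number of subjects
#' @return list of `timeseries_set`
#' @export
gen_subject_set <- function(design, n_subjects) {
  stopifnot(inherits(design, "planted_design"))
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(i)
    gen_modular_timeseries(design, seed = design$seed + i,
                           subject_id = sprintf("sub-%03d", i)))
}

#' Benchmark graph generators
#'
#' Deterministic and seeded constructions used as oracle fixtures:
#' \describe{
#'   \item{complete}{K_N; `params$N`}
#'   \item{cycle}{N-cycle; `params$N`}
#'   \item{path}{path graph; `params$N`}
#'   \item{star}{one center plus N-1 leaves; `params$N`}
#'   \item{er}{Erdos-Renyi G(N, p); `params$N`, `params$p`}
#'   \item{ring_lattice}{ring with `params$k` neighbors per side (2k-regular);
#'     `params$N`, `params$k`}
#'   \item{watts_strogatz}{ring lattice with each edge rewired independently
#'     with probability `params$p` (duplicate/self-loop proposals skipped);
#'     `params$N`, `params$k`, `params$p`}
#'   \item{planted_partition}{`params$blocks` blocks of `params$size` nodes,
#'     edge probabilities `params$p_in` within and `params$p_out` between}
#'   \item{two_cliques}{two disjoint K_`params$size` cliques}
#'   \item{barbell}{two K_`params$size` cliques joined by a single bridge edge}
#' }
#'
#' @param kind generator name (see above)
#' @param params list of parameters for the generator
#' @param seed integer seed (random kinds only)
#' @return a `binary_graph`; planted kinds carry `attr(, "module")`
#' @export
gen_graph <- function(kind, params = list(), seed = 1L) {
  kind <- match.arg(kind, c("complete", "cycle", "path", "star", "er",
                            "ring_lattice", "watts_strogatz",
                            "planted_partition", "two_cliques", "barbell"))
  p <- params
  full_edges <- function(nodes) t(utils::combn(nodes, 2L))
  switch(kind,
    complete = {
      N <- p$N; if (is.null(N) || N < 2) stop("complete: need N >= 2")
      binary_graph(full_edges(seq_len(N)), N)
    },
    cycle = {
      N <- p$N; if (is.null(N) || N < 3) stop("cycle: need N >= 3")
      binary_graph(cbind(seq_len(N), c(seq_len(N)[-1L], 1L)), N)
    },
    path = {
      N <- p$N; if (is.null(N) || N < 2) stop("path: need N >= 2")
      binary_graph(cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L), N)
    },
    star = {
      N <- p$N; if (is.null(N) || N < 2) stop("star: need N >= 2")
      binary_graph(cbind(1L, 2:N), N)
    },
    er = {
      N <- p$N; prob <- p$p
      if (is.null(N) || is.null(prob) || N < 2 || prob < 0 || prob > 1)
        stop("er: need N >= 2 and p in [0, 1]")
      set.seed(as.integer(seed))
      all_e <- full_edges(seq_len(N))
      keep <- stats::runif(nrow(all_e)) < prob
      binary_graph(all_e[keep, , drop = FALSE], N)
    },
    ring_lattice = {
      N <- p$N; k <- p$k
      if (is.null(N) || is.null(k) || k < 1 || N < 2 * k + 1)
        stop("ring_lattice: need k >= 1 and N >= 2k + 1")
      i <- rep(seq_len(N), each = k)
      off <- rep(seq_len(k), N)
      j <- ((i - 1L + off) %% N) + 1L
      binary_graph(cbind(i, j), N)
    },
    watts_strogatz = {
      N <- p$N; k <- p$k; prob <- p$p
      if (is.null(prob) || prob < 0 || prob > 1)
        stop("watts_strogatz: need rewiring p in [0, 1]")
      g0 <- gen_graph("ring_lattice", list(N = N, k = k))
      set.seed(as.integer(seed))
      E <- graph_edges(g0)
      adj <- g0$neighbors
      for (idx in seq_len(nrow(E))) {
        if (stats::runif(1) >= prob) next
        a <- E[idx, 1L]; b <- E[idx, 2L]
        cand <- sample.int(N, 1L)
        if (cand == a || cand %in% adj[[a]]) next
        adj[[a]] <- c(adj[[a]][adj[[a]] != b], cand)
        adj[[b]] <- adj[[b]][adj[[b]] != a]
        adj[[cand]] <- c(adj[[cand]], a)
        E[idx, ] <- c(min(a, cand), max(a, cand))
      }
      binary_graph(E, N)
    },
    planted_partition = {
      nb <- p$blocks; sz <- p$size; p_in <- p$p_in; p_out <- p$p_out
      if (is.null(nb) || is.null(sz) || is.null(p_in) || is.null(p_out))
        stop("planted_partition: need blocks, size, p_in, p_out")
      N <- nb * sz
      lab <- rep(seq_len(nb), each = sz)
      set.seed(as.integer(seed))
      all_e <- full_edges(seq_len(N))
      pr <- ifelse(lab[all_e[, 1L]] == lab[all_e[, 2L]], p_in, p_out)
      keep <- stats::runif(nrow(all_e)) < pr
      g <- binary_graph(all_e[keep, , drop = FALSE], N)
      attr(g, "module") <- lab
      g
    },
    two_cliques = {
      sz <- p$size; if (is.null(sz) || sz < 2) stop("two_cliques: need size >= 2")
      e <- rbind(full_edges(seq_len(sz)), full_edges(sz + seq_len(sz)))
      g <- binary_graph(e, 2L * sz)
      attr(g, "module") <- rep(1:2, each = sz)
      g
    },
    barbell = {
      sz <- p$size; if (is.null(sz) || sz < 2) stop("barbell: need size >= 2")
      e <- rbind(full_edges(seq_len(sz)), full_edges(sz + seq_len(sz)),
                 c(sz, sz + 1L))
      g <- binary_graph(e, 2L * sz)
      attr(g, "module") <- rep(1:2, each = sz)
      g
    })
}
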