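# Independent oracles used across the suite. These deliberately use the
# most naive formulation available (dense triple loops, exhaustive
# enumeration) and never call the package's own engines.

# textbook Floyd-Warshall on a dense adjacency matrix
naive_fw <- function(A) {
  N <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(N)) {
    for (i in seq_len(N)) {
      alt <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], alt)
    }
  }
  D
}

# brute-force modularity: the literal double sum over all ordered pairs
brute_Q <- function(A, labels) {
  k <- rowSums(A)
  m2 <- sum(k)
  N <- nrow(A)
  q <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (labels[i] == labels[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# dense modularity matrix
dense_B <- function(A) {
  k <- rowSums(A)
  A - outer(k, k) / sum(k)
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return()
    }
    for (lab in seq_len(next_max + 1L)) {
      rec(c(labels, lab), max(next_max, lab))
    }
  }
  rec(integer(), 0L)
  out
}

# exhaustive maximum-modularity search (small n only)
best_Q <- function(A) {
  parts <- all_partitions(nrow(A))
  max(vapply(parts, function(p) brute_Q(A, p), 0))
}

# random simple graph helper (uniform over edges)
random_graph <- function(N, p, seed) {
  gen_graph("er", list(N = N, p = p), seed = seed)
}

# do two label vectors describe the same partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}
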