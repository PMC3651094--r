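test_that("degree and clustering match enumeration oracles", {
  star <- gen_graph("star", list(N = 5))
  expect_equal(degree_vector(star), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(clustering(star)$local, rep(0, 5))
  empty <- binary_graph(matrix(integer(), ncol = 2), 4)
  expect_equal(degree_vector(empty), rep(0L, 4))

  k3 <- gen_graph("complete", list(N = 3))
  expect_equal(clustering(k3)$Cp, 1)

  # handshake identity and triple-enumeration oracle on random graphs
  for (s in 1:10) {
    g <- random_graph(30, 0.2, seed = s)
    expect_equal(sum(degree_vector(g)), 2L * g$M)
    A <- as.matrix(g)
    ci_or <- sapply(seq_len(g$N), function(i) {
      nb <- which(A[i, ] > 0)
      if (length(nb) < 2) return(0)
      tri <- 0
      for (a in nb) for (b in nb) if (a < b && A[a, b] > 0) tri <- tri + 1
      2 * tri / (length(nb) * (length(nb) - 1))
    })
    expect_equal(clustering(g)$local, ci_or)
  }
})

test_that("clustering agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    g <- random_graph(40, 0.15, seed = 100 + s)
    ig <- igraph::graph_from_edgelist(graph_edges(g), directed = FALSE)
    ig <- igraph::add_vertices(ig, g$N - igraph::vcount(ig))
    ref <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    # igraph treats k < 2 as NaN/zero per isolates; align convention
    expect_equal(clustering(g)$local, ref, tolerance = 1e-12)
  }
})

test_that("both APSP engines equal the textbook Floyd-Warshall", {
  p4 <- gen_graph("path", list(N = 4))
  D <- as.matrix(apsp_bfs(p4))
  expect_equal(D[1, 4], 3)
  expect_equal(D[2, 3], 1)

  for (s in 1:15) {
    g <- random_graph(sample(10:40, 1), runif(1, 0.05, 0.6), seed = 200 + s)
    Dref <- naive_fw(as.matrix(g))
    expect_equal(as.matrix(apsp_bfs(g)), Dref)
    for (bn in c(1, 4, 7, g$N)) {
      expect_equal(as.matrix(apsp_blocked_fw(g, bn)), Dref)
    }
    # worker count is a pure scheduling knob
    expect_identical(as.matrix(apsp_bfs(g, workers = 4)),
                     as.matrix(apsp_bfs(g, workers = 1)))
  }

  # disconnected components get Inf between, finite within
  g2 <- gen_graph("two_cliques", list(size = 3))
  D2 <- as.matrix(apsp_blocked_fw(g2, 2))
  expect_true(all(is.infinite(D2[1:3, 4:6])))
  expect_true(all(D2[1:3, 1:3][upper.tri(diag(3))] == 1))
})

test_that("blocked FW distances agree with an independent graph library", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    g <- random_graph(35, 0.1, seed = 300 + s)
    ig <- igraph::graph_from_edgelist(graph_edges(g), directed = FALSE)
    ig <- igraph::add_vertices(ig, g$N - igraph::vcount(ig))
    ref <- igraph::distances(ig)
    expect_equal(as.matrix(apsp_blocked_fw(g, 8)), ref, ignore_attr = TRUE)
  }
})

test_that("path length and efficiency follow their closed forms", {
  p3 <- gen_graph("path", list(N = 3))
  expect_equal(characteristic_path_length(apsp_bfs(p3)), 4 / 3)
  expect_equal(global_efficiency(apsp_bfs(p3)), 5 / 6)

  k6 <- gen_graph("complete", list(N = 6))
  expect_equal(characteristic_path_length(apsp_bfs(k6)), 1)
  expect_equal(global_efficiency(apsp_bfs(k6)), 1)

  # two disjoint edges: finite-pairs policy counts only intra-pair distances
  e2 <- binary_graph(rbind(c(1, 2), c(3, 4)), 4)
  expect_equal(characteristic_path_length(apsp_bfs(e2)), 1)
  expect_error(characteristic_path_length(apsp_bfs(e2), strict = TRUE),
               "disconnected")
  expect_equal(global_efficiency(apsp_bfs(binary_graph(matrix(integer(), ncol = 2), 3))), 0)

  # ring of even N: Lp = (N^2/4)/(N-1)
  for (N in seq(4, 20, by = 2)) {
    ring <- gen_graph("cycle", list(N = N))
    expect_equal(characteristic_path_length(apsp_bfs(ring)),
                 (N^2 / 4) / (N - 1))
  }
  # ring lattice Cp closed form 3(k-1)/(2(2k-1)), rewiring 0
  for (k in 2:4) {
    rl <- gen_graph("ring_lattice", list(N = 30, k = k))
    expect_equal(clustering(rl)$Cp, 3 * (k - 1) / (2 * (2 * k - 1)))
  }
})

test_that("engine selection switches at the sparsity crossover, ties to BFS", {
  expect_equal(select_apsp(0.00151), "bfs")
  expect_equal(select_apsp(0.05), "fw")
  expect_equal(select_apsp(0.02), "bfs")
  expect_equal(select_apsp(0.5, crossover = 0.6), "bfs")
  expect_error(select_apsp(1.2), "sparsity")
})
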