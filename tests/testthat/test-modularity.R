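test_that("the implicit operator matches the dense modularity matrix", {
  for (s in 1:5) {
    g <- random_graph(6, 0.5, seed = 400 + s)
    if (g$M < 1) next
    A <- as.matrix(g)
    B <- dense_B(A)
    op <- modularity_operator(g)
    for (t in 1:3) {
      x <- rnorm(6)
      expect_equal(apply_B(op, x), as.numeric(B %*% x), tolerance = 1e-12)
    }
    # rows of B sum to zero: the all-ones vector is annihilated
    expect_lt(max(abs(apply_B(op, rep(1, 6)))), 1e-9)
    # restricted operator: generalized matrix rows still sum to zero
    sub <- 1:4
    opr <- modularity_operator(g, nodes = sub)
    expect_lt(max(abs(apply_B(opr, rep(1, 4)))), 1e-9)
    # and matches the dense generalized matrix
    Bg <- B[sub, sub] - diag(rowSums(B[sub, sub]))
    x <- rnorm(4)
    expect_equal(apply_B(opr, x), as.numeric(Bg %*% x), tolerance = 1e-12)
  }
  expect_error(apply_B(modularity_operator(random_graph(6, 0.5, 1)), rnorm(5)),
               "length")
})

test_that("power iteration returns the most positive eigenvalue", {
  # diagonal stand-ins with known spectra; exercises the negative-dominant shift
  r1 <- power_method(diag(c(3, 1, -5)), seed = 2)
  expect_true(r1$converged)
  expect_equal(r1$beta, 3, tolerance = 1e-6)
  r2 <- power_method(diag(c(2, 2, 0)), seed = 2)
  expect_equal(r2$beta, 2, tolerance = 1e-6)
  # near-cancelling +/- dominant pair: the norm-bound fallback must resolve it
  r3 <- power_method(diag(c(3, -3, 1)), seed = 2)
  expect_equal(r3$beta, 3, tolerance = 1e-5)

  # two disconnected triangles: beta > 0, sign pattern separates the cliques
  g <- gen_graph("two_cliques", list(size = 3))
  er <- power_method(modularity_operator(g), seed = 5)
  ref <- eigen(dense_B(as.matrix(g)), symmetric = TRUE)
  expect_equal(er$beta, ref$values[1], tolerance = 1e-6)
  s <- sign(er$x)
  expect_true(length(unique(s[1:3])) == 1 && length(unique(s[4:6])) == 1 &&
                s[1] != s[4])
  # residual contract
  op <- modularity_operator(g)
  expect_lt(max(abs(apply_B(op, er$x) - er$beta * er$x)), 1e-6 * er$beta)
})

test_that("modularity Q equals the brute-force double sum", {
  g <- gen_graph("two_cliques", list(size = 3))
  expect_equal(modularity_Q(g, rep(1, 6)), 0)          # one module: exact zero
  expect_equal(modularity_Q(g, attr(g, "module")), 0.5) # 2*(3/6 - (6/12)^2)
  for (s in 1:10) {
    gg <- random_graph(8, 0.4, seed = 500 + s)
    if (gg$M < 1) next
    lab <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_Q(gg, lab), brute_Q(as.matrix(gg), lab),
                 tolerance = 1e-12)
  }
})

test_that("spectral division finds planted and optimal structure", {
  # two disconnected K3s: the division queue should stop at the exact optimum
  g <- gen_graph("two_cliques", list(size = 3))
  p <- spectral_divide(g, seed = 1)
  expect_equal(p$module_count, 2L)
  expect_equal(p$Q, 0.5)
  expect_equal(p$Q, best_Q(as.matrix(g)))
  expect_true(same_partition(p$labels, attr(g, "module")))

  # complete graph: no positive eigenvalue, single module, Q = 0
  k5 <- gen_graph("complete", list(N = 5))
  pk <- spectral_divide(k5, seed = 1)
  expect_equal(pk$module_count, 1L)
  expect_equal(pk$Q, 0)

  # barbell: exhaustive optimum is the two-clique split
  gb <- gen_graph("barbell", list(size = 4))
  pb <- spectral_divide(gb, seed = 1)
  expect_equal(pb$Q, best_Q(as.matrix(gb)), tolerance = 1e-10)
  expect_true(same_partition(pb$labels, attr(gb, "module")))

  # planted partition at a fixed seed recovers the four blocks exactly
  gp <- gen_graph("planted_partition",
                  list(blocks = 4, size = 10, p_in = 0.9, p_out = 0.05),
                  seed = 1)
  pp <- spectral_divide(gp, seed = 1)
  expect_equal(pp$module_count, 4L)
  expect_true(same_partition(pp$labels, attr(gp, "module")))

  # labels are dense 0-based ids and Q is within [-1, 1]
  expect_setequal(unique(pp$labels), 0:3)
  expect_true(pp$Q >= -1 && pp$Q <= 1)
})

test_that("every accepted split strictly increases Q and seeds fix the result", {
  for (s in 1:6) {
    g <- random_graph(25, 0.15, seed = 600 + s)
    if (g$M < 2) next
    p1 <- spectral_divide(g, seed = 42)
    p2 <- spectral_divide(g, seed = 42)
    expect_identical(p1$labels, p2$labels)   # determinism under fixed seed
    expect_gte(p1$Q, 0)
    for (rec in p1$log) if (rec$accepted) expect_gt(rec$dQ, 0)
  }
})

test_that("modularity z-scores are location-invariant sample-sd ratios", {
  expect_equal(modularity_zscore(0.2, c(0.1, 0.2, 0.3)), 0)
  expect_equal(modularity_zscore(0.8, c(0.1, 0.2, 0.3)), 6.0)
  expect_equal(modularity_zscore(0.8 + 5, c(0.1, 0.2, 0.3) + 5),
               modularity_zscore(0.8, c(0.1, 0.2, 0.3)))
  expect_error(modularity_zscore(0.5, c(0.2, 0.2)), "zero spread")
  expect_error(modularity_zscore(0.5, 0.2), "at least 2")
})
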