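test_that("normalization makes U'U the Pearson matrix", {
  # closed-form column: (1,2,3) -> (-1/sqrt(2), 0, 1/sqrt(2))
  u <- normalize_series(cbind(a = c(1, 2, 3), b = c(2, 1, 2)))
  expect_equal(u$U[, 1], c(-1, 0, 1) / sqrt(2))
  # identical columns correlate at 1, negated at -1
  x <- rnorm(20)
  U <- normalize_series(cbind(x, x, -x))$U
  R <- crossprod(U)
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  # oracle: direct Pearson formula
  set.seed(7)
  M <- matrix(rnorm(25 * 6), 25, 6)
  expect_equal(crossprod(normalize_series(M)$U), cor(M), tolerance = 1e-9,
               ignore_attr = TRUE)
  # column sums ~ 0, unit norms
  expect_lt(max(abs(colSums(normalize_series(M)$U))), 1e-9)
  expect_lt(max(abs(sqrt(colSums(normalize_series(M)$U^2)) - 1)), 1e-9)
  # constant column is a hard error naming the node
  expect_error(normalize_series(cbind(rnorm(10), rep(2, 10))), "node.*2")
})

test_that("blocked correlation tiles the upper triangle and matches the dense product", {
  set.seed(11)
  X <- matrix(rnorm(20 * 30), 20, 30)
  ns <- normalize_series(X)
  ref <- cor(X)
  # block count: N = 5, block 2 -> 3x3 block grid, 6 upper blocks
  blk5 <- blocked_correlation(normalize_series(X[, 1:5]), 2)
  expect_length(blk5, 6L)
  for (bs in c(1, 3, 7, 30, 64)) {
    blocks <- blocked_correlation(ns, bs)
    R <- assemble_correlation(blocks, 30)
    expect_false(anyNA(R))  # tiles cover everything exactly once
    expect_equal(R, ref, tolerance = 1e-9, ignore_attr = TRUE)
    # emitted blocks never dip below the block diagonal
    for (b in blocks) expect_gte(b$col_range[1], b$row_range[1])
  }
  # block_size >= N gives exactly one block equal to the full matrix
  one <- blocked_correlation(ns, 30)
  expect_length(one, 1L)
  expect_equal(one[[1]]$values, ref, tolerance = 1e-9, ignore_attr = TRUE)
  # streaming callback visits the same blocks without accumulating
  seen <- 0L
  blocked_correlation(ns, 7, callback = function(b) seen <<- seen + 1L)
  expect_equal(seen, length(blocked_correlation(ns, 7)))
})

test_that("group averaging is the element-wise mean (with a Fisher-z option)", {
  set.seed(3)
  mats <- replicate(3, {
    m <- matrix(runif(16, -0.8, 0.8), 4); m <- (m + t(m)) / 2; diag(m) <- 1; m
  }, simplify = FALSE)
  expect_equal(group_average(mats[1]), mats[[1]])
  expect_equal(group_average(list(mats[[1]], -mats[[1]])),
               matrix(0, 4, 4))
  hand <- (mats[[1]] + mats[[2]] + mats[[3]]) / 3
  expect_equal(group_average(mats), hand)
  expect_error(group_average(list(mats[[1]], matrix(0, 3, 3))), "identical shape")
  # Fisher-z average of identical matrices is the matrix itself
  expect_equal(group_average(list(mats[[2]], mats[[2]]), fisher = TRUE),
               mats[[2]], tolerance = 1e-9)
})

test_that("analytic sparsity bounds behave as derived", {
  expect_equal(sparsity_lower_bound(3), log(3) / 2)
  expect_error(sparsity_lower_bound(2))
  # strictly decreasing in N
  Ns <- round(10^seq(log10(3), 6, length.out = 40))
  expect_true(all(diff(sapply(Ns, sparsity_lower_bound)) < 0))

  # r_crit increases with N at fixed L, and vanishes as the per-test level -> 1
  rs <- sapply(c(10, 100, 1000, 1e5), bonferroni_threshold, L = 100)
  expect_true(all(diff(rs) > 0))
  expect_lt(bonferroni_threshold(2, 100, alpha = 0.9999), 0.01)
  expect_error(bonferroni_threshold(100, 100, alpha = 1.5), "alpha")

  # oracle: numeric inversion of the t tail via uniroot on the p-value
  r1 <- bonferroni_threshold(500, 120)
  pval <- function(r, L) 2 * pt(r * sqrt((L - 2) / (1 - r^2)), df = L - 2,
                                lower.tail = FALSE)
  r_or <- uniroot(function(r) pval(r, 120) - 0.05 / (500 * 499 / 2),
                  c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  expect_equal(r1, r_or, tolerance = 1e-8)
})

test_that("Monte-Carlo null correlations exceed r_crit at the nominal rate", {
  # independent Gaussian pairs, L = 50: exceedance of the two-tailed critical
  # value should match the per-test level within 3 binomial standard errors
  set.seed(2024)
  L <- 50; npair <- 1e5
  X <- matrix(rnorm(L * npair), L)
  Y <- matrix(rnorm(L * npair), L)
  cx <- sweep(X, 2, colMeans(X)); cy <- sweep(Y, 2, colMeans(Y))
  r <- colSums(cx * cy) / sqrt(colSums(cx^2) * colSums(cy^2))
  # choose a per-test level via the Bonferroni helper with N giving ~1% tests
  alpha_per <- 0.01
  N_eff <- 2  # single comparison; scale alpha so alpha / 1 = alpha_per
  rc <- bonferroni_threshold(N_eff, L, alpha = alpha_per)
  obs <- mean(abs(r) > rc)
  se <- sqrt(alpha_per * (1 - alpha_per) / npair)
  expect_lt(abs(obs - alpha_per), 3 * se)
})

test_that("binarization thresholds strictly and tracks sparsity", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.2
  R[2, 3] <- R[3, 2] <- 0.5
  g <- binarize(R, 0.45)
  expect_equal(g$M, 2L)
  expect_true(has_edge(g, 1, 2) && has_edge(g, 2, 3))
  expect_equal(binarize(R, 0.9)$M, 0L)       # strict: 0.9 > 0.9 is FALSE
  expect_equal(binarize(R, 0.1)$M, 3L)
  Rb <- R; Rb[1, 2] <- 0.3
  expect_error(binarize(Rb, 0.5), "symmetric")

  expect_equal(sparsity(gen_graph("complete", list(N = 5))), 1.0)
  expect_equal(sparsity(binary_graph(matrix(integer(), ncol = 2), 4)), 0.0)
  k3_iso <- binary_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), 4)
  expect_equal(sparsity(k3_iso), 0.5)

  # sparsity of binarize(R, t) is non-increasing in t
  set.seed(5)
  Rr <- cor(matrix(rnorm(40 * 12), 40, 12))
  sp <- sapply(seq(-0.5, 0.9, by = 0.1), function(t) sparsity(binarize(Rr, t)))
  expect_true(all(diff(sp) <= 0))
})
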