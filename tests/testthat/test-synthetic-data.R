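test_that("planted designs validate their covariance constraints", {
  expect_error(planted_design(within_r = 0.5, between_r = 0.7), "PSD")
  expect_error(planted_design(within_r = 1.0), "PSD")
  expect_error(planted_design(N = 3, n_modules = 5), "per module")
  d <- planted_design(N = 12, L = 100, n_modules = 3)
  expect_equal(d$module, rep(1:3, each = 4))
})

test_that("generated series are deterministic and match the design covariance", {
  d <- planted_design(N = 40, L = 200, n_modules = 4, within_r = 0.7,
                      between_r = 0.2, subject_noise_sd = 0, seed = 9)
  t1 <- gen_modular_timeseries(d)
  t2 <- gen_modular_timeseries(d)
  expect_identical(t1$data, t2$data)

  # sample covariance converges to the block design as L grows
  frob <- sapply(c(200, 2000), function(L) {
    dd <- planted_design(N = 40, L = L, n_modules = 4, within_r = 0.7,
                         between_r = 0.2, subject_noise_sd = 0, seed = 9)
    R <- correlation_matrix(gen_modular_timeseries(dd))
    tgt <- matrix(0.2, 40, 40)
    same <- outer(dd$module, dd$module, "==")
    tgt[same] <- 0.7
    diag(tgt) <- 1
    sqrt(sum((R - tgt)^2))
  })
  expect_lt(frob[2], frob[1])
  expect_lt(frob[2] / 40, 0.05)  # per-row RMS error small at L = 2000
})

test_that("within_r equal to between_r gives homogeneous correlations", {
  d <- planted_design(N = 60, L = 2000, n_modules = 4, within_r = 0.4,
                      between_r = 0.4, subject_noise_sd = 0, seed = 13)
  R <- correlation_matrix(gen_modular_timeseries(d))
  same <- outer(d$module, d$module, "==") & upper.tri(R)
  diff <- (!outer(d$module, d$module, "==")) & upper.tri(R)
  gap <- mean(R[same]) - mean(R[diff])
  # generous bound: 3 single-pair standard errors, sd(r) ~ (1-r^2)/sqrt(L)
  expect_lt(abs(gap), 3 * (1 - 0.4^2) / sqrt(2000))
})

test_that("the end-to-end planted pipeline recovers its parameters", {
  d <- planted_design(N = 100, L = 2000, n_modules = 4, within_r = 0.9,
                      between_r = 0.0, seed = 1)
  ts <- gen_modular_timeseries(d)
  R <- correlation_matrix(ts)
  p <- spectral_divide(binarize(R, 0.45), seed = 1)
  expect_equal(p$module_count, 4L)
  expect_true(same_partition(p$labels, attr(ts, "module")))
})

test_that("subject sets are independent but share the population structure", {
  d <- planted_design(N = 30, L = 500, n_modules = 3, within_r = 0.6,
                      between_r = 0.1, seed = 4)
  subs <- gen_subject_set(d, 20)
  expect_length(subs, 20L)
  expect_false(identical(subs[[1]]$data, subs[[2]]$data))
  expect_length(gen_subject_set(d, 1), 1L)
  Rbar <- group_average(lapply(subs, correlation_matrix))
  same <- outer(d$module, d$module, "==") & upper.tri(Rbar)
  expect_lt(abs(mean(Rbar[same]) - d$within_r), 0.05)
})

test_that("benchmark graph generators satisfy their defining invariants", {
  expect_equal(gen_graph("complete", list(N = 5))$M, 10L)
  expect_true(all(degree_vector(gen_graph("ring_lattice", list(N = 20, k = 2))) == 4L))
  g1 <- gen_graph("er", list(N = 30, p = 0.2), seed = 8)
  g2 <- gen_graph("er", list(N = 30, p = 0.2), seed = 8)
  expect_identical(g1$neighbors, g2$neighbors)
  ws <- gen_graph("watts_strogatz", list(N = 30, k = 2, p = 0.3), seed = 2)
  expect_equal(ws$M, 60L)   # rewiring preserves edge count
  bb <- gen_graph("barbell", list(size = 4))
  expect_equal(bb$M, 2L * 6L + 1L)
  expect_error(gen_graph("er", list(N = 5, p = 2)), "p in")
  expect_error(gen_graph("ring_lattice", list(N = 4, k = 2)), "N >= 2k")
})
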