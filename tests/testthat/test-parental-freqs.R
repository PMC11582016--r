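# est_p against the conjugate Beta posterior (the model is exactly
# Beta-binomial with a Jeffreys prior when genotypes are known)

test_that("est_p matches the conjugate Beta posterior", {
  # 10 diploids all G = 0 in source 0 -> Beta(0.5, 20.5)
  # counts (0,1,1,2,2) in source 1 -> Beta(6.5, 4.5)
  s0 <- gen_data(matrix(0, 10, 1))
  s1 <- gen_data(matrix(c(0, 1, 1, 2, 2), 5, 1))
  f <- est_p(s0, s1, config = quick_cfg(seed = 11, chains = 4))
  s <- f$summary
  expect_lt(abs(s$median[1] - qbeta(0.5, 0.5, 20.5)), 0.02)
  expect_lt(abs(s$median[2] - qbeta(0.5, 6.5, 4.5)), 0.03)
  expect_lt(abs(s$lo[2] - qbeta(0.05, 6.5, 4.5)), 0.03)
  expect_lt(abs(s$hi[2] - qbeta(0.95, 6.5, 4.5)), 0.03)
})

test_that("an all-missing locus is flagged and keeps the Jeffreys prior", {
  G <- matrix(c(1, 1, NA, NA), 2, 2)
  s0 <- gen_data(G)
  s1 <- gen_data(matrix(c(1, 1, 2, 0), 2, 2))
  expect_message(
    f <- est_p(s0, s1, config = quick_cfg(seed = 2)),
    "no data"
  )
  expect_equal(f$uninformative$source, 0L)
  expect_equal(f$uninformative$locus, "locus_2")
  # posterior = Beta(0.5, 0.5): median 0.5, wide interval
  i <- 2
  expect_lt(abs(f$summary$median[i] - 0.5), 0.06)
  expect_lt(f$summary$lo[i], qbeta(0.07, 0.5, 0.5))
})

test_that("point_freqs clamps extreme posterior medians", {
  # Beta(0.5, 1000.5) / Beta(1000.5, 0.5): medians beyond the clamp bounds
  s0 <- gen_data(matrix(0, 500, 1))
  s1 <- gen_data(matrix(2, 500, 1))
  f <- est_p(s0, s1, config = quick_cfg(seed = 5))
  P <- point_freqs(f)
  expect_equal(P$p0, 0.001)
  expect_equal(P$p1, 0.999)
})

test_that("certain genotype likelihoods reproduce known-genotype results", {
  g <- gen_data(matrix(c(0, 1, 2, 1, 0, 2), 3, 2))
  f1 <- est_p(g, g, config = quick_cfg(seed = 31, chains = 2))
  f2 <- est_p(as_gen_lik(g), as_gen_lik(g), config = quick_cfg(seed = 31, chains = 2))
  expect_lt(max(abs(f1$summary$median - f2$summary$median)), 0.03)
})
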