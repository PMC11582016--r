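# ancestry-class likelihood and posterior against Dirichlet oracles

test_that("q_loglik evaluates the ancestry-class mixture", {
  P <- parental_freqs(0.2, 0.8)
  g1 <- gen_data(matrix(1, 1, 1))
  # Q = (0, 1, 0), G = 1: p1(1-p0) + p0(1-p1) = 0.68
  expect_equal(q_loglik(g1, P, c(0, 1, 0)), log(0.68))
  # Q = (1, 0, 0): Hardy-Weinberg at p0
  expect_equal(q_loglik(g1, P, c(1, 0, 0)), log(2 * 0.2 * 0.8))
  g2 <- gen_data(matrix(2, 1, 1))
  expect_equal(q_loglik(g2, P, c(1, 0, 0)), log(0.2^2))
  # genotype probabilities are normalized: sum over G of each class mixture = 1
  for (Q in list(c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 0.5))) {
    tot <- sum(vapply(0:2, function(g) {
      exp(q_loglik(gen_data(matrix(g, 1, 1)), P, Q))
    }, 0))
    expect_equal(tot, 1)
  }
  expect_error(q_loglik(g1, P, c(0.5, 0.6, -0.1)), "simplex")
})

test_that("diagnostic markers give the conjugate Dirichlet posterior", {
  # genotype counts (n0, n1, n2) = (2, 5, 3) -> Dirichlet(3, 6, 4)
  g <- gen_data(matrix(c(rep(0, 2), rep(1, 5), rep(2, 3)), 1, 10))
  fit <- est_Q(g, diag_freqs(10), config = quick_cfg(seed = 19, chains = 4))
  pt <- q_point(fit)
  # marginals of Dirichlet(3, 6, 4) are Beta(a_k, 13 - a_k)
  expect_lt(abs(pt$Q00 - qbeta(0.5, 3, 10)), 0.035)
  expect_lt(abs(pt$Q10 - qbeta(0.5, 6, 7)), 0.035)
  expect_lt(abs(pt$Q11 - qbeta(0.5, 4, 9)), 0.035)
})

test_that("an individual with no data keeps the uniform simplex prior", {
  g <- gen_data(matrix(NA_real_, 1, 4))
  expect_message(
    fit <- est_Q(g, diag_freqs(4), config = quick_cfg(seed = 4)),
    "no data"
  )
  pt <- q_point(fit)
  # Dirichlet(1,1,1) marginal medians: Beta(1,2) median = 1 - sqrt(0.5)
  expect_lt(abs(pt$Q10 - (1 - sqrt(0.5))), 0.05)
})

test_that("every posterior draw lies on the simplex", {
  set.seed(2)
  g <- gen_data(matrix(rbinom(30, 2, 0.5), 3, 10))
  fit <- est_Q(g, diag_freqs(10), config = quick_cfg(seed = 8))
  arr <- fit$draws$draws
  ids <- fit$individuals
  tot <- arr[, , paste0("Q00[", ids, "]")] +
    arr[, , paste0("Q10[", ids, "]")] + arr[, , paste0("Q11[", ids, "]")]
  expect_lt(max(abs(tot - 1)), 1e-9)
})

test_that("an F1-like individual has Q10 near 1 and derived H near 0.5", {
  g <- gen_data(matrix(1, 1, 60))
  fit <- est_Q(g, diag_freqs(60), config = quick_cfg(seed = 29, chains = 4))
  expect_gt(q_point(fit)$Q10, 0.9)
  dh <- derive_H(fit)
  expect_lt(abs(hi_point(dh) - 0.5), 0.02)
  # derive_H is the per-draw identity H = Q11 + Q10/2
  arr <- fit$draws$draws
  expect_equal(
    as.vector(dh$draws$draws[, , 1]),
    as.vector(arr[, , "Q11[ind_1]"] + 0.5 * arr[, , "Q10[ind_1]"])
  )
})

test_that("haploid-only data trigger the identifiability warning", {
  g <- gen_data(matrix(c(0, 1), 1, 2), ploidy = 1)
  expect_warning(
    est_Q(g, diag_freqs(2), config = quick_cfg(seed = 5)),
    "haploid"
  )
})

test_that("est_Q and est_hi agree on simulated diagnostic data", {
  set.seed(14)
  sim <- sim_generative_clines(
    n_loci = 60, n_ind = 12, sigma_v = 0.2,
    sigma_c = 0.4, afd_min = 1, seed = 14
  )
  P <- diag_freqs(60)
  hi <- est_hi(sim$genotypes, P, config = quick_cfg(seed = 41, chains = 2))
  qf <- est_Q(sim$genotypes, P, config = quick_cfg(seed = 43, chains = 2))
  dh <- derive_H(qf)
  expect_lt(max(abs(hi_point(hi) - hi_point(dh))), 0.05)
  # triangle constraint on point estimates (with Monte-Carlo slack)
  pt <- q_point(qf)
  H <- hi_point(dh)
  expect_true(all(pt$Q10 <= 2 * pmin(H, 1 - H) + 0.08))
})
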