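# hybrid index likelihood and posterior against closed-form oracles

test_that("hi_loglik evaluates the allele-count kernel", {
  P <- parental_freqs(0.2, 0.8)
  g <- gen_data(matrix(1, 1, 1))
  # (0.5*0.8 + 0.5*0.2) * (0.5*0.2 + 0.5*0.8) = 0.25
  expect_equal(hi_loglik(g, P, H = 0.5), log(0.25))
  # identical frequencies carry no ancestry information
  P5 <- parental_freqs(0.5, 0.5)
  lls <- vapply(c(0.1, 0.4, 0.9), function(h) hi_loglik(g, P5, h), 0)
  expect_equal(diff(lls), c(0, 0))
  # near-diagnostic locus, G = N = 2 at H = 0.5: ~ 2 log(0.5) up to clamping
  Pd <- diag_freqs(1)
  g2 <- gen_data(matrix(2, 1, 1))
  expect_lt(abs(hi_loglik(g2, Pd, 0.5) - 2 * log(0.5)), 0.01)
  expect_error(hi_loglik(g, P, H = 1), "inside \\(0, 1\\)")
})

test_that("diagnostic markers give the conjugate Beta posterior for H", {
  # one individual, two diploid loci, G = (2, 1) -> Beta(0.5 + 3, 0.5 + 1)
  g <- gen_data(matrix(c(2, 1), 1, 2))
  fit <- est_hi(g, diag_freqs(2), config = quick_cfg(seed = 21, chains = 4))
  expect_lt(abs(hi_point(fit) - qbeta(0.5, 3.5, 1.5)), 0.03)
  expect_lt(abs(fit$summary$lo - qbeta(0.05, 3.5, 1.5)), 0.04)
  expect_lt(abs(fit$summary$hi - qbeta(0.95, 3.5, 1.5)), 0.04)
})

test_that("an individual with no data keeps the Jeffreys prior and is flagged", {
  g <- gen_data(matrix(c(2, NA, 1, NA), 2, 2))
  expect_message(
    fit <- est_hi(g, diag_freqs(2), config = quick_cfg(seed = 3)),
    "no informative loci"
  )
  expect_equal(fit$flagged, "ind_2")
  expect_lt(abs(fit$summary$median[2] - 0.5), 0.08)
})

test_that("adding a G = N diagnostic locus never decreases the posterior median", {
  base <- matrix(c(2, 1, 0, 1, 2), 1, 5)
  f1 <- est_hi(gen_data(base), diag_freqs(5), config = quick_cfg(seed = 13, chains = 4))
  f2 <- est_hi(
    gen_data(cbind(base, 2)), diag_freqs(6),
    config = quick_cfg(seed = 13, chains = 4)
  )
  expect_gte(hi_point(f2) + 0.01, hi_point(f1))
})

test_that("certain genotype likelihoods match known-genotype fits", {
  set.seed(6)
  g <- gen_data(matrix(rbinom(40, 2, 0.6), 4, 10))
  P <- parental_freqs(runif(10, 0, 0.3), runif(10, 0.7, 1))
  f1 <- est_hi(g, P, config = quick_cfg(seed = 17, chains = 2))
  f2 <- est_hi(as_gen_lik(g), P, config = quick_cfg(seed = 17, chains = 2))
  expect_lt(max(abs(hi_point(f1) - hi_point(f2))), 0.04)
  # and the exported log likelihoods agree up to the mixture's binomial constants
  H <- rep(0.4, 4)
  con <- sum(lchoose(g$N[!g$miss], g$G[!g$miss]))
  expect_equal(
    hi_loglik(as_gen_lik(g), P, H), hi_loglik(g, P, H) + con,
    tolerance = 1e-8
  )
})

test_that("a hybrid allele absent from both sources triggers a warning", {
  g <- gen_data(matrix(c(2, 1), 1, 2))
  P <- parental_freqs(c(0, 0), c(0, 1)) # locus 1 near-absent everywhere
  expect_warning(
    est_hi(g, P, config = quick_cfg(seed = 1)),
    "near-absent"
  )
})

test_that("mixed-ploidy data enter with single-copy kernels", {
  # haploid cell with G = 1 contributes one copy: Beta(0.5 + 3, 0.5 + 1)
  g <- gen_data(matrix(c(2, 1, 1), 1, 3), ploidy = matrix(c(2, 2, 1), 1, 3))
  fit <- est_hi(g, diag_freqs(3), config = quick_cfg(seed = 23, chains = 4))
  expect_lt(abs(hi_point(fit) - qbeta(0.5, 4.5, 1.5)), 0.04)
})
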