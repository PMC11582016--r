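# the built-in NUTS sampler checked against analytically known targets

test_that("sampler recovers a standard normal target", {
  ld <- function(q) list(value = -0.5 * sum(q^2), grad = -q)
  d <- sample_posterior(ld, n_pars = 2, config = sampler_config(seed = 42))
  x <- as.vector(d$draws[, , 1])
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(sd(x) - 1), 0.05)
  expect_equal(sum(d$divergences), 0)
})

test_that("sampler matches analytic Beta quantiles through a logit transform", {
  a <- 3.5
  b <- 1.5
  ld <- function(q) {
    p <- plogis(q)
    list(value = a * log(p) + b * log(1 - p), grad = a * (1 - p) - b * p)
  }
  d <- sample_posterior(ld,
    n_pars = 1, config = sampler_config(seed = 9),
    transform = function(m) plogis(m)
  )
  x <- as.vector(d$draws)
  for (pr in c(0.1, 0.5, 0.9)) {
    expect_lt(abs(quantile(x, pr) - qbeta(pr, a, b)), 0.02)
  }
})

test_that("sampling is exactly reproducible under a fixed seed", {
  ld <- function(q) list(value = -0.5 * sum(q^2), grad = -q)
  cfg <- sampler_config(n_chains = 2, n_iter = 600, n_warmup = 300, seed = 7)
  d1 <- sample_posterior(ld, n_pars = 3, config = cfg)
  d2 <- sample_posterior(ld, n_pars = 3, config = cfg)
  expect_identical(d1$draws, d2$draws)
})

test_that("initialization fails informatively when the density is never finite", {
  ld <- function(q) list(value = -Inf, grad = q * 0)
  expect_error(
    sample_posterior(ld, n_pars = 1, config = sampler_config(seed = 1)),
    "100 attempts"
  )
})

test_that("summaries use posterior medians and equal-tail interval quantiles", {
  mk_draws <- function(x, chains = 1) {
    arr <- array(rep(x, chains), c(length(x), chains, 1),
      dimnames = list(NULL, NULL, "theta")
    )
    structure(
      list(draws = arr, divergences = integer(chains)),
      class = "hz_draws"
    )
  }
  s <- summarize_posterior(mk_draws(1:100), ci = 0.90)
  expect_equal(s$median, 50.5)
  expect_equal(s$lo, 5.95)
  expect_equal(s$hi, 95.05)

  s2 <- summarize_posterior(mk_draws(rep(3.2, 200)))
  expect_equal(s2$median, 3.2)
  expect_equal(s2$hi - s2$lo, 0)

  s3 <- summarize_posterior(mk_draws(1:100), ci = 0.5)
  expect_equal(s3$lo, unname(quantile(1:100, 0.25)))
  expect_equal(s3$hi, unname(quantile(1:100, 0.75)))

  expect_error(summarize_posterior(mk_draws(1:50)), "100 kept draws")
})

test_that("split R-hat and ESS behave on iid and pathological chains", {
  set.seed(3)
  arr <- array(rnorm(4000), c(1000, 4, 1), dimnames = list(NULL, NULL, "x"))
  d <- structure(list(draws = arr, divergences = integer(4)), class = "hz_draws")
  diag <- compute_diagnostics(d, quiet = TRUE)
  expect_lt(abs(diag$rhat - 1), 0.02)
  expect_gt(diag$ess, 0.8 * 4000)
  expect_lt(diag$ess, 1.2 * 4000 * log10(4000))

  # disjoint chains must be detected
  arr2 <- array(c(rnorm(500), rnorm(500, 10)), c(500, 2, 1),
    dimnames = list(NULL, NULL, "x")
  )
  d2 <- structure(list(draws = arr2, divergences = integer(2)), class = "hz_draws")
  w <- capture_warnings(diag2 <- compute_diagnostics(d2))
  expect_true(any(grepl("R-hat", w))) # (its ESS also collapses, second warning)
  expect_gt(diag2$rhat, 1.5)

  # single chain: R-hat unavailable
  arr1 <- array(rnorm(500), c(500, 1, 1), dimnames = list(NULL, NULL, "x"))
  d1 <- structure(list(draws = arr1, divergences = 0L), class = "hz_draws")
  expect_message(diag1 <- compute_diagnostics(d1), "single chain")
  expect_true(is.na(diag1$rhat))
})

test_that("ESS agrees with an independent implementation on autocorrelated chains", {
  skip_if_not_installed("coda")
  set.seed(8)
  # AR(1) with known autocorrelation
  n <- 4000
  x <- as.vector(arima.sim(list(ar = 0.7), n))
  arr <- array(x, c(n, 1, 1), dimnames = list(NULL, NULL, "x"))
  d <- structure(list(draws = arr, divergences = 0L), class = "hz_draws")
  ours <- compute_diagnostics(d, quiet = TRUE)$ess
  theirs <- unname(coda::effectiveSize(coda::mcmc(x)))
  expect_lt(abs(ours - theirs) / theirs, 0.35)
  # both should be near the theoretical n (1-phi)/(1+phi)
  expect_lt(abs(ours - n * 0.3 / 1.7) / (n * 0.3 / 1.7), 0.35)
})
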