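test_that("mae is the mean absolute deviation", {
  expect_equal(mae(c(0.5, 0.5), c(0.6, 0.4)), 0.1)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(c(0, 1), c(1, 0)), 1)
  expect_error(mae(1:3, 1:2), "lengths")
})

test_that("ci_coverage counts endpoints as covered and validates bounds", {
  expect_equal(ci_coverage(c(1, 2), c(0, 0), c(3, 3)), 1)
  expect_equal(ci_coverage(0.5, 0.5, 0.9), 1) # endpoint convention
  expect_equal(ci_coverage(c(1, 10), c(0, 0), c(2, 2)), 0.5)
  expect_error(ci_coverage(1, 2, 1), "lo > hi")
})

test_that("pearson matches the textbook formula and rejects degenerate input", {
  x <- c(1, 2, 4, 7)
  y <- c(2, 3, 9, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), num / den)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("permutation test separates distinct groups and not identical ones", {
  set.seed(11)
  x <- c(rnorm(20, 2), rnorm(20, 0))
  labs <- rep(c("a", "b"), each = 20)
  res <- perm_test(x, labs, n_perm = 500, seed = 1)
  expect_lt(res$p_value, 0.01)
  x0 <- rnorm(40)
  res0 <- perm_test(x0, labs, n_perm = 500, seed = 2)
  expect_gt(res0$p_value, 0.05)
})

test_that("experiment drivers return the documented table shapes", {
  cfg <- sampler_config(n_chains = 2, n_iter = 700, n_warmup = 350, seed = 1)
  tb <- run_experiment("hi_q_recovery",
    scale = 0.2, seed = 3, config = cfg,
    afd = c(1, 0.1), gl = FALSE, capacity = 60, generations = 25, n_sample = 20
  )
  expect_tibble(tb, c("rep", "afd", "genotypes", "mae_h", "mae_q10", "cov_h", "cov_q10"))
  expect_equal(nrow(tb), 2)
  expect_true(all(tb$mae_h >= 0 & tb$mae_h <= 1))
  expect_lt(tb$mae_h[tb$afd == 1], tb$mae_h[tb$afd == 0.1])

  tb2 <- run_experiment("cline_variability",
    scale = 0.2, seed = 5, config = cfg,
    levels = tibble::tibble(level = "low", sigma_v = 0.2, sigma_c = 0.5)
  )
  expect_tibble(tb2, c("level", "sigma_v_hat", "sigma_c_hat", "cor_v", "cov_c"))

  tb3 <- run_experiment("zone_architectures",
    scale = 1 / 3, seed = 7, config = cfg,
    archs = "oligogenic", generations = 60, n_sample = 30
  )
  expect_tibble(tb3, c("arch", "cor_logv_dist", "sigma_v_hat"))
  expect_error(run_experiment("nope"), "arg")
})

test_that("tidiers and plots expose fits as tibbles and ggplots", {
  sim <- sim_generative_clines(15, 10, 0.3, 0.6, afd_min = 1, seed = 90)
  cfg <- quick_cfg(seed = 91)
  hi <- est_hi(sim$genotypes, diag_freqs(15), config = cfg)
  expect_tibble(tidy(hi), c("individual", "H", "lo", "hi", "ess", "rhat"))
  expect_tibble(glance(hi), c("n_individuals", "n_divergent", "max_rhat"))
  qf <- est_Q(sim$genotypes, diag_freqs(15), config = cfg)
  expect_tibble(tidy(qf), c("individual", "class", "median"))
  cl <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "hierarchical", config = cfg
  )
  expect_tibble(tidy(cl), c("locus", "v", "c", "log10_v", "logit_c"))
  expect_s3_class(ggplot2::autoplot(hi), "ggplot")
  expect_s3_class(ggplot2::autoplot(qf), "ggplot")
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
})
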