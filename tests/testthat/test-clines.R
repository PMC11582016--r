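# the logit-logistic cline function, cline likelihood, hierarchical fit,
# sum-to-zero constraint and outlier flags

test_that("phi satisfies its algebraic identities", {
  h <- seq(0.05, 0.95, by = 0.05)
  # null cline is the identity
  expect_equal(phi(h, 1, 0.5), h)
  # the center is where phi = 0.5, for any slope
  for (v in c(0.3, 1, 2, 8)) {
    for (cc in c(0.1, 0.5, 0.9)) expect_equal(phi(cc, v, cc), 0.5)
  }
  # strictly increasing in h
  expect_true(all(diff(phi(h, 2.5, 0.3)) > 0))
  # label-swap symmetry: phi(1-h, v, 1-c) = 1 - phi(h, v, c)
  expect_equal(phi(1 - h, 1.7, 1 - 0.25), 1 - phi(h, 1.7, 0.25))
  # exact endpoints
  expect_equal(phi(c(0, 1), 3, 0.4), c(0, 1))
  # direct evaluation oracle
  expect_equal(phi(0.7, 2, 0.3), 0.9674, tolerance = 1e-4)
  expect_error(phi(0.5, -1, 0.5), "positive")
})

test_that("cline likelihood reduces to the hybrid index likelihood at the null cline", {
  set.seed(31)
  g <- gen_data(matrix(rbinom(50, 2, 0.5), 5, 10))
  P <- parental_freqs(runif(10, 0, 0.4), runif(10, 0.6, 1))
  H <- runif(5, 0.05, 0.95)
  expect_equal(
    cline_loglik(g, P, H, v = rep(1, 10), c = rep(0.5, 10)),
    hi_loglik(g, P, H)
  )
  # kernels: ancestry mode with phi = 0.5, Z = 1, N = 2 -> 0.25
  z <- ancestry_data(matrix(1, 1, 1))
  expect_equal(cline_loglik(z, H = 0.5, v = 1, c = 0.5), log(0.25))
  # genotype mode, P0 = 0.2, P1 = 0.8, G = 1 at phi = 0.5 -> 0.25
  g1 <- gen_data(matrix(1, 1, 1))
  expect_equal(
    cline_loglik(g1, parental_freqs(0.2, 0.8), H = 0.5, v = 1, c = 0.5),
    log(0.25)
  )
})

test_that("hybrid indexes of exactly 0 or 1 are nudged with a warning", {
  g <- gen_data(matrix(c(0, 2), 2, 1))
  expect_warning(
    cline_loglik(g, diag_freqs(1), H = c(0, 1), v = 1, c = 0.5),
    "nudged"
  )
})

test_that("null data produce small cline SDs and no credible outliers", {
  set.seed(5)
  n <- 40
  L <- 40
  H <- runif(n, 0.02, 0.98)
  Z <- matrix(rbinom(n * L, 2, H), n, L) # v = 1, c = 0.5 for every locus
  g <- gen_data(Z)
  fit <- est_gencline(g, diag_freqs(L), H,
    mode = "hierarchical",
    config = quick_cfg(seed = 37, chains = 2)
  )
  sds <- cline_sds(fit)
  expect_lt(sds[["sigma_v"]], 0.15)
  expect_lt(sds[["sigma_c"]], 0.4)
  flags <- flag_outliers(fit)
  expect_lt(mean(flags$v_flag != "none"), 0.1)
  expect_lt(mean(flags$c_flag != "none"), 0.15)
})

test_that("fixed-SD fits agree with the hierarchical fit they are anchored to", {
  sim <- sim_generative_clines(40, 30, 0.3, 0.6, afd_min = 1, seed = 71)
  hier <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "hierarchical", config = quick_cfg(seed = 53, chains = 2)
  )
  sds <- cline_sds(hier)
  fixed <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "fixed_sd", sigma_v = sds[["sigma_v"]], sigma_c = sds[["sigma_c"]],
    config = quick_cfg(seed = 59, chains = 2)
  )
  expect_lt(
    max(abs(log10(cline_point(hier)$v) - log10(cline_point(fixed)$v))), 0.05
  )
  expect_error(
    est_gencline(sim$genotypes, sim$freqs, sim$truth$H, mode = "fixed_sd"),
    "positive sigma"
  )
})

test_that("the hierarchical prior shrinks slopes relative to a flat-prior fit", {
  sim <- sim_generative_clines(40, 30, 0.3, 0.6, afd_min = 1, seed = 73)
  hier <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "hierarchical", config = quick_cfg(seed = 61, chains = 2)
  )
  flat <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "fixed_sd", sigma_v = 100, sigma_c = 100,
    config = quick_cfg(seed = 67, chains = 2)
  )
  expect_lt(
    mean(abs(log10(cline_point(hier)$v))),
    mean(abs(log10(cline_point(flat)$v)))
  )
})

test_that("ancestry mode matches genotype mode at clamped diagnostic frequencies", {
  sim <- sim_generative_clines(30, 30, 0.3, 0.6, afd_min = 1, seed = 79)
  ga <- est_gencline(sim$ancestry,
    H = sim$truth$H, mode = "hierarchical",
    config = quick_cfg(seed = 83, chains = 2)
  )
  gg <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "hierarchical", config = quick_cfg(seed = 83, chains = 2)
  )
  expect_lt(mean(abs(log10(cline_point(ga)$v) - log10(cline_point(gg)$v))), 0.05)
  expect_lt(mean(abs(cline_point(ga)$c - cline_point(gg)$c)), 0.03)
})

test_that("free-means mode recovers a nonzero hierarchical mean", {
  set.seed(91)
  L <- 50
  n <- 60
  v <- 10^rnorm(L, 0.3, 0.15) # mu_v = 0.3 on the log10 scale
  cc <- plogis(rnorm(L, 0, 0.4))
  H <- runif(n, 0.02, 0.98)
  ph <- plogis(sweep(outer(qlogis(H), v), 2, v * qlogis(cc)))
  z <- ancestry_data(matrix(rbinom(n * L, 2, ph), n, L))
  fit <- est_gencline(z,
    H = H, mode = "free_means",
    config = quick_cfg(seed = 97, chains = 2)
  )
  mu_v <- fit$summary[fit$summary$param == "mu_v", ]
  expect_lt(abs(mu_v$median - 0.3), 0.12)
  expect_true(mu_v$lo > 0) # credibly above zero
})

test_that("sum2zero centers every posterior iteration exactly and is idempotent", {
  sim <- sim_generative_clines(20, 20, 0.4, 0.8, afd_min = 1, seed = 101)
  fit <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
    mode = "hierarchical", config = quick_cfg(seed = 103, chains = 2)
  )
  cen <- sum2zero(fit, mode = "full")
  vn <- paste0("v[", cen$loci, "]")
  cn <- paste0("c[", cen$loci, "]")
  mlv <- apply(log10(cen$draws$draws[, , vn]), c(1, 2), mean)
  mth <- apply(qlogis(cen$draws$draws[, , cn]), c(1, 2), mean)
  expect_lt(max(abs(mlv)), 1e-12)
  expect_lt(max(abs(mth)), 1e-12)
  cen2 <- sum2zero(cen, mode = "full")
  expect_equal(cen2$summary$median, cen$summary$median, tolerance = 1e-12)
})

test_that("point-mode sum2zero shifts point estimates by the across-locus mean", {
  fake <- structure(
    list(
      summary = tibble::tibble(
        param = c("v[a]", "v[b]", "c[a]", "c[b]"),
        median = c(10^0.2, 10^0.4, 0.5, 0.5),
        lo = c(10^0.1, 10^0.3, 0.4, 0.4),
        hi = c(10^0.3, 10^0.5, 0.6, 0.6),
        ess = 1000, rhat = 1
      ),
      loci = c("a", "b"), mode = "fixed_sd", fixed = c(sigma_v = 1, sigma_c = 1),
      ci = 0.9, centered = FALSE, draws = NULL
    ),
    class = "hz_cline_fit"
  )
  cen <- sum2zero(fake, mode = "point")
  expect_equal(log10(cline_point(cen)$v), c(-0.1, 0.1))
  expect_equal(cline_point(cen)$c, c(0.5, 0.5))
})

test_that("flag_outliers applies the credible-interval rules", {
  fake <- structure(
    list(
      summary = tibble::tibble(
        param = c("v[a]", "v[b]", "v[c]", "c[a]", "c[b]", "c[c]"),
        median = c(1.5, 0.6, 1.0, 0.5, 0.7, 0.3),
        lo = c(1.2, 0.4, 0.8, 0.3, 0.55, 0.1),
        hi = c(1.8, 0.8, 1.3, 0.7, 0.9, 0.45),
        ess = 1000, rhat = 1
      ),
      loci = c("a", "b", "c"), mode = "fixed_sd",
      fixed = c(sigma_v = 1, sigma_c = 1), ci = 0.9, centered = FALSE,
      draws = NULL
    ),
    class = "hz_cline_fit"
  )
  flags <- flag_outliers(fake)
  expect_equal(flags$v_flag, c("steep", "shallow", "none"))
  expect_equal(flags$c_flag, c("none", "excess_source0", "excess_source1"))
})

test_that("hierarchical modes refuse single-locus data", {
  g <- gen_data(matrix(c(1, 2), 2, 1))
  expect_error(
    est_gencline(g, diag_freqs(1), c(0.4, 0.6), mode = "hierarchical"),
    "at least 2 loci"
  )
})

test_that("the batched workflow reproduces one-shot fixed-SD estimates", {
  sim <- sim_generative_clines(40, 25, 0.3, 0.6, afd_min = 1, seed = 107)
  bat <- est_gencline_batched(sim$genotypes, sim$freqs, sim$truth$H,
    n_subset = 20, batch_size = 15,
    config = quick_cfg(seed = 109, chains = 2), recenter = TRUE
  )
  expect_equal(bat$mode, "batched_fixed_sd")
  expect_equal(nrow(bat$summary), 80)
  # point-mode recentering leaves across-locus means at zero
  pt <- cline_point(bat)
  expect_lt(abs(mean(log10(pt$v))), 1e-9)
  expect_lt(abs(mean(qlogis(pt$c))), 1e-9)
})
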