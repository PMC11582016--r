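# shared fixtures and a fast sampler configuration for unit tests
quick_cfg <- function(seed = 1, chains = 2) {
  sampler_config(
    n_chains = chains, n_iter = 1200, n_warmup = 600, seed = seed
  )
}

# diagnostic (fixed-difference) parental frequencies, clamped on construction
diag_freqs <- function(L) parental_freqs(rep(0, L), rep(1, L))

# small genotype matrix fixture
small_gen <- function() {
  gen_data(
    matrix(c(0, 1, 2, NA, 1, 0), 2, 3),
    individuals = c("a", "b"), loci = c("l1", "l2", "l3")
  )
}

expect_tibble <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% colnames(x)))
}
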