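#' Run a packaged simulation experiment
#'
#' End-to-end drivers for the package's method-evaluation designs. Each
#' preset simulates data with the package's own simulators, fits the
#' corresponding models, and reports recovery metrics per replicate.
#'
#' Presets:
#' * `"hi_q_recovery"`: neutral single-deme secondary contact (200
#'   generations, capacity 500, parental migration 0.1, 510 loci on ten
#'   1-Morgan chromosomes, 50 sampled individuals); genotypes sampled at
#'   parental allele-frequency differences 1, 0.5, 0.1, with and without
#'   read-based genotype likelihoods (Poisson depth 7, 1% error); hybrid
#'   index and ancestry-class fits; MAE and 90% CI coverage.
#' * `"cline_variability"`: generative cline simulations (100 diagnostic
#'   loci, 50 hybrids) at low (0.2, 0.5), moderate (0.4, 0.8) and high
#'   (0.6, 1.2) `(sigma_v, sigma_c)`; hierarchical cline fits with known
#'   hybrid indexes; SD recovery, per-locus MAE/correlation/coverage.
#' * `"afd_gl_effects"`: generative simulations at `sigma_v = 0.3`,
#'   `sigma_c = 0.7` with minimum allele-frequency differences 1, 0.5, 0.1,
#'   known genotypes vs genotype likelihoods; hierarchical cline fits.
#' * `"zone_architectures"`: stepping-stone hybrid zones (15 demes,
#'   capacity 100, neighbor migration 0.05, 251 markers on one 1-Morgan
#'   chromosome) under neutrality, oligogenic underdominance (2 loci,
#'   s = 0.3 at 25 and 75 cM), and weak/strong polygenic underdominance
#'   (50 loci, s = 0.005 / 0.01); hierarchical cline fits on ancestry of
#'   100 sampled individuals; correlation of log cline slope with map
#'   distance to the nearest selected locus.
#'
#' @param preset One of the preset names above.
#' @param scale Replicate multiplier applied to the preset's base replicate
#'   count (base: 5, 5, 5, 3 respectively).
#' @param seed Integer seed governing all simulation and fitting randomness.
#' @param config A [sampler_config()]; its seed is overridden
#'   deterministically per fit.
#' @param ... Preset-specific overrides: `afd` / `gl` (hi_q_recovery,
#'   afd_gl_effects), `levels` (cline_variability), `archs`, `generations`,
#'   `n_sample` (zone_architectures).
#' @return A tibble of per-replicate, per-condition results.
#' @export
run_experiment <- function(preset = c(
                             "hi_q_recovery", "cline_variability",
                             "afd_gl_effects", "zone_architectures"
                           ),
                           scale = 1, seed = 1,
                           config = sampler_config(), ...) {
  preset <- match.arg(preset)
  driver <- switch(preset,
    hi_q_recovery = exp_hi_q_recovery,
    cline_variability = exp_cline_variability,
    afd_gl_effects = exp_afd_gl_effects,
    zone_architectures = exp_zone_architectures
  )
  base_reps <- c(
    hi_q_recovery = 5, cline_variability = 5,
    afd_gl_effects = 5, zone_architectures = 3
  )[[preset]]
  n_rep <- max(1L, as.integer(round(base_reps * scale)))
  driver(n_rep = n_rep, seed = as.integer(seed), config = config, ...)
}

cfg_seed <- function(config, s) {
  config$seed <- as.integer(abs(s) %% 2000000000)
  config
}

exp_hi_q_recovery <- function(n_rep, seed, config,
                              afd = c(1, 0.5, 0.1), gl = c(FALSE, TRUE),
                              capacity = 500, generations = 200,
                              n_sample = 50) {
  grid <- tidyr::expand_grid(rep = seq_len(n_rep), afd = afd, gl = gl)
  purrr::pmap_dfr(grid, function(rep, afd, gl) {
    zone_seed <- seed + 1009 * rep
    zone <- sim_zone(
      n_demes = 1, capacity = capacity, migration = 0.1,
      generations = generations, n_chrom = 10, chrom_length = 1,
      markers_per_chrom = 51, s = 0, n_sample = n_sample, seed = zone_seed
    )
    cond <- round(100 * afd) * 2 + gl
    P <- parental_freqs(
      rep(0.5 - afd / 2, 510), rep(0.5 + afd / 2, 510),
      loci = zone$ancestry$loci
    )
    G <- genotypes_from_ancestry(zone$ancestry, 0.5 - afd / 2, 0.5 + afd / 2,
      seed = zone_seed + cond
    )
    dat <- if (gl) sim_reads(G, 7, 0.01, seed = zone_seed + cond + 1) else G
    hi <- est_hi(dat, P, config = cfg_seed(config, zone_seed + cond + 2))
    qf <- est_Q(dat, P, config = cfg_seed(config, zone_seed + cond + 3))
    q10 <- q_point(qf)$Q10
    qs <- qf$summary
    qi <- grepl("^Q10\\[", qs$param)
    tibble::tibble(
      rep = rep, afd = afd, genotypes = ifelse(gl, "likelihood", "known"),
      mae_h = mae(zone$truth$H, hi_point(hi)),
      mae_q10 = mae(zone$truth$Q10, q10),
      cov_h = ci_coverage(zone$truth$H, hi$summary$lo, hi$summary$hi),
      cov_q10 = ci_coverage(zone$truth$Q10, qs$lo[qi], qs$hi[qi]),
      seed = zone_seed
    )
  })
}

variability_levels <- function() {
  tibble::tibble(
    level = c("low", "moderate", "high"),
    sigma_v = c(0.2, 0.4, 0.6),
    sigma_c = c(0.5, 0.8, 1.2)
  )
}

exp_cline_variability <- function(n_rep, seed, config,
                                  levels = variability_levels()) {
  grid <- tidyr::expand_grid(rep = seq_len(n_rep), idx = seq_len(nrow(levels)))
  purrr::pmap_dfr(grid, function(rep, idx) {
    lv <- levels[idx, ]
    sim_seed <- seed + 2003 * rep + 97 * idx
    sim <- sim_generative_clines(
      n_loci = 100, n_ind = 50, sigma_v = lv$sigma_v, sigma_c = lv$sigma_c,
      afd_min = 1, seed = sim_seed
    )
    fit <- est_gencline(sim$genotypes, sim$freqs, sim$truth$H,
      mode = "hierarchical", sigma0 = 2,
      config = cfg_seed(config, sim_seed + 1)
    )
    cline_recovery_row(fit, sim,
      tibble::tibble(
        rep = rep, level = lv$level,
        sigma_v_true = lv$sigma_v, sigma_c_true = lv$sigma_c, seed = sim_seed
      )
    )
  })
}

exp_afd_gl_effects <- function(n_rep, seed, config,
                               afd = c(1, 0.5, 0.1), gl = c(FALSE, TRUE),
                               sigma_v = 0.3, sigma_c = 0.7) {
  grid <- tidyr::expand_grid(rep = seq_len(n_rep), afd = afd, gl = gl)
  purrr::pmap_dfr(grid, function(rep, afd, gl) {
    sim_seed <- seed + 3001 * rep + round(1000 * afd) + gl
    sim <- sim_generative_clines(
      n_loci = 100, n_ind = 50, sigma_v = sigma_v, sigma_c = sigma_c,
      afd_min = afd, seed = sim_seed
    )
    dat <- if (gl) {
      sim_reads(sim$genotypes, 7, 0.01, seed = sim_seed + 7)
    } else {
      sim$genotypes
    }
    fit <- est_gencline(dat, sim$freqs, sim$truth$H,
      mode = "hierarchical", sigma0 = 2,
      config = cfg_seed(config, sim_seed + 11)
    )
    cline_recovery_row(fit, sim,
      tibble::tibble(
        rep = rep, afd_min = afd,
        genotypes = ifelse(gl, "likelihood", "known"),
        sigma_v_true = sigma_v, sigma_c_true = sigma_c, seed = sim_seed
      )
    )
  })
}

cline_recovery_row <- function(fit, sim, front) {
  pt <- cline_point(fit)
  sds <- cline_sds(fit)
  dplyr::bind_cols(
    front,
    tibble::tibble(
      sigma_v_hat = sds[["sigma_v"]], sigma_c_hat = sds[["sigma_c"]],
      mae_v = mae(sim$truth$v, pt$v),
      mae_c = mae(sim$truth$c, pt$c),
      cor_v = pearson(sim$truth$v, pt$v),
      cor_c = pearson(sim$truth$c, pt$c),
      cov_v = ci_coverage(sim$truth$v, pt$v_lo, pt$v_hi),
      cov_c = ci_coverage(sim$truth$c, pt$c_lo, pt$c_hi)
    )
  )
}

zone_arch_params <- function(arch) {
  poly_pos <- seq(0.01, 0.99, length.out = 50)
  switch(arch,
    neutral = list(sel_pos = numeric(0), s = 0, dist_pos = poly_pos),
    oligogenic = list(sel_pos = c(0.25, 0.75), s = 0.3, dist_pos = NULL),
    polygenic_weak = list(sel_pos = poly_pos, s = 0.005, dist_pos = NULL),
    polygenic_strong = list(sel_pos = poly_pos, s = 0.01, dist_pos = NULL),
    stop("unknown architecture: ", arch)
  )
}

exp_zone_architectures <- function(n_rep, seed, config,
                                   archs = c(
                                     "neutral", "oligogenic",
                                     "polygenic_weak", "polygenic_strong"
                                   ),
                                   generations = 5000, n_sample = 100) {
  grid <- tidyr::expand_grid(rep = seq_len(n_rep), arch = archs)
  purrr::pmap_dfr(grid, function(rep, arch) {
    pars <- zone_arch_params(arch)
    sim_seed <- seed + 5003 * rep + sum(utf8ToInt(arch))
    zone <- sim_zone(
      n_demes = 15, capacity = 100, migration = 0.05,
      generations = generations, n_chrom = 1, chrom_length = 1,
      markers_per_chrom = 251, sel_pos = pars$sel_pos, s = pars$s,
      n_sample = n_sample, seed = sim_seed
    )
    H <- zone$truth$H
    keep <- H > 0 & H < 1 # pure parentals carry no cline information
    anc <- subset_individuals(zone$ancestry, keep)
    fit <- est_gencline(anc,
      H = H[keep], mode = "hierarchical", sigma0 = 2,
      config = cfg_seed(config, sim_seed + 13)
    )
    pt <- cline_point(fit)
    sds <- cline_sds(fit)
    # distance (cM) from each marker to the nearest underdominant locus;
    # for neutral zones, to the positions used in the polygenic designs
    dist <- if (is.null(pars$dist_pos)) {
      zone$map$dist_sel * 100
    } else {
      vapply(zone$map$pos, function(x) min(abs(pars$dist_pos - x)), 0) * 100
    }
    flags <- flag_outliers(fit)
    tibble::tibble(
      rep = rep, arch = arch,
      cor_logv_dist = pearson(log(pt$v), dist),
      sigma_v_hat = sds[["sigma_v"]], sigma_c_hat = sds[["sigma_c"]],
      n_steep = sum(flags$v_flag == "steep"),
      n_center_outlier = sum(flags$c_flag != "none"),
      n_analyzed = sum(keep), seed = sim_seed
    )
  })
}

subset_individuals <- function(data, keep) {
  out <- data
  for (f in intersect(names(data), c("G", "N", "miss", "L0", "L1", "L2"))) {
    out[[f]] <- data[[f]][keep, , drop = FALSE]
  }
  out$individuals <- data$individuals[keep]
  out
}
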