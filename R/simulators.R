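#' Simulate hybrids from the generative logit-logistic cline model
#'
#' Draws per-locus cline parameters `log10(v) ~ N(0, sigma_v)` and
#' `logit(c) ~ N(0, sigma_c)`, per-individual hybrid indexes `H ~ U(0, 1)`,
#' computes the cline probabilities `phi`, and samples diploid local ancestry
#' `Z ~ Binomial(2, phi)`. Per-locus allele-frequency differences are drawn
#' uniformly between `afd_min` and 1 and centered symmetrically about 0.5
#' (`p0 = 0.5 - afd/2`, `p1 = 0.5 + afd/2`); genotypes are then sampled from
#' ancestry and frequencies. With `afd_min = 1` all loci are diagnostic and
#' the genotypes equal the ancestry.
#'
#' @param n_loci,n_ind Numbers of loci and admixed individuals.
#' @param sigma_v,sigma_c Standard deviations of `log10(v)` and `logit(c)`
#'   across loci (genome-wide cline variability).
#' @param afd_min Minimum parental allele-frequency difference, in (0, 1].
#' @param seed Integer seed.
#' @return A list with elements `truth` (list: `H`, `v`, `c`, `sigma_v`,
#'   `sigma_c`, `Z`, `Q10`), `ancestry` ([ancestry_data()]), `genotypes`
#'   ([gen_data()]), and `freqs` ([parental_freqs()], unclamped values in
#'   `truth$p0`, `truth$p1`).
#' @export
sim_generative_clines <- function(n_loci = 100, n_ind = 50, sigma_v = 0.3,
                                  sigma_c = 0.7, afd_min = 1, seed = NULL) {
  stopifnot(sigma_v >= 0, sigma_c >= 0, afd_min > 0, afd_min <= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- 10^rnorm(n_loci, 0, sigma_v)
  cc <- plogis(rnorm(n_loci, 0, sigma_c))
  H <- runif(n_ind)
  ph <- plogis(sweep(outer(qlogis(H), v), 2, v * qlogis(cc)))
  Z <- matrix(rbinom(n_ind * n_loci, 2, ph), n_ind, n_loci)
  afd <- if (afd_min >= 1) rep(1, n_loci) else runif(n_loci, afd_min, 1)
  p0 <- 0.5 - afd / 2
  p1 <- 0.5 + afd / 2
  anc <- ancestry_data(Z, ploidy = 2)
  G <- genotypes_from_ancestry(anc, p0, p1)
  list(
    truth = list(
      H = H, v = v, c = cc, sigma_v = sigma_v, sigma_c = sigma_c,
      Z = Z, Q10 = rowMeans(Z == 1), p0 = p0, p1 = p1
    ),
    ancestry = anc,
    genotypes = G,
    freqs = parental_freqs(p0, p1, loci = anc$loci)
  )
}

#' Sample genotypes from local ancestry and parental frequencies
#'
#' Each gene copy draws its allele independently: Bernoulli(`p1`) for copies
#' with source-1 ancestry and Bernoulli(`p0`) otherwise. With `p0 = 0`,
#' `p1 = 1` the genotypes equal the ancestry exactly.
#'
#' @param Z An [ancestry_data()] object (or integer matrix of ancestry copy
#'   counts).
#' @param p0,p1 Allele frequencies in sources 0 and 1; scalars or per-locus
#'   vectors.
#' @param seed Optional integer seed.
#' @return A [gen_data()] object.
#' @export
genotypes_from_ancestry <- function(Z, p0, p1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(Z, "gen_data")) Z <- ancestry_data(as.matrix(Z))
  stopifnot(all(p0 >= 0 & p0 <= 1), all(p1 >= 0 & p1 <= 1))
  n <- n_ind(Z)
  L <- n_loci_of(Z)
  P0 <- matrix(rep(rep_len(p0, L), each = n), n, L)
  P1 <- matrix(rep(rep_len(p1, L), each = n), n, L)
  Zm <- zeroed(Z$G, Z$miss)
  G <- matrix(
    rbinom(n * L, Zm, P1) + rbinom(n * L, Z$N - Zm, P0), n, L
  )
  G[Z$miss] <- NA
  gen_data(G, ploidy = Z$N, individuals = Z$individuals, loci = Z$loci)
}

#' Simulate read-based genotype likelihoods
#'
#' Emulates low-coverage sequencing: per cell the read depth is
#' Poisson(`depth_lambda`); each read reports the counted allele with
#' probability `(G/N)(1 - e) + (1 - G/N) e` where `e` is the per-read error
#' rate; genotype likelihoods are computed from the read counts under the
#' same error model. Zero-depth (and originally missing) cells become
#' equal-likelihood vectors.
#'
#' @param G A [gen_data()] object of true genotypes.
#' @param depth_lambda Mean read depth.
#' @param error_rate Per-read error rate, in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return A [gen_lik()] object.
#' @export
sim_reads <- function(G, depth_lambda = 7, error_rate = 0.01, seed = NULL) {
  stopifnot(inherits(G, "gen_data"), depth_lambda > 0,
    error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  n <- n_ind(G)
  L <- n_loci_of(G)
  depth <- matrix(rpois(n * L, depth_lambda), n, L)
  depth[G$miss] <- 0
  p_alt <- (zeroed(G$G, G$miss) / G$N) * (1 - error_rate) +
    (1 - zeroed(G$G, G$miss) / G$N) * error_rate
  k <- matrix(rbinom(n * L, depth, p_alt), n, L)
  lik <- array(0, c(n, L, 3))
  for (g in 0:2) {
    pg <- (g / G$N) * (1 - error_rate) + (1 - g / G$N) * error_rate
    lik[, , g + 1] <- ifelse(g <= G$N, dbinom(k, depth, pg), 0)
  }
  # zero depth carries no information
  for (g in 0:2) {
    slice <- lik[, , g + 1]
    slice[depth == 0] <- ifelse(g <= G$N, 1, 0)[depth == 0]
    lik[, , g + 1] <- slice
  }
  gen_lik(lik, ploidy = G$N, individuals = G$individuals, loci = G$loci)
}

#' Individual-based secondary-contact hybrid zone simulation
#'
#' Forward-in-time simulation of diploid hermaphrodites in one admixed deme
#' (fed by migrants from both parental populations) or a stepping-stone
#' chain of demes (neighbor migration, pure parental populations beyond the
#' edges). Haplotypes are ancestry (0/1) sequences tracked at an even marker
#' grid along each chromosome; gametes form with Poisson(map length)
#' crossovers at uniform positions. Hybrid fitness is underdominant:
#' offspring survive with probability `w = (1 - s)^n` where `n` counts
#' ancestry-heterozygous selected loci. Generations iterate migration,
#' random mating within deme (distinct parents), offspring viability, and
#' population regulation to a fixed capacity.
#'
#' @param n_demes Number of hybrid-zone demes (1 = single admixed deme).
#' @param capacity Adults per deme.
#' @param migration For a single deme, the total migration rate from the
#'   parental populations (split equally between sources); otherwise the
#'   migration rate between neighboring demes (applied per neighbor).
#' @param generations Generations after secondary contact.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Map length per chromosome, Morgans.
#' @param markers_per_chrom Evenly spaced marker loci per chromosome.
#' @param sel_pos Map positions (Morgans) of underdominant loci.
#' @param sel_chrom Chromosome (1-based) of each selected locus.
#' @param s Selection coefficient per underdominant locus.
#' @param n_sample Optionally subsample this many individuals at random.
#' @param seed Integer seed.
#' @return A list with `ancestry` ([ancestry_data()] at the marker loci),
#'   `truth` (list: `H`, `Q10` per individual), `deme` (integer vector),
#'   and `map` (tibble: `chrom`, `pos`, and `dist_sel`, the map distance to
#'   the nearest selected locus, when selection is present).
#' @export
sim_zone <- function(n_demes = 1, capacity = 500, migration = 0.1,
                     generations = 200, n_chrom = 10, chrom_length = 1,
                     markers_per_chrom = 51, sel_pos = numeric(0),
                     sel_chrom = integer(0), s = 0, n_sample = NULL,
                     seed = NULL) {
  stopifnot(
    migration >= 0, migration <= 0.5, s >= 0,
    length(sel_pos) == length(sel_chrom) ||
      (length(sel_chrom) == 0 && n_chrom == 1)
  )
  if (length(sel_pos) > 0 && length(sel_chrom) == 0) {
    sel_chrom <- rep(1L, length(sel_pos))
  }
  if (any(sel_pos < 0 | sel_pos > chrom_length)) {
    stop("selected positions must lie within the map length")
  }
  seed <- seed %||% sample.int(.Machine$integer.max, 1)
  mpos <- seq(0, chrom_length, length.out = markers_per_chrom)
  res <- hz_sim_zone(
    as.integer(n_demes), as.integer(capacity),
    mig_parental = if (n_demes == 1) migration else 0,
    mig_neighbor = if (n_demes > 1) migration else 0,
    as.integer(generations), as.integer(n_chrom), chrom_length,
    mpos, as.integer(sel_chrom - 1L), sel_pos, s, seed
  )
  Z <- res$Z
  deme <- res$deme
  if (!is.null(n_sample) && n_sample < nrow(Z)) {
    set.seed(seed + 1L)
    idx <- sort(sample.int(nrow(Z), n_sample))
    Z <- Z[idx, , drop = FALSE]
    deme <- deme[idx]
  }
  map <- tibble::tibble(
    chrom = rep(seq_len(n_chrom), each = markers_per_chrom),
    pos = rep(mpos, n_chrom)
  )
  if (length(sel_pos) > 0) {
    map$dist_sel <- purrr::map2_dbl(map$chrom, map$pos, function(ch, x) {
      same <- sel_chrom == ch
      if (!any(same)) return(NA_real_)
      min(abs(sel_pos[same] - x))
    })
  }
  loci <- paste0("c", map$chrom, "_m", rep(seq_len(markers_per_chrom), n_chrom))
  anc <- ancestry_data(Z,
    ploidy = 2,
    individuals = paste0("ind_", seq_len(nrow(Z))), loci = loci
  )
  list(
    ancestry = anc,
    truth = list(H = rowMeans(Z) / 2, Q10 = rowMeans(Z == 1)),
    deme = deme,
    map = map
  )
}

#' Underdominant fitness of an ancestry-heterozygous genotype
#'
#' `w = (1 - s)^n` for an individual heterozygous for ancestry at `n`
#' selected loci: e.g., two loci with `s = 0.3` give 0.49; fifty loci with
#' `s = 0.005` give about 0.78 and with `s = 0.01` about 0.61 for a fully
#' heterozygous (F1) individual.
#'
#' @param n_het Number of ancestry-heterozygous selected loci.
#' @param s Selection coefficient per locus.
#' @return Relative fitness in (0, 1].
#' @export
underdominant_fitness <- function(n_het, s) (1 - s)^n_het
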