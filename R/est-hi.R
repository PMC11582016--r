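#' Hybrid index log likelihood
#'
#' Log likelihood of hybrid indexes `H` given genetic data and parental
#' allele frequencies: the probability that a sampled allele copy is the
#' counted allele is `H p1 + (1 - H) p0` per locus, and allele counts are
#' binomial in that probability (the binomial coefficient, constant in `H`,
#' is omitted). With genotype likelihoods the per-genotype likelihood is
#' averaged over states weighted by the likelihood vector; with local
#' ancestry the kernel is `H^Z (1 - H)^(N - Z)`. Loci with identical source
#' frequencies contribute a constant: they carry no ancestry information.
#'
#' @param data A [gen_data()], [gen_lik()] or [ancestry_data()] object.
#' @param P A [parental_freqs()] object (ignored for ancestry data).
#' @param H Numeric vector of hybrid indexes in (0, 1), one per individual.
#' @return Scalar log likelihood.
#' @export
hi_loglik <- function(data, P = NULL, H) {
  if (any(H <= 0) || any(H >= 1)) stop("H must lie strictly inside (0, 1)")
  stopifnot(length(H) == n_ind(data))
  pp <- effective_freqs(data, P)
  p <- outer(H, pp$p1 - pp$p0) + rep(pp$p0, each = length(H))
  data_loglik(data, p)
}

#' Estimate hybrid indexes
#'
#' Posterior inference of the per-individual hybrid index `H` (proportion of
#' the genome inherited from source population 1) with a Jeffreys
#' Beta(0.5, 0.5) prior. Individuals are conditionally independent given the
#' parental allele frequencies and are sampled jointly in one vectorized
#' model. Works with known genotypes, genotype likelihoods, or local
#' ancestry.
#'
#' @inheritParams hi_loglik
#' @param config A [sampler_config()].
#' @param ci Credible-interval mass for summaries.
#' @return An object of class `hz_hi_fit` with posterior `draws` (parameters
#'   `H[id]`), a `summary` tibble, and `flagged` individuals with no
#'   informative loci (posterior approximately equals the prior).
#' @export
est_hi <- function(data, P = NULL, config = sampler_config(), ci = 0.90) {
  pp <- effective_freqs(data, P)
  check_impossible_alleles(data, pp)
  ids <- data$individuals
  spec <- hi_spec(data, pp)
  transform <- function(m) {
    out <- plogis(m)
    colnames(out) <- paste0("H[", ids, "]")
    out
  }
  fit <- fit_nuts(spec, n_ind(data), config, transform = transform)
  informative <- abs(pp$p1 - pp$p0) > 1e-9
  flagged <- ids[rowSums(!data$miss[, informative, drop = FALSE]) == 0]
  if (length(flagged) > 0) {
    message(sprintf(
      "%d individual(s) with no informative loci: posterior equals the prior",
      length(flagged)
    ))
  }
  s <- summarize_posterior(fit, ci)
  new_hi_fit(fit, s, ids, flagged, ci)
}

new_hi_fit <- function(draws, summary, ids, flagged = character(), ci = 0.90,
                       derived = FALSE) {
  structure(
    list(
      draws = draws, summary = summary, individuals = ids,
      flagged = flagged, ci = ci, derived = derived
    ),
    class = "hz_hi_fit"
  )
}

#' Posterior-median hybrid indexes
#'
#' @param fit An `hz_hi_fit`.
#' @return Named numeric vector of posterior medians, one per individual.
#' @export
hi_point <- function(fit) {
  stopifnot(inherits(fit, "hz_hi_fit"))
  setNames(fit$summary$median, fit$individuals)
}

#' @export
print.hz_hi_fit <- function(x, ...) {
  cat(sprintf(
    "<hybrid index fit%s: %d individuals; median H in [%.3f, %.3f]>\n",
    if (x$derived) " (derived from ancestry classes)" else "",
    length(x$individuals), min(x$summary$median), max(x$summary$median)
  ))
  invisible(x)
}

# source frequencies entering the likelihood: clamped estimates, or exact
# 0/1 for local-ancestry data (the ancestry kernel needs no frequencies)
effective_freqs <- function(data, P) {
  if (inherits(data, "ancestry_data")) {
    return(list(p0 = rep(0, n_loci_of(data)), p1 = rep(1, n_loci_of(data))))
  }
  if (is.null(P)) stop("parental frequencies are required for genotype data")
  stopifnot(inherits(P, "parental_freqs"))
  check_loci_match(data, P)
  list(p0 = P$p0, p1 = P$p1)
}

hi_spec <- function(data, pp) {
  if (inherits(data, "gen_lik")) {
    return(list(
      type = "hi", a = 0.5, b = 0.5, N = data$N, miss = data$miss,
      P0 = pp$p0, P1 = pp$p1,
      mode = 1L, L0 = data$L0, L1 = data$L1, L2 = data$L2
    ))
  }
  # known genotypes: collapse loci sharing parental frequencies into
  # per-individual sufficient statistics (allele and copy counts)
  key <- paste(pp$p0, pp$p1)
  grp <- match(key, unique(key))
  ok <- !data$miss
  Y <- t(rowsum(t(zeroed(data$G, data$miss) * ok), grp)) + 0.0
  M <- t(rowsum(t(data$N * ok), grp)) + 0.0
  storage.mode(Y) <- storage.mode(M) <- "double"
  first <- match(seq_len(max(grp)), grp)
  list(
    type = "hi", a = 0.5, b = 0.5, mode = 2L,
    Y = Y, M = M, P0g = pp$p0[first], P1g = pp$p1[first]
  )
}

# log likelihood of the data given per-cell source-1 allele probabilities p
data_loglik <- function(data, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ok <- !data$miss
  if (inherits(data, "gen_lik")) {
    w <- gl_mix(data, p)
    sum(log(w[ok]))
  } else {
    G <- zeroed(data$G, data$miss)
    sum((G * log(p) + (data$N - G) * log(1 - p))[ok])
  }
}

# genotype-likelihood mixture P(reads | p) per cell
gl_mix <- function(data, p) {
  dip <- data$N == 2
  w <- data$L0 * (1 - p) + data$L1 * p
  w[dip] <- (data$L0 * (1 - p)^2 + 2 * data$L1 * p * (1 - p) +
    data$L2 * p^2)[dip]
  w
}

check_impossible_alleles <- function(data, pp) {
  if (inherits(data, "gen_lik") || inherits(data, "ancestry_data")) {
    return(invisible(NULL))
  }
  ok <- !data$miss
  lo <- pp$p0 <= 0.001 & pp$p1 <= 0.001
  hi <- pp$p0 >= 0.999 & pp$p1 >= 0.999
  n_bad <- sum(ok[, lo, drop = FALSE] & data$G[, lo, drop = FALSE] > 0,
    na.rm = TRUE
  ) +
    sum(ok[, hi, drop = FALSE] &
      data$G[, hi, drop = FALSE] < data$N[, hi, drop = FALSE], na.rm = TRUE)
  if (n_bad > 0) {
    warning(sprintf(
      "%d genotype(s) carry an allele that is near-absent from both source populations",
      n_bad
    ))
  }
  invisible(NULL)
}
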