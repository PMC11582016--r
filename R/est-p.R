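#' Estimate source-population allele frequencies
#'
#' Per-locus Bayesian estimate of the allele frequency in each of the two
#' source (reference) populations. The likelihood is binomial in the allele
#' counts with a Jeffreys Beta(0.5, 0.5) prior; with genotype likelihoods the
#' binomial likelihood is averaged over genotype states weighted by the
#' normalized likelihood vector. Loci with no data in a source are flagged:
#' their posterior equals the prior.
#'
#' @param source0,source1 [gen_data()] or [gen_lik()] objects holding the
#'   reference-population individuals, one object per source.
#' @param config A [sampler_config()].
#' @param ci Credible-interval mass for the summary.
#' @return An object of class `hz_freqs_fit` with elements `draws0`,
#'   `draws1` (posterior draws per source), `summary` (parameters `p0[locus]`
#'   and `p1[locus]`), and `uninformative` (tibble of flagged locus/source
#'   pairs).
#' @export
est_p <- function(source0, source1, config = sampler_config(), ci = 0.90) {
  if (n_loci_of(source0) != n_loci_of(source1)) {
    stop("sources have different numbers of loci")
  }
  loci <- source0$loci
  fits <- lapply(list(source0, source1), function(src) {
    spec <- freq_spec(src)
    transform <- function(m) {
      out <- plogis(m)
      colnames(out) <- loci
      out
    }
    fit_nuts(spec, n_loci_of(src), config, transform = transform)
  })
  flag <- dplyr::bind_rows(
    tibble::tibble(locus = loci[no_data_loci(source0)], source = 0L),
    tibble::tibble(locus = loci[no_data_loci(source1)], source = 1L)
  )
  if (nrow(flag) > 0) {
    message(sprintf(
      "%d locus/source pair(s) with no data: posterior equals the Beta(0.5, 0.5) prior",
      nrow(flag)
    ))
  }
  s0 <- summarize_posterior(fits[[1]], ci)
  s1 <- summarize_posterior(fits[[2]], ci)
  s0$param <- paste0("p0[", s0$param, "]")
  s1$param <- paste0("p1[", s1$param, "]")
  structure(
    list(
      draws0 = fits[[1]], draws1 = fits[[2]],
      summary = dplyr::bind_rows(s0, s1),
      uninformative = flag, loci = loci, ci = ci
    ),
    class = "hz_freqs_fit"
  )
}

#' Point estimates of parental allele frequencies
#'
#' Posterior medians from an [est_p()] fit, clamped to `[0.001, 0.999]`, as
#' required wherever frequencies enter a likelihood.
#'
#' @param posterior An `hz_freqs_fit` from [est_p()].
#' @return A [parental_freqs()] object.
#' @export
point_freqs <- function(posterior) {
  stopifnot(inherits(posterior, "hz_freqs_fit"))
  L <- length(posterior$loci)
  s <- posterior$summary
  parental_freqs(
    p0 = s$median[seq_len(L)],
    p1 = s$median[L + seq_len(L)],
    loci = posterior$loci
  )
}

#' @export
print.hz_freqs_fit <- function(x, ...) {
  cat(sprintf(
    "<parental allele frequency fit: %d loci; %d uninformative locus/source pair(s)>\n",
    length(x$loci), nrow(x$uninformative)
  ))
  invisible(x)
}

freq_spec <- function(src) {
  if (inherits(src, "gen_lik")) {
    list(
      type = "freq", n_loci = n_loci_of(src), mode = 1L, a = 0.5, b = 0.5,
      L0 = src$L0, L1 = src$L1, L2 = src$L2, N = src$N,
      miss = src$miss
    )
  } else {
    ok <- !src$miss
    list(
      type = "freq", n_loci = n_loci_of(src), mode = 0L, a = 0.5, b = 0.5,
      y = colSums(src$G * ok, na.rm = TRUE),
      n = colSums(src$N * ok)
    )
  }
}

no_data_loci <- function(src) colSums(!src$miss) == 0
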