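#' Ancestry-class log likelihood
#'
#' Log likelihood of per-individual ancestry-class proportions
#' `Q = (Q00, Q10, Q11)` — the proportions of the genome with both gene
#' copies from source 0, one copy from each source, and both copies from
#' source 1. Genotype probabilities at diploid loci are the ancestry-class
#' mixture with Hardy-Weinberg expectations within classes (heterozygotes
#' within a homozygous-ancestry class carry the usual factor of 2, so each
#' locus's probabilities sum to one over genotypes). Haploid loci inform
#' only the marginal source-1 proportion `q1 = Q11 + Q10/2`.
#'
#' @param data A [gen_data()], [gen_lik()] or [ancestry_data()] object.
#' @param P A [parental_freqs()] object (ignored for ancestry data).
#' @param Q Numeric matrix `individuals x 3` (columns Q00, Q10, Q11), or a
#'   single simplex vector recycled across individuals.
#' @return Scalar log likelihood.
#' @export
q_loglik <- function(data, P = NULL, Q) {
  if (is.vector(Q)) Q <- matrix(Q, n_ind(data), 3, byrow = TRUE)
  stopifnot(nrow(Q) == n_ind(data), ncol(Q) == 3)
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-9)) {
    stop("each row of Q must be a simplex (non-negative, summing to 1)")
  }
  A <- q_coefficients(data, P)
  w <- A[[1]] * Q[, 1] + A[[2]] * Q[, 2] + A[[3]] * Q[, 3]
  sum(log(w[!data$miss]))
}

#' Estimate ancestry-class proportions
#'
#' Posterior inference of the per-individual ancestry-class simplex
#' `(Q00, Q10, Q11)` under a uniform Dirichlet(1, 1, 1) prior, given parental
#' allele frequencies. `Q10` is the interpopulation-ancestry proportion.
#' When only haploid loci are present the split of non-`Q10` ancestry is
#' weakly identified and a warning is issued.
#'
#' @inheritParams q_loglik
#' @param config A [sampler_config()].
#' @param ci Credible-interval mass for summaries.
#' @return An object of class `hz_q_fit` with posterior `draws` (parameters
#'   `Q00[id]`, `Q10[id]`, `Q11[id]`), a `summary` tibble, and flagged
#'   individuals without informative loci.
#' @export
est_Q <- function(data, P = NULL, config = sampler_config(), ci = 0.90) {
  if (all(data$N == 1)) {
    warning(paste(
      "only haploid loci present: these inform the source-1 proportion but",
      "not its split into interpopulation vs homozygous ancestry"
    ))
  }
  ids <- data$individuals
  n <- n_ind(data)
  spec <- q_spec(data, P)
  transform <- function(m) {
    # columns are (y1, y2) pairs per individual; simplex via softmax(y1, y2, 0)
    y1 <- m[, 2 * seq_len(n) - 1, drop = FALSE]
    y2 <- m[, 2 * seq_len(n), drop = FALSE]
    mx <- pmax(y1, y2, 0)
    e1 <- exp(y1 - mx)
    e2 <- exp(y2 - mx)
    e3 <- exp(-mx)
    den <- e1 + e2 + e3
    out <- cbind(e1 / den, e2 / den, e3 / den)
    colnames(out) <- c(
      paste0("Q00[", ids, "]"), paste0("Q10[", ids, "]"),
      paste0("Q11[", ids, "]")
    )
    out
  }
  fit <- fit_nuts(spec, 2L * n, config, transform = transform)
  flagged <- ids[rowSums(!data$miss) == 0]
  if (length(flagged) > 0) {
    message(sprintf(
      "%d individual(s) with no data: posterior equals the Dirichlet(1,1,1) prior",
      length(flagged)
    ))
  }
  structure(
    list(
      draws = fit, summary = summarize_posterior(fit, ci),
      individuals = ids, flagged = flagged, ci = ci
    ),
    class = "hz_q_fit"
  )
}

#' Hybrid index derived from ancestry-class proportions
#'
#' Per posterior draw, `H = Q11 + Q10 / 2`: the proportion of gene copies
#' inherited from source 1.
#'
#' @param Q An `hz_q_fit` from [est_Q()].
#' @param ci Credible-interval mass for summaries.
#' @return An `hz_hi_fit` (marked as derived).
#' @export
derive_H <- function(Q, ci = 0.90) {
  stopifnot(inherits(Q, "hz_q_fit"))
  ids <- Q$individuals
  arr <- Q$draws$draws
  H <- arr[, , paste0("Q11[", ids, "]"), drop = FALSE] +
    0.5 * arr[, , paste0("Q10[", ids, "]"), drop = FALSE]
  dimnames(H)[[3]] <- paste0("H[", ids, "]")
  draws <- Q$draws
  draws$draws <- H
  new_hi_fit(draws, summarize_posterior(draws, ci), ids,
    flagged = Q$flagged, ci = ci, derived = TRUE
  )
}

#' Posterior-median ancestry-class proportions
#'
#' @param fit An `hz_q_fit`.
#' @return A tibble with columns `individual`, `Q00`, `Q10`, `Q11`.
#' @export
q_point <- function(fit) {
  stopifnot(inherits(fit, "hz_q_fit"))
  n <- length(fit$individuals)
  m <- matrix(fit$summary$median, n, 3)
  tibble::tibble(
    individual = fit$individuals,
    Q00 = m[, 1], Q10 = m[, 2], Q11 = m[, 3]
  )
}

#' @export
print.hz_q_fit <- function(x, ...) {
  n <- length(x$individuals)
  cat(sprintf(
    "<ancestry-class fit: %d individuals; median Q10 in [%.3f, %.3f]>\n",
    n, min(x$summary$median[n + seq_len(n)]),
    max(x$summary$median[n + seq_len(n)])
  ))
  invisible(x)
}

# sampler model specification: grouped sufficient statistics for known
# genotypes, per-cell coefficients for genotype likelihoods
q_spec <- function(data, P) {
  if (inherits(data, "gen_lik")) {
    A <- q_coefficients(data, P)
    return(list(
      type = "q", grouped = FALSE,
      A0 = A[[1]], A1 = A[[2]], A2 = A[[3]], miss = data$miss
    ))
  }
  pp <- effective_freqs(data, P)
  key <- paste(pp$p0, pp$p1)
  grp <- match(key, unique(key))
  first <- match(seq_len(max(grp)), grp)
  n <- n_ind(data)
  # observation category = (frequency group, ploidy, genotype)
  G <- zeroed(data$G, data$miss)
  code <- (rep(grp, each = n) - 1L) * 6L + (data$N - 1L) * 3L + G
  code[data$miss] <- NA
  cats <- sort(unique(as.vector(code[!data$miss])))
  m <- match(code, cats)
  dim(m) <- dim(code)
  W <- t(apply(m, 1, tabulate, nbins = length(cats))) + 0.0
  if (length(cats) == 1) W <- matrix(W, n, 1)
  storage.mode(W) <- "double"
  a <- vapply(cats, function(cc) {
    g_ <- cc %% 3L
    nij <- ((cc %/% 3L) %% 2L) + 1L
    k <- cc %/% 6L + 1L
    q_coef_cell(g_, nij, pp$p0[first][k], pp$p1[first][k])
  }, numeric(3))
  list(
    type = "q", grouped = TRUE, W = W,
    a0 = a[1, ], a1 = a[2, ], a2 = a[3, ]
  )
}

# coefficients of (Q00, Q10, Q11) for a single genotype observation
q_coef_cell <- function(g, nij, p0, p1) {
  if (nij == 2) {
    c(
      dbinom(g, 2, p0),
      switch(as.character(g),
        "0" = (1 - p1) * (1 - p0),
        "1" = p1 * (1 - p0) + p0 * (1 - p1),
        "2" = p1 * p0
      ),
      dbinom(g, 2, p1)
    )
  } else {
    pa <- function(q1) p0 + q1 * (p1 - p0)
    if (g == 1) c(pa(0), pa(0.5), pa(1)) else 1 - c(pa(0), pa(0.5), pa(1))
  }
}

# per-cell likelihood coefficients of (Q00, Q10, Q11); genotype-likelihood
# cells average the coefficients over genotype states
q_coefficients <- function(data, P) {
  pp <- effective_freqs(data, P)
  n <- n_ind(data)
  p0 <- rep(pp$p0, each = n)
  p1 <- rep(pp$p1, each = n)
  dim(p0) <- dim(p1) <- dim(data$N)
  coef_g <- function(g) {
    dip <- data$N == 2
    a0 <- a1 <- a2 <- matrix(0, nrow(data$N), ncol(data$N))
    # diploid classes: HW within class, interclass one copy from each source
    a0[dip] <- dbinom(g, 2, p0[dip])
    a2[dip] <- dbinom(g, 2, p1[dip])
    a1[dip] <- switch(as.character(g),
      "0" = ((1 - p1) * (1 - p0))[dip],
      "1" = (p1 * (1 - p0) + p0 * (1 - p1))[dip],
      "2" = (p1 * p0)[dip]
    )
    if (g < 2) {
      hap <- !dip
      pa <- function(q1) p0 + q1 * (p1 - p0)
      a0[hap] <- (if (g == 1) pa(0) else 1 - pa(0))[hap]
      a1[hap] <- (if (g == 1) pa(0.5) else 1 - pa(0.5))[hap]
      a2[hap] <- (if (g == 1) pa(1) else 1 - pa(1))[hap]
    }
    list(a0, a1, a2)
  }
  if (inherits(data, "gen_lik")) {
    acc <- list(0, 0, 0)
    Lg <- list(data$L0, data$L1, data$L2)
    for (g in 0:2) {
      cg <- coef_g(g)
      for (k in 1:3) acc[[k]] <- acc[[k]] + Lg[[g + 1]] * cg[[k]]
    }
    acc
  } else {
    G <- zeroed(data$G, data$miss)
    out <- list(
      matrix(0, n, n_loci_of(data)), matrix(0, n, n_loci_of(data)),
      matrix(0, n, n_loci_of(data))
    )
    for (g in 0:2) {
      cg <- coef_g(g)
      sel <- G == g & !data$miss
      for (k in 1:3) out[[k]][sel] <- cg[[k]][sel]
    }
    # missing cells get a constant positive coefficient (skipped anyway)
    for (k in 1:3) out[[k]][data$miss] <- 1
    out
  }
}
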