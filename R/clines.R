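#' Logit-logistic genomic cline function
#'
#' Probability that a gene copy at a locus with cline slope `v` and center
#' `c` derives from source population 1, given an individual's hybrid index
#' `h`: `logit(phi) = v (logit(h) - logit(c))`, equivalently
#' `phi = h^v / (h^v + (1 - h)^v e^u)` with `u = logit(c) v`. `v = 1`,
#' `c = 0.5` is the genome-average (null) cline where `phi = h`; `h = c`
#' gives `phi = 0.5` for any slope. Endpoints are exact: `phi(0) = 0`,
#' `phi(1) = 1`.
#'
#' @param h Hybrid index in `[0, 1]` (vectorized).
#' @param v Cline slope (> 0).
#' @param c Cline center in (0, 1).
#' @return `phi` on the same scale, in `[0, 1]`.
#' @export
phi <- function(h, v, c) {
  if (any(v <= 0)) stop("cline slope v must be positive")
  if (any(c <= 0 | c >= 1)) stop("cline center c must lie in (0, 1)")
  if (any(h < 0 | h > 1)) stop("hybrid index must lie in [0, 1]")
  out <- plogis(v * (qlogis(h) - qlogis(c)))
  out[h == 0] <- 0
  out[h == 1] <- 1
  out
}

#' Genomic-cline log likelihood
#'
#' Log likelihood of per-locus cline parameters given genetic data, parental
#' allele frequencies and fixed hybrid indexes. The per-copy source-1
#' probability `phi` from [phi()] replaces the hybrid index in the
#' hybrid-index likelihood: per cell the allele-count kernel is
#' `(phi p1 + (1 - phi) p0)^G ((phi (1 - p1) + (1 - phi)(1 - p0)))^(N - G)`.
#' With local ancestry the kernel is `phi^Z (1 - phi)^(N - Z)`; with genotype
#' likelihoods the per-genotype likelihood is averaged over states. With
#' `v = 1`, `c = 0.5` at every locus this reduces exactly to [hi_loglik()].
#' Hierarchical prior terms are part of the model fit, not of this data
#' likelihood.
#'
#' @param data A [gen_data()], [gen_lik()] or [ancestry_data()] object.
#' @param P A [parental_freqs()] object (ignored for ancestry data).
#' @param H Numeric vector of hybrid indexes (point estimates); values of
#'   exactly 0 or 1 are nudged to 0.001/0.999 with a warning.
#' @param v,c Numeric vectors of per-locus cline slopes and centers.
#' @return Scalar log likelihood.
#' @export
cline_loglik <- function(data, P = NULL, H, v, c) {
  stopifnot(length(H) == n_ind(data))
  L <- n_loci_of(data)
  v <- rep_len(v, L)
  c <- rep_len(c, L)
  H <- nudge_H(H)
  pp <- effective_freqs(data, P)
  ph <- plogis(outer(qlogis(H), v, "*") -
    rep(v * qlogis(c), each = length(H)))
  p <- ph * rep(pp$p1 - pp$p0, each = length(H)) +
    rep(pp$p0, each = length(H))
  data_loglik(data, p)
}

#' Fit hierarchical Bayesian genomic clines
#'
#' Estimates per-locus logit-logistic cline slopes `v` and centers `c` from
#' genotype, genotype-likelihood, or local-ancestry data, given parental
#' allele frequencies and externally estimated hybrid indexes (modularity:
#' uncertainty in `P` and `H` is not propagated). Hierarchical priors
#' `log10(v) ~ N(mu_v, sigma_v)` and `logit(c) ~ N(mu_c, sigma_c)` share
#' information across loci; the standard deviations measure genome-wide
#' variability in introgression.
#'
#' Modes:
#' * `"hierarchical"` (default): means fixed at 0 (soft centering),
#'   `sigma_v`, `sigma_c` estimated with half-Normal(0, `sigma0`) hyperpriors.
#' * `"fixed_sd"`: `sigma_v`, `sigma_c` supplied and fixed; loci are then
#'   independent, enabling batch-parallel fitting of large data sets. Setting
#'   large SDs (e.g., 100) gives the non-hierarchical variant.
#' * `"free_means"`: additionally estimates `mu_v`, `mu_c` with
#'   Normal(0, `mu0`) priors, for comparing a locus set against hybrid
#'   indexes estimated from a different set.
#'
#' The hierarchical modes use a non-centered parameterization (locus effects
#' as standard-normal deviates scaled by sigma) to avoid funnel pathologies.
#'
#' @inheritParams cline_loglik
#' @param H Hybrid indexes: an `hz_hi_fit` (posterior medians are used) or a
#'   numeric vector.
#' @param mode One of `"hierarchical"`, `"fixed_sd"`, `"free_means"`.
#' @param sigma_v,sigma_c Fixed prior standard deviations (required and > 0
#'   for `mode = "fixed_sd"`).
#' @param sigma0 Hyperprior scale for the cline standard deviations.
#' @param mu0 Prior scale for the hierarchical means in `"free_means"` mode.
#' @param config A [sampler_config()].
#' @param ci Credible-interval mass for summaries.
#' @return An object of class `hz_cline_fit`: posterior `draws` over
#'   `v[locus]`, `c[locus]` (natural scale) and hierarchy parameters, a
#'   per-locus `summary`, and a `hierarchy` summary.
#' @export
est_gencline <- function(data, P = NULL, H,
                         mode = c("hierarchical", "fixed_sd", "free_means"),
                         sigma_v = NULL, sigma_c = NULL, sigma0 = 2, mu0 = 2,
                         config = sampler_config(), ci = 0.90) {
  mode <- match.arg(mode)
  if (inherits(H, "hz_hi_fit")) H <- hi_point(H)
  stopifnot(length(H) == n_ind(data))
  H <- nudge_H(H)
  L <- n_loci_of(data)
  loci <- data$loci
  if (mode != "fixed_sd" && L < 2) {
    stop("hierarchical modes need at least 2 loci to identify the cline SDs")
  }
  est_sigma <- mode != "fixed_sd"
  est_mu <- mode == "free_means"
  if (!est_sigma) {
    if (is.null(sigma_v) || is.null(sigma_c) || sigma_v <= 0 || sigma_c <= 0) {
      stop("fixed_sd mode requires positive sigma_v and sigma_c")
    }
  }
  pp <- effective_freqs(data, P)
  spec <- c(
    list(
      type = "cline", est_sigma = est_sigma, est_mu = est_mu,
      sigma0 = sigma0, mu0 = mu0,
      sv_fixed = sigma_v %||% 1, sc_fixed = sigma_c %||% 1,
      N = data$N, miss = data$miss, P0 = pp$p0, P1 = pp$p1, t = qlogis(H)
    ),
    if (inherits(data, "gen_lik")) {
      list(mode = 1L, L0 = data$L0, L1 = data$L1, L2 = data$L2)
    } else {
      list(mode = 0L, G = zeroed(data$G, data$miss))
    }
  )
  n_pars <- 2L * L + 2L * est_sigma + 2L * est_mu
  transform <- function(m) {
    rv <- m[, seq_len(L), drop = FALSE]
    rc <- m[, L + seq_len(L), drop = FALSE]
    if (est_sigma) {
      sv <- exp(m[, 2 * L + 1])
      sc <- exp(m[, 2 * L + 2])
      mv <- if (est_mu) m[, 2 * L + 3] else 0
      mc <- if (est_mu) m[, 2 * L + 4] else 0
      lv <- mv + sv * rv
      th <- mc + sc * rc
    } else {
      lv <- rv
      th <- rc
    }
    out <- cbind(10^lv, plogis(th))
    colnames(out) <- c(paste0("v[", loci, "]"), paste0("c[", loci, "]"))
    if (est_sigma) {
      out <- cbind(out, sigma_v = sv, sigma_c = sc)
    }
    if (est_mu) {
      out <- cbind(out, mu_v = m[, 2 * L + 3], mu_c = m[, 2 * L + 4])
    }
    out
  }
  fit <- fit_nuts(spec, n_pars, config, transform = transform)
  build_cline_fit(fit, loci, mode, ci,
    fixed = if (!est_sigma) c(sigma_v = sigma_v, sigma_c = sigma_c) else NULL
  )
}

build_cline_fit <- function(fit, loci, mode, ci, fixed = NULL) {
  s <- summarize_posterior(fit, ci)
  hier <- s[!grepl("^[vc]\\[", s$param), ]
  structure(
    list(
      draws = fit, summary = s, hierarchy = hier, loci = loci,
      mode = mode, fixed = fixed, ci = ci, centered = FALSE
    ),
    class = "hz_cline_fit"
  )
}

#' Posterior-median cline parameters
#'
#' @param fit An `hz_cline_fit`.
#' @return A tibble with columns `locus`, `v`, `v_lo`, `v_hi`, `c`, `c_lo`,
#'   `c_hi`.
#' @export
cline_point <- function(fit) {
  stopifnot(inherits(fit, "hz_cline_fit"))
  s <- fit$summary
  vi <- match(paste0("v[", fit$loci, "]"), s$param)
  ci_ <- match(paste0("c[", fit$loci, "]"), s$param)
  tibble::tibble(
    locus = fit$loci,
    v = s$median[vi], v_lo = s$lo[vi], v_hi = s$hi[vi],
    c = s$median[ci_], c_lo = s$lo[ci_], c_hi = s$hi[ci_]
  )
}

#' Cline standard-deviation point estimates
#'
#' Posterior medians of `sigma_v` and `sigma_c` from a hierarchical fit, or
#' the fixed values from a fixed-SD fit.
#'
#' @param fit An `hz_cline_fit`.
#' @return Named numeric vector `c(sigma_v = , sigma_c = )`.
#' @export
cline_sds <- function(fit) {
  stopifnot(inherits(fit, "hz_cline_fit"))
  if (!is.null(fit$fixed)) {
    return(fit$fixed)
  }
  s <- fit$summary
  c(
    sigma_v = s$median[s$param == "sigma_v"],
    sigma_c = s$median[s$param == "sigma_c"]
  )
}

#' Apply a sum-to-zero constraint to fitted clines
#'
#' The hierarchical priors give soft centering only; this enforces the hard
#' constraint that locus deviations average to zero. In `"full"` mode the
#' across-locus means of `log10(v)` and `logit(c)` are subtracted within
#' every posterior iteration and the posterior is re-summarized (preferable
#' when draws are available). In `"point"` mode only the point estimates and
#' interval bounds are shifted by the across-locus mean of the point
#' estimates (useful after batch fitting when full draws are burdensome).
#' Applying the constraint twice is a no-op.
#'
#' @param clines An `hz_cline_fit`.
#' @param mode `"full"` or `"point"`.
#' @return A recentered `hz_cline_fit`.
#' @export
sum2zero <- function(clines, mode = c("full", "point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(clines, "hz_cline_fit"))
  loci <- clines$loci
  if (length(loci) < 2) stop("sum-to-zero needs at least 2 loci")
  vn <- paste0("v[", loci, "]")
  cn <- paste0("c[", loci, "]")
  if (mode == "full") {
    if (is.null(clines$draws)) {
      stop("full-mode recentering needs posterior draws; use mode = 'point'")
    }
    arr <- clines$draws$draws
    lv <- log10(arr[, , vn, drop = FALSE])
    th <- qlogis(arr[, , cn, drop = FALSE])
    mean_lv <- apply(lv, c(1, 2), mean)
    mean_th <- apply(th, c(1, 2), mean)
    arr[, , vn] <- 10^sweep(lv, c(1, 2), mean_lv)
    arr[, , cn] <- plogis(sweep(th, c(1, 2), mean_th))
    out <- clines
    out$draws$draws <- arr
    out$summary <- summarize_posterior(out$draws, clines$ci)
    out$hierarchy <- out$summary[!grepl("^[vc]\\[", out$summary$param), ]
    out$centered <- TRUE
    return(out)
  }
  s <- clines$summary
  vi <- match(vn, s$param)
  ci_ <- match(cn, s$param)
  dv <- mean(log10(s$median[vi]))
  dc <- mean(qlogis(s$median[ci_]))
  for (col in c("median", "lo", "hi")) {
    s[[col]][vi] <- 10^(log10(s[[col]][vi]) - dv)
    s[[col]][ci_] <- plogis(qlogis(s[[col]][ci_]) - dc)
  }
  out <- clines
  out$summary <- s
  out$centered <- TRUE
  out
}

#' Flag loci with credible deviations from genome-average introgression
#'
#' A locus is flagged `steep` when its credible interval for `v` lies
#' entirely above `null_v`, `shallow` when entirely below; `excess_source0`
#' when the interval for `c` lies entirely above `null_c` (introgression
#' biased toward source 0 ancestry), `excess_source1` when entirely below.
#' Flags are reported raw, per locus, without multiple-testing adjustment.
#'
#' @param clines An `hz_cline_fit`.
#' @param null_v,null_c Null cline parameters (genome average).
#' @param ci Credible-interval mass used for flagging; recomputed from the
#'   draws when it differs from the fit's stored summary.
#' @return A tibble with columns `locus`, `v_flag`, `c_flag`.
#' @export
flag_outliers <- function(clines, null_v = 1, null_c = 0.5, ci = 0.90) {
  stopifnot(inherits(clines, "hz_cline_fit"))
  pt <- if (abs(ci - clines$ci) < 1e-12) {
    cline_point(clines)
  } else {
    s <- summarize_posterior(clines$draws, ci)
    tmp <- clines
    tmp$summary <- s
    cline_point(tmp)
  }
  tibble::tibble(
    locus = pt$locus,
    v_flag = dplyr::case_when(
      pt$v_lo > null_v ~ "steep",
      pt$v_hi < null_v ~ "shallow",
      TRUE ~ "none"
    ),
    c_flag = dplyr::case_when(
      pt$c_lo > null_c ~ "excess_source0",
      pt$c_hi < null_c ~ "excess_source1",
      TRUE ~ "none"
    )
  )
}

#' Batched cline fitting for large locus sets
#'
#' The scaling workflow for genome-sized data: fit the hierarchical model on
#' a random subset of loci to estimate the cline standard deviations, then
#' fit the remaining loci in independent fixed-SD batches using those point
#' estimates, and optionally apply a point-mode sum-to-zero adjustment across
#' the pooled results.
#'
#' @inheritParams est_gencline
#' @param n_subset Number of loci in the initial hierarchical fit.
#' @param batch_size Loci per fixed-SD batch.
#' @param recenter Apply [sum2zero()] in point mode to the pooled summary.
#' @return An `hz_cline_fit` with a pooled summary (no pooled draws) and the
#'   subset-estimated SDs in `$fixed`.
#' @export
est_gencline_batched <- function(data, P = NULL, H, n_subset = 100,
                                 batch_size = 200, sigma0 = 2,
                                 config = sampler_config(), ci = 0.90,
                                 recenter = TRUE) {
  if (inherits(H, "hz_hi_fit")) H <- hi_point(H)
  L <- n_loci_of(data)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE
  )
  set.seed(config$seed)
  sub <- sort(sample.int(L, min(n_subset, L)))
  hier <- est_gencline(subset_loci(data, sub), subset_freqs(P, sub, data), H,
    mode = "hierarchical", sigma0 = sigma0, config = config, ci = ci
  )
  sds <- cline_sds(hier)
  batches <- split(seq_len(L), ceiling(seq_len(L) / batch_size))
  summaries <- lapply(batches, function(idx) {
    f <- est_gencline(subset_loci(data, idx), subset_freqs(P, idx, data), H,
      mode = "fixed_sd", sigma_v = sds[["sigma_v"]],
      sigma_c = sds[["sigma_c"]], config = config, ci = ci
    )
    f$summary
  })
  s <- dplyr::bind_rows(summaries)
  ord <- c(paste0("v[", data$loci, "]"), paste0("c[", data$loci, "]"))
  s <- s[match(ord, s$param), ]
  out <- structure(
    list(
      draws = NULL, summary = s, hierarchy = hier$hierarchy,
      loci = data$loci, mode = "batched_fixed_sd", fixed = sds, ci = ci,
      centered = FALSE
    ),
    class = "hz_cline_fit"
  )
  if (recenter) out <- sum2zero(out, mode = "point")
  out
}

subset_loci <- function(data, idx) {
  out <- data
  for (f in intersect(names(data), c("G", "N", "miss", "L0", "L1", "L2"))) {
    out[[f]] <- data[[f]][, idx, drop = FALSE]
  }
  out$loci <- data$loci[idx]
  out
}

subset_freqs <- function(P, idx, data) {
  if (is.null(P) || inherits(data, "ancestry_data")) {
    return(NULL)
  }
  parental_freqs(P$p0[idx], P$p1[idx], loci = P$loci[idx])
}

nudge_H <- function(H) {
  if (any(H < 0 | H > 1)) stop("hybrid indexes must lie in [0, 1]")
  if (any(H == 0 | H == 1)) {
    warning("hybrid indexes of exactly 0 or 1 nudged to 0.001/0.999")
    H[H == 0] <- 0.001
    H[H == 1] <- 0.999
  }
  H
}

#' @export
print.hz_cline_fit <- function(x, ...) {
  sds <- tryCatch(cline_sds(x), error = function(e) NULL)
  cat(sprintf(
    "<genomic cline fit (%s%s): %d loci%s>\n",
    x$mode, if (x$centered) ", sum-to-zero" else "", length(x$loci),
    if (!is.null(sds)) {
      sprintf("; sigma_v = %.3f, sigma_c = %.3f", sds[1], sds[2])
    } else {
      ""
    }
  ))
  invisible(x)
}
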