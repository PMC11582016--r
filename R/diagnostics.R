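#' Summarize posterior draws
#'
#' Point estimates are posterior medians; uncertainty is the equal-tail
#' credible interval between the `(1 - ci)/2` and `1 - (1 - ci)/2` quantiles
#' (linear-interpolation quantiles). Split R-hat and effective sample size
#' are attached per parameter.
#'
#' @param draws An `hz_draws` object.
#' @param ci Credible-interval mass, default 0.90.
#' @return A tibble with columns `param`, `median`, `lo`, `hi`, `ess`,
#'   `rhat`.
#' @export
summarize_posterior <- function(draws, ci = 0.90) {
  stopifnot(inherits(draws, "hz_draws"), ci > 0, ci < 1)
  if (n_draws(draws) < 100) {
    stop("at least 100 kept draws are required to summarize a posterior")
  }
  a <- (1 - ci) / 2
  pars <- dimnames(draws$draws)[[3]]
  diag <- compute_diagnostics(draws, quiet = TRUE)
  qs <- t(apply(draws$draws, 3, quantile, probs = c(a, 0.5, 1 - a), names = FALSE))
  tibble::tibble(
    param = pars,
    median = unname(qs[, 2]), lo = unname(qs[, 1]), hi = unname(qs[, 3]),
    ess = diag$ess[match(pars, diag$param)],
    rhat = diag$rhat[match(pars, diag$param)]
  )
}

#' Convergence diagnostics for posterior draws
#'
#' Split R-hat (potential scale reduction computed after splitting each chain
#' in half) and effective sample size from the autocorrelation of the chains,
#' per parameter. A warning is emitted when any R-hat exceeds 1.05 or any ESS
#' falls below 100. With a single chain, R-hat is reported as `NA`.
#'
#' @param draws An `hz_draws` object.
#' @param quiet Suppress the convergence warning.
#' @return A tibble with columns `param`, `rhat`, `ess`.
#' @export
compute_diagnostics <- function(draws, quiet = FALSE) {
  stopifnot(inherits(draws, "hz_draws"))
  pars <- dimnames(draws$draws)[[3]]
  single <- dim(draws$draws)[2] < 2
  if (single && !quiet) message("single chain: split R-hat unavailable")
  rhat <- vapply(pars, function(p) {
    if (single) NA_real_ else split_rhat(par_matrix(draws, p))
  }, 0)
  ess <- vapply(pars, function(p) ess_mean(par_matrix(draws, p)), 0)
  out <- tibble::tibble(param = pars, rhat = unname(rhat), ess = unname(ess))
  if (!quiet) {
    if (any(out$rhat > 1.05, na.rm = TRUE)) {
      warning(sprintf(
        "%d parameter(s) with split R-hat > 1.05; chains may not have mixed",
        sum(out$rhat > 1.05, na.rm = TRUE)
      ))
    }
    if (any(out$ess < 100, na.rm = TRUE)) {
      warning(sprintf(
        "%d parameter(s) with effective sample size < 100",
        sum(out$ess < 100, na.rm = TRUE)
      ))
    }
  }
  out
}

# split each column (chain) in half, then classic potential scale reduction
split_rhat <- function(mat) {
  mat <- as.matrix(mat)
  sp <- split_chains(mat)
  n <- nrow(sp)
  if (n < 4) return(NA_real_)
  mu <- colMeans(sp)
  s2 <- apply(sp, 2, var)
  W <- mean(s2)
  B <- n * var(mu)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

split_chains <- function(mat) {
  n <- nrow(mat)
  h <- n %/% 2
  do.call(cbind, lapply(seq_len(ncol(mat)), function(k) {
    cbind(mat[seq_len(h), k], mat[(n - h + 1):n, k])
  }))
}

# effective sample size for the mean: multi-chain autocovariance with
# Geyer's initial monotone positive sequence
ess_mean <- function(mat) {
  sp <- split_chains(as.matrix(mat))
  n <- nrow(sp)
  m <- ncol(sp)
  if (n < 4) return(NA_real_)
  acov <- apply(sp, 2, autocov_fft)
  mean_acov <- rowMeans(acov)
  W <- mean(apply(sp, 2, var))
  varplus <- W * (n - 1) / n + var(colMeans(sp)) * (m > 1)
  if (varplus <= 0) return(NA_real_)
  rho <- 1 - (W - mean_acov) / varplus
  # paired sums; stop at first negative pair, enforce monotone decrease
  maxt <- n - 1
  psum_prev <- Inf
  tot <- 0
  t <- 2 # rho[1] is lag 0
  while (t + 1 <= maxt + 1) {
    p <- rho[t] + ifelse(t + 1 <= maxt + 1, rho[t + 1], 0)
    if (!is.finite(p) || p < 0) break
    p <- min(p, psum_prev)
    psum_prev <- p
    tot <- tot + p
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * tot)
  min(ess, m * n * log10(max(m * n, 10)))
}

autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nf <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, nf - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (nf)
  ac / ac[1] * sum(x^2) / n
}
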