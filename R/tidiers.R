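#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of model fits
#'
#' `tidy()` returns one row per estimated quantity with posterior median,
#' equal-tail credible interval and diagnostics; `glance()` returns a
#' one-row model-level summary (dimensions, divergences, worst R-hat,
#' smallest ESS).
#'
#' @param x A fit object (`hz_hi_fit`, `hz_q_fit`, `hz_cline_fit`,
#'   `hz_freqs_fit`) or raw `hz_draws`.
#' @param ... Unused.
#' @return A tibble.
#' @name hz-tidiers
NULL

#' @rdname hz-tidiers
#' @exportS3Method generics::tidy
tidy.hz_hi_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(individual = x$individuals),
    x$summary[, c("median", "lo", "hi", "ess", "rhat")]
  ) |>
    dplyr::rename(H = "median")
}

#' @rdname hz-tidiers
#' @exportS3Method generics::tidy
tidy.hz_q_fit <- function(x, ...) {
  x$summary |>
    tidyr::extract("param", c("class", "individual"), "(Q\\d\\d)\\[(.*)\\]") |>
    dplyr::relocate("individual")
}

#' @rdname hz-tidiers
#' @exportS3Method generics::tidy
tidy.hz_cline_fit <- function(x, ...) {
  pt <- cline_point(x)
  pt$log10_v <- log10(pt$v)
  pt$logit_c <- qlogis(pt$c)
  pt
}

#' @rdname hz-tidiers
#' @exportS3Method generics::tidy
tidy.hz_freqs_fit <- function(x, ...) {
  x$summary |>
    tidyr::extract("param", c("source", "locus"), "p([01])\\[(.*)\\]") |>
    dplyr::relocate("locus")
}

#' @rdname hz-tidiers
#' @exportS3Method generics::tidy
tidy.hz_draws <- function(x, ...) summarize_posterior(x)

glance_draws <- function(draws) {
  diag <- compute_diagnostics(draws, quiet = TRUE)
  tibble::tibble(
    n_chains = dim(draws$draws)[2],
    n_kept = dim(draws$draws)[1],
    n_divergent = sum(draws$divergences),
    max_rhat = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
    min_ess = min(diag$ess, na.rm = TRUE)
  )
}

#' @rdname hz-tidiers
#' @exportS3Method generics::glance
glance.hz_hi_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_individuals = length(x$individuals)),
    glance_draws(x$draws)
  )
}

#' @rdname hz-tidiers
#' @exportS3Method generics::glance
glance.hz_q_fit <- function(x, ...) glance.hz_hi_fit(x, ...)

#' @rdname hz-tidiers
#' @exportS3Method generics::glance
glance.hz_cline_fit <- function(x, ...) {
  sds <- cline_sds(x)
  front <- tibble::tibble(
    n_loci = length(x$loci), mode = x$mode,
    sigma_v = sds[["sigma_v"]], sigma_c = sds[["sigma_c"]]
  )
  if (is.null(x$draws)) front else dplyr::bind_cols(front, glance_draws(x$draws))
}
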