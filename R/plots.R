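#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot hybrid index estimates
#'
#' Point estimates with credible intervals, individuals ordered by posterior
#' median.
#'
#' @param object An `hz_hi_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hz_hi_fit <- function(object, ...) {
  tb <- tidy(object) |>
    dplyr::arrange(.data$H) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$rank, y = .data$H)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      color = "grey60"
    ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(
      x = "individual (ordered)", y = "hybrid index (H)",
      title = "Hybrid index posterior medians and credible intervals"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Triangle plot of interpopulation ancestry against hybrid index
#'
#' `Q10` against `H = Q11 + Q10/2`; the triangle boundary
#' `Q10 = 2 min(H, 1 - H)` marks the maximum interpopulation ancestry for a
#' given hybrid index (points near it indicate a non-admixed parent).
#'
#' @param object An `hz_q_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hz_q_fit <- function(object, ...) {
  pt <- q_point(object)
  pt$H <- pt$Q11 + pt$Q10 / 2
  tri <- tibble::tibble(H = c(0, 0.5, 1), Q10 = c(0, 1, 0))
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$H, y = .data$Q10)) +
    ggplot2::geom_path(data = tri, linetype = 2, color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "hybrid index (H)", y = "interpopulation ancestry (Q10)",
      title = "Ancestry-class triangle plot"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted genomic clines
#'
#' Per-locus cline curves (probability of source-1 ancestry against hybrid
#' index) from posterior-median parameters, highlighting loci whose credible
#' intervals exclude the null cline.
#'
#' @param object An `hz_cline_fit`.
#' @param n_loci Plot at most this many loci (sampled evenly).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hz_cline_fit <- function(object, n_loci = 100, ...) {
  pt <- cline_point(object)
  flags <- flag_outliers(object)
  pt$outlier <- flags$v_flag != "none" | flags$c_flag != "none"
  if (nrow(pt) > n_loci) {
    pt <- pt[round(seq(1, nrow(pt), length.out = n_loci)), ]
  }
  h <- seq(0.001, 0.999, length.out = 101)
  curves <- purrr::pmap_dfr(
    list(pt$locus, pt$v, pt$c, pt$outlier),
    function(locus, v, c, outlier) {
      tibble::tibble(locus = locus, h = h, phi = phi(h, v, c), outlier = outlier)
    }
  )
  ggplot2::ggplot(
    curves,
    ggplot2::aes(
      x = .data$h, y = .data$phi, group = .data$locus,
      color = .data$outlier, linewidth = .data$outlier
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey55", `TRUE` = "#b2182b")) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 0.7)) +
    ggplot2::labs(
      x = "hybrid index (H)", y = "probability of source-1 ancestry",
      title = "Genomic clines", color = "credible deviation",
      linewidth = "credible deviation"
    ) +
    ggplot2::theme_minimal()
}
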