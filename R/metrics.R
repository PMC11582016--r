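#' Mean absolute error
#'
#' @param truth,estimates Numeric vectors of equal length.
#' @return Mean of `|truth - estimates|`.
#' @export
mae <- function(truth, estimates) {
  if (length(truth) != length(estimates)) {
    stop("truth and estimates have different lengths")
  }
  mean(abs(truth - estimates))
}

#' Credible-interval coverage
#'
#' Fraction of intervals `[lo, hi]` containing the true value; endpoints
#' count as covered.
#'
#' @param truth,lo,hi Numeric vectors of equal length with `lo <= hi`.
#' @return Proportion in `[0, 1]`.
#' @export
ci_coverage <- function(truth, lo, hi) {
  if (length(truth) != length(lo) || length(truth) != length(hi)) {
    stop("truth, lo and hi have different lengths")
  }
  if (any(lo > hi)) stop("interval bounds with lo > hi")
  mean(lo <= truth & truth <= hi)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the argument checks used
#' throughout the package's evaluation code.
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y have different lengths")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  cor(x, y)
}

#' Label-shuffling permutation test
#'
#' Generic randomization test: the statistic is recomputed under random
#' permutations of the labels. The default statistic is the difference in
#' group means (first level minus second) for a two-level label.
#'
#' @param x Numeric vector of per-unit values.
#' @param labels Vector of group labels, same length as `x`.
#' @param statistic Function of `(x, labels)` returning a scalar.
#' @param n_perm Number of permutations.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param seed Optional integer seed.
#' @return A list with `observed`, `p_value`, and the permutation `null`
#'   distribution.
#' @export
perm_test <- function(x, labels, statistic = NULL, n_perm = 1000,
                      alternative = c("greater", "less", "two.sided"),
                      seed = NULL) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(labels))
  if (is.null(statistic)) {
    lv <- unique(labels)
    if (length(lv) != 2) stop("default statistic needs exactly two label levels")
    statistic <- function(x, labels) {
      mean(x[labels == lv[1]]) - mean(x[labels == lv[2]])
    }
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic(x, labels)
  null <- vapply(
    seq_len(n_perm),
    function(i) statistic(x, sample(labels)), 0
  )
  p <- switch(alternative,
    greater = (1 + sum(null >= obs)) / (n_perm + 1),
    less = (1 + sum(null <= obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  )
  list(observed = obs, p_value = p, null = null)
}
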