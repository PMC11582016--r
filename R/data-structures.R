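#' Genotype data for admixed and source individuals
#'
#' Stores counts of the source-1-associated (e.g., non-reference) allele for
#' each individual and locus, together with per-cell ploidy and a missing-data
#' mask. Loci may be diploid or haploid, and ploidy may vary across cells
#' (e.g., Z-linked loci in female birds or butterflies are haploid).
#'
#' @param G Integer matrix, individuals in rows and loci in columns; each cell
#'   is the allele count in `0..N_ij` or `NA` for missing.
#' @param ploidy Either a single ploidy (1 or 2) for every cell or an integer
#'   matrix of the same dimension as `G` with entries 1 or 2.
#' @param individuals,loci Optional character IDs; defaults to the dimnames of
#'   `G` or generated IDs.
#'
#' @return An object of class `gen_data` with elements `G`, `N`, `miss`,
#'   `individuals`, `loci`.
#' @export
gen_data <- function(G, ploidy = 2L, individuals = NULL, loci = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  N <- expand_ploidy(ploidy, dim(G))
  miss <- is.na(G)
  ok <- !miss
  if (any(G[ok] != round(G[ok]))) {
    stop("genotype counts must be integers")
  }
  if (any(G[ok] < 0) || any(G[ok] > N[ok])) {
    bad <- which(ok & (G < 0 | G > N), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "allele count out of range 0..ploidy at individual %d, locus %d",
      bad[1], bad[2]
    ))
  }
  structure(
    list(
      G = G, N = N, miss = miss,
      individuals = default_ids(individuals, rownames(G), nrow(G), "ind"),
      loci = default_ids(loci, colnames(G), ncol(G), "locus")
    ),
    class = "gen_data"
  )
}

#' Local-ancestry data
#'
#' Like [gen_data()] but cells are counts of gene copies inherited from source
#' population 1 (local ancestry `Z`), as produced by local-ancestry inference
#' software or by the package's hybrid zone simulator.
#'
#' @inheritParams gen_data
#' @param Z Integer matrix of source-1 ancestry copy counts, `0..N_ij`.
#' @return An object of class `ancestry_data` (and `gen_data`).
#' @export
ancestry_data <- function(Z, ploidy = 2L, individuals = NULL, loci = NULL) {
  out <- gen_data(Z, ploidy, individuals, loci)
  class(out) <- c("ancestry_data", "gen_data")
  out
}

#' Genotype likelihoods
#'
#' Relative likelihoods of each genotype state per individual and locus, as
#' emitted by variant callers (GL/PL fields) or by [sim_reads()]. Vectors are
#' renormalized to sum to one on construction; a vector with equal entries
#' across its valid states encodes a fully missing genotype, with the same
#' semantics as a masked cell in [gen_data()].
#'
#' @param L Numeric array `individuals x loci x 3` of non-negative relative
#'   likelihoods for genotype states 0, 1, 2 copies of the source-1-associated
#'   allele. For haploid cells only the first two slices are used.
#' @inheritParams gen_data
#' @return An object of class `gen_lik` with elements `L0`, `L1`, `L2`
#'   (matrices of normalized state likelihoods), `N`, `miss`, `individuals`,
#'   `loci`.
#' @export
gen_lik <- function(L, ploidy = 2L, individuals = NULL, loci = NULL) {
  stopifnot(is.array(L), length(dim(L)) == 3, dim(L)[3] == 3)
  n <- dim(L)[1]
  nl <- dim(L)[2]
  N <- expand_ploidy(ploidy, c(n, nl))
  L0 <- L[, , 1, drop = TRUE]
  L1 <- L[, , 2, drop = TRUE]
  L2 <- L[, , 3, drop = TRUE]
  dim(L0) <- dim(L1) <- dim(L2) <- c(n, nl)
  L2[N == 1] <- 0
  na <- is.na(L0) | is.na(L1) | (N == 2 & is.na(L2))
  L0[na] <- 1
  L1[na] <- 1
  L2[na] <- ifelse(N[na] == 2, 1, 0)
  if (any(c(L0, L1, L2) < 0)) stop("genotype likelihoods must be non-negative")
  tot <- L0 + L1 + L2
  if (any(tot <= 0)) stop("each genotype-likelihood vector needs a positive entry")
  L0 <- L0 / tot
  L1 <- L1 / tot
  L2 <- L2 / tot
  # equal entries across valid states carry no information -> missing
  miss <- na |
    (N == 2 & abs(L0 - L1) < 1e-9 & abs(L1 - L2) < 1e-9) |
    (N == 1 & abs(L0 - L1) < 1e-9)
  structure(
    list(
      L0 = L0, L1 = L1, L2 = L2, N = N, miss = miss,
      individuals = default_ids(individuals, dimnames(L)[[1]], n, "ind"),
      loci = default_ids(loci, dimnames(L)[[2]], nl, "locus")
    ),
    class = "gen_lik"
  )
}

#' Convert known genotypes to certain genotype likelihoods
#'
#' Each non-missing genotype becomes a likelihood vector with a single unit
#' entry; missing cells become equal-likelihood vectors. Model fits on the
#' result reproduce known-genotype fits exactly.
#'
#' @param x A [gen_data()] object.
#' @return A [gen_lik()] object.
#' @export
as_gen_lik <- function(x) {
  stopifnot(inherits(x, "gen_data"))
  n <- nrow(x$G)
  nl <- ncol(x$G)
  L <- array(0, c(n, nl, 3))
  G <- x$G
  for (g in 0:2) L[, , g + 1] <- ifelse(!x$miss & G == g, 1, 0)
  eq <- array(rep(ifelse(x$miss, 1, 0), 3), c(n, nl, 3))
  eq[, , 3][x$N == 1] <- 0
  L <- L + eq
  gen_lik(L, ploidy = x$N, individuals = x$individuals, loci = x$loci)
}

#' Parental (source population) allele frequencies
#'
#' Per-locus frequencies of the counted allele in the two source populations.
#' Frequencies are clamped to `[0.001, 0.999]` so that loci with fixed
#' differences do not produce infinite log probabilities in the likelihoods.
#'
#' @param p0,p1 Numeric vectors in `[0, 1]`: frequencies in source 0 and
#'   source 1.
#' @param loci Optional locus IDs.
#' @return An object of class `parental_freqs` with clamped `p0`, `p1`.
#' @export
parental_freqs <- function(p0, p1, loci = NULL) {
  stopifnot(length(p0) == length(p1))
  if (any(!is.finite(p0)) || any(!is.finite(p1)) ||
    any(p0 < 0 | p0 > 1) || any(p1 < 0 | p1 > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  structure(
    list(
      p0 = pmin(pmax(p0, 0.001), 0.999),
      p1 = pmin(pmax(p1, 0.001), 0.999),
      loci = default_ids(loci, names(p0), length(p0), "locus")
    ),
    class = "parental_freqs"
  )
}

#' @export
print.gen_data <- function(x, ...) {
  kind <- if (inherits(x, "ancestry_data")) "ancestry" else "genotype"
  cat(sprintf(
    "<%s data: %d individuals x %d loci; %d haploid cells; %.1f%% missing>\n",
    kind, nrow(x$G), ncol(x$G), sum(x$N == 1), 100 * mean(x$miss)
  ))
  invisible(x)
}

#' @export
print.gen_lik <- function(x, ...) {
  cat(sprintf(
    "<genotype likelihoods: %d individuals x %d loci; %.1f%% uninformative>\n",
    nrow(x$L0), ncol(x$L0), 100 * mean(x$miss)
  ))
  invisible(x)
}

#' @export
print.parental_freqs <- function(x, ...) {
  cat(sprintf(
    "<parental allele frequencies: %d loci; mean |p1 - p0| = %.3f>\n",
    length(x$p0), mean(abs(x$p1 - x$p0))
  ))
  invisible(x)
}

n_ind <- function(x) length(x$individuals)
n_loci_of <- function(x) length(x$loci)

expand_ploidy <- function(ploidy, dims) {
  if (length(ploidy) == 1) {
    N <- matrix(as.integer(ploidy), dims[1], dims[2])
  } else {
    N <- as.matrix(ploidy)
    storage.mode(N) <- "integer"
    if (!all(dim(N) == dims)) {
      stop("ploidy matrix dimensions do not match the data matrix")
    }
  }
  if (!all(N %in% c(1L, 2L))) stop("ploidy must be 1 or 2")
  N
}

default_ids <- function(ids, fallback, n, prefix) {
  out <- ids %||% fallback %||% paste0(prefix, "_", seq_len(n))
  if (length(out) != n) stop("ID length does not match data dimension")
  as.character(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: genotype matrix with NAs zeroed for passing to compiled code
zeroed <- function(M, miss) {
  M[miss] <- 0
  M
}

check_loci_match <- function(data, P) {
  if (length(P$p0) != n_loci_of(data)) {
    stop("data and parental frequencies have different numbers of loci")
  }
  if (!identical(P$loci, data$loci) &&
    !all(grepl("^locus_", P$loci)) && !all(grepl("^locus_", data$loci))) {
    warning("locus IDs of data and parental frequencies differ; matching by position")
  }
  invisible(TRUE)
}
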