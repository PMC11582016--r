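#' Read a genotype (or ancestry) matrix from TSV
#'
#' Expects a header row of locus IDs and a first column of individual IDs;
#' cells are allele counts in `{0, 1, 2}` or `NA`. Locus and individual order
#' is preserved from the file.
#'
#' @param path Path to a tab-separated file.
#' @param ploidy A single ploidy (1 or 2), or the path to a TSV of the same
#'   layout holding a per-cell ploidy matrix, or a ploidy matrix itself.
#' @param ancestry If `TRUE`, return [ancestry_data()] (cells are local
#'   ancestry copy counts) instead of [gen_data()].
#' @return A [gen_data()] or [ancestry_data()] object.
#' @export
read_genotypes_tsv <- function(path, ploidy = 2L, ancestry = FALSE) {
  tb <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(tb) < 2) stop("expected an ID column plus at least one locus column")
  ids <- as.character(tb[[1]])
  loci <- colnames(tb)[-1]
  M <- as.matrix(tb[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(M), nrow(M), ncol(M)))
  bad <- which(!is.na(M) & toupper(M) != "NA" & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "malformed genotype cell '%s' at row %d (individual %s), column %s",
      M[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]], loci[bad[1, 2]]
    ))
  }
  if (is.character(ploidy) && length(ploidy) == 1) {
    ptb <- readr::read_tsv(ploidy,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    ploidy <- matrix(
      as.integer(as.matrix(ptb[, -1, drop = FALSE])), nrow(ptb), ncol(ptb) - 1
    )
  }
  rownames(num) <- ids
  colnames(num) <- loci
  if (ancestry) {
    ancestry_data(num, ploidy, individuals = ids, loci = loci)
  } else {
    gen_data(num, ploidy, individuals = ids, loci = loci)
  }
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotypes_tsv()]: individuals as rows, loci as columns,
#' `NA` for missing cells.
#'
#' @param x A [gen_data()] (or [ancestry_data()]) object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(x, path) {
  stopifnot(inherits(x, "gen_data"))
  G <- x$G
  G[x$miss] <- NA
  tb <- tibble::as_tibble(as.data.frame(G))
  colnames(tb) <- x$loci
  tb <- dplyr::bind_cols(tibble::tibble(id = x$individuals), tb)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

summary_cols <- c("param", "median", "lo", "hi", "ess", "rhat")

#' Write a posterior summary table to TSV
#'
#' Columns are `param`, `median`, `lo`, `hi`, `ess`, `rhat`. Numeric values
#' are stored at 6 significant digits and round-trip losslessly through
#' [read_summary()]. Writing refuses tables that violate the interval
#' invariant `lo <= median <= hi`.
#'
#' @param table A data frame with the summary columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path) {
  if (!all(summary_cols %in% colnames(table))) {
    stop("summary table must have columns ", paste(summary_cols, collapse = ", "))
  }
  tb <- tibble::as_tibble(table)[, summary_cols]
  ok <- is.na(tb$lo) | is.na(tb$hi) |
    (tb$lo <= tb$median + 1e-12 & tb$median <= tb$hi + 1e-12)
  if (!all(ok)) {
    stop("interval invariant violated (lo <= median <= hi) for parameter ",
      tb$param[which(!ok)[1]])
  }
  num <- setdiff(summary_cols, "param")
  tb[num] <- lapply(tb[num], signif, digits = 6)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  tb <- readr::read_tsv(path,
    col_types = readr::cols(
      param = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (!all(summary_cols %in% colnames(tb))) {
    stop("not a summary table: expected columns ",
      paste(summary_cols, collapse = ", "))
  }
  tb[, summary_cols]
}
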