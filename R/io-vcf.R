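#' Read genotypes or genotype likelihoods from VCF
#'
#' Reads biallelic SNP records from a VCF 4.x file. Multiallelic records are
#' skipped (with a message reporting the count), not split, because the
#' models are defined for biallelic loci. `GT` mode counts ALT alleles;
#' `GL` (log10-scaled) and `PL` (phred-scaled) modes convert the stored
#' triplets to normalized linear genotype likelihoods. Haploid calls are
#' recorded with ploidy 1. Missing calls (`./.`, `.`) become masked cells or
#' equal-likelihood vectors.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param mode One of `"GT"`, `"GL"`, `"PL"`.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples to read.
#' @return A [gen_data()] object in GT mode, otherwise a [gen_lik()] object.
#' @export
read_vcf <- function(path, mode = c("GT", "GL", "PL"), samples = NULL) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0) stop("VCF contains no genotype records")
  keep <- vcfR::is.biallelic(vcf)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("skipped %d multiallelic record(s)", n_skip))
    vcf <- vcf[keep, ]
  }
  fix <- vcf@fix
  ids <- fix[, "ID"]
  loci <- ifelse(is.na(ids) | ids == ".",
    paste0(fix[, "CHROM"], ":", fix[, "POS"]), ids
  )
  fmt_fields <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if (!mode %in% fmt_fields) {
    stop(sprintf("requested FORMAT field %s absent from VCF", mode))
  }
  all_samples <- colnames(vcf@gt)[-1]
  sel <- samples %||% all_samples
  if (!all(sel %in% all_samples)) {
    stop("sample(s) not present in VCF: ",
      paste(setdiff(sel, all_samples), collapse = ", "))
  }

  if (mode == "GT") {
    gt <- vcfR::extract.gt(vcf, element = "GT")[, sel, drop = FALSE]
    gt <- gsub("\\|", "/", gt)
    alleles <- strsplit(ifelse(is.na(gt), ".", gt), "/")
    n_copies <- vapply(alleles, function(a) sum(a %in% c("0", "1")), 0L)
    n_alt <- vapply(alleles, function(a) sum(a == "1"), 0L)
    N <- matrix(pmax(n_copies, 1L), nrow(gt), ncol(gt))
    G <- matrix(ifelse(n_copies == 0, NA_real_, n_alt), nrow(gt), ncol(gt))
    return(gen_data(t(G),
      ploidy = t(N), individuals = sel, loci = loci
    ))
  }

  raw <- vcfR::extract.gt(vcf, element = mode)[, sel, drop = FALSE]
  n <- length(sel)
  nl <- nrow(raw)
  L <- array(NA_real_, c(n, nl, 3))
  N <- matrix(2L, n, nl)
  for (i in seq_len(nl)) {
    for (j in seq_len(n)) {
      cell <- raw[i, j]
      if (is.na(cell) || cell == "." || cell == "") next
      vals <- suppressWarnings(as.numeric(strsplit(cell, ",")[[1]]))
      if (anyNA(vals)) next
      lin <- if (mode == "PL") 10^(-vals / 10) else 10^vals
      if (length(lin) == 2) {
        N[j, i] <- 1L
        L[j, i, ] <- c(lin, 0)
      } else if (length(lin) == 3) {
        L[j, i, ] <- lin
      }
    }
  }
  gen_lik(L, ploidy = N, individuals = sel, loci = loci)
}
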