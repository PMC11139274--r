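#' Write a genotype table as CSV
#'
#' Long format, one row per individual-locus combination: `individual`
#' (row index), `locus` (column index), `class`, `allele1`, `allele2`
#' (states 0/1/2).
#'
#' @param gt A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- nrow(gt$A1)
  L <- ncol(gt$A1)
  out <- data.frame(
    individual = rep(seq_len(n), times = L),
    locus = rep(seq_len(L), each = n),
    class = rep(gt$spec$classes, each = n),
    allele1 = as.vector(gt$A1),
    allele2 = as.vector(gt$A2))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a genotype table as a minimal VCF
#'
#' Diploid, unphased VCFv4.2 records on a single synthetic contig: one
#' record per locus at position = locus index, REF `A` for state 0, ALT
#' `C,T` for states 1 (alternate / source-diagnostic) and 2 (mutant), GT
#' codes `a/b` with a, b in \{0, 1, 2\}.  The locus class is carried in the
#' INFO field (`CLASS=`).  Intended for interoperability with standard VCF
#' tooling; positions and alleles are synthetic.
#'
#' @param gt A [genotype_table()].
#' @param path Output file path.
#' @param chrom Contig name (default `"sim1"`).
#' @param sample_prefix Sample-name prefix (default `"ind"`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gt, path, chrom = "sim1",
                                sample_prefix = "ind") {
  stopifnot(inherits(gt, "genotype_table"))
  n <- nrow(gt$A1)
  L <- ncol(gt$A1)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, L),
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Locus class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0(sample_prefix, seq_len(n))), collapse = "\t"))
  gts <- matrix(paste0(t(gt$A1), "/", t(gt$A2)), nrow = L)
  body <- vapply(seq_len(L), function(j) {
    paste(c(chrom, j, paste0("locus", j), "A", "C,T", ".", "PASS",
            paste0("CLASS=", gt$spec$classes[j]), "GT", gts[j, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
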