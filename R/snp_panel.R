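#' Transcript SNP panel for the BCL2L13 / BID / MICAL3 locus
#'
#' Returns the panel of eight transcript SNPs (three in *BCL2L13*, one in
#' *BID*, four in *MICAL3*) plus the intronic marker SNP rs2277831 used for
#' genotype stratification. Allele pairs are ordered so that the first allele
#' is the numerator of the allelic expression ratio, matching the orientation
#' in which ratios are reported. Positions are 1-based chromosome 22
#' coordinates (NCBI build 37.3) and are carried as opaque metadata; the
#' pairwise linkage-disequilibrium columns (`d_prime`, `r2` relative to
#' rs2277831) derive from external reference panels and are configuration
#' inputs for simulation, not quantities this package estimates.
#'
#' @return A data.frame with one row per SNP and columns `snp_id`,
#'   `allele_num` (numerator allele of the reported ratio), `allele_den`,
#'   `gene`, `position`, `maf`, `region` (one of `"3'UTR"`, `"exonic"`,
#'   `"intronic"`), `d_prime` and `r2`.
#' @examples
#' snp_panel()
#' @export
snp_panel <- function() {
  data.frame(
    snp_id = c("rs4488761", "rs2587100", "rs9967", "rs11538",
               "rs5992854", "rs11917", "rs1057721", "rs4819639",
               "rs2277831"),
    allele_num = c("A", "C", "C", "T", "T", "T", "G", "C", "A"),
    allele_den = c("G", "G", "T", "C", "C", "G", "A", "T", "G"),
    gene = c("BCL2L13", "BCL2L13", "BCL2L13", "BID",
             "MICAL3", "MICAL3", "MICAL3", "MICAL3", "MICAL3"),
    position = c(18209613L, 18210704L, 18211205L, 18220831L,
                 18300240L, 18343011L, 18343843L, 18347127L, NA_integer_),
    maf = c(0.46, 0.40, 0.38, 0.18, 0.32, 0.41, 0.41, 0.29, NA_real_),
    region = c("3'UTR", "3'UTR", "3'UTR", "3'UTR",
               "exonic", "3'UTR", "3'UTR", "3'UTR", "intronic"),
    d_prime = c(0.11, 0.02, 0.21, 0.12, 1.00, 0.76, 0.78, 0.74, NA_real_),
    r2 = c(0.00, 0.00, 0.01, 0.00, 0.71, 0.11, 0.13, 0.06, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Define a transcript SNP assay
#'
#' Constructs a SNP definition with an explicit allele orientation: the first
#' allele is the numerator of every ratio reported for the assay. Orientation
#' is a property of the assay design and is never inferred from data.
#'
#' @param id SNP identifier (e.g. `"rs5992854"`).
#' @param alleles Character vector of two distinct single-letter alleles
#'   (numerator first), each one of A, C, G, T.
#' @param gene Gene symbol.
#' @param position 1-based base-pair coordinate (metadata only).
#' @param region One of `"3'UTR"`, `"exonic"`, `"intronic"`.
#' @return An object of class `snp_def`.
#' @export
snp_def <- function(id, alleles, gene = NA_character_, position = NA_integer_,
                    region = c("3'UTR", "exonic", "intronic")) {
  region <- match.arg(region)
  if (length(alleles) != 2L || anyDuplicated(alleles) ||
      !all(alleles %in% c("A", "C", "G", "T"))) {
    stop("`alleles` must be two distinct bases from {A,C,G,T}", call. = FALSE)
  }
  if (!is.na(position) && position <= 0) {
    stop("`position` must be a positive 1-based coordinate", call. = FALSE)
  }
  structure(
    list(id = as.character(id), alleles = as.character(alleles),
         gene = as.character(gene), position = as.integer(position),
         region = region),
    class = "snp_def"
  )
}

# Unordered genotype key: "GA" and "AG" are the same genotype.
geno_key <- function(g) {
  vapply(strsplit(as.character(g), ""), function(x) {
    paste(sort(x), collapse = "")
  }, character(1))
}

#' Test whether genotypes are heterozygous
#'
#' @param g Character vector of two-letter genotype strings (order
#'   irrelevant: `"AG"` and `"GA"` are equivalent). `NA` stays `NA`.
#' @return Logical vector.
#' @export
is_het <- function(g) {
  out <- rep(NA, length(g))
  ok <- !is.na(g)
  out[ok] <- vapply(strsplit(as.character(g[ok]), ""), function(x) {
    length(x) == 2L && x[1] != x[2]
  }, logical(1))
  out
}
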