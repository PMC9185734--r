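#' Read biallelic SNP genotypes and allele frequencies from a VCF
#'
#' Parses diploid GT fields of a VCF 4.x file into a
#' [GenotypeMatrix-class] (dosage counts the ALT allele; `./.` and `.`
#' honoured as missing) and computes per-locus ALT-allele frequencies
#' from the called genotypes. Multi-allelic records and indels are
#' skipped with a reported count. Positions are 1-based per the VCF
#' standard.
#'
#' @param path VCF path (plain or bgzipped).
#' @param strata optional per-sample grouping (e.g. sex, named by VCF
#'   sample id) for stratified frequencies.
#' @return A list: `genotypes` ([GenotypeMatrix-class]), `freqs`
#'   ([AlleleFrequencyTable-class], allele 1 = ALT), `nSkipped`
#'   (multi-allelic/indel record count).
#' @export
readVcfGenotypes <- function(path, strata = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) stop("no usable records in ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (!any(snp)) stop("no usable records in ", path,
                      " (all records multi-allelic or indel)")
  gt <- vcfR::extract.gt(vcf)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L,
                                     dimnames = list(rownames(fix),
                                                     names(gt)))
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  dos <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".") || any(is.na(a)))
      return(NA_integer_)
    sum(a == "1")
  }, integer(1L))
  d <- matrix(dos, nrow = nrow(gt), dimnames = list(ids, colnames(gt)))
  gm <- GenotypeMatrix(d, allele1 = fix[, "ALT"], allele2 = fix[, "REF"])
  strat_vec <- NULL
  if (!is.null(strata)) strat_vec <- strata[colnames(d)]
  list(genotypes = gm, freqs = alleleFrequencies(gm, strat_vec),
       nSkipped = n_skipped)
}
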