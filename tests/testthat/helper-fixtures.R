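# shared fixtures, all generated in code

# a noiseless tier: every read on target, no dropout, no errors
clean_tier <- function(depth = 150) {
  sampleQualityTier("clean", onTargetFraction = 1, meanDepth = depth,
                    dropoutProb = 0, errorRate = 0)
}

# small fixed panel with hand-chosen sequences (distinct, ACGT only)
toy_panel <- function() {
  AmpliconPanel(
    locusId = c("locA", "locB"),
    fwdPrimer = c("ACGTACGTACGTACG", "TTGCATTGCATTGCA"),
    probeAllele1 = c("GGGAAACCC", "TTTCCCAAA"),
    probeAllele2 = c("GGGAAACCG", "TTTCCCAAG"))
}

# dosage matrix helper with default names
dosage_matrix <- function(values, n_loci, n_samples) {
  matrix(as.integer(values), n_loci, n_samples,
         dimnames = list(sprintf("L%03d", seq_len(n_loci)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# hand-written two-sample, two-locus VCF plus an indel record
write_toy_vcf <- function(path, body = TRUE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", sep = "\t"))
  records <- c(
    paste("chr1", "100", "snp1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t"),
    paste("chr1", "200", "snp2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "./.", sep = "\t"),
    paste("chr1", "300", "indel1", "C", "CTT", ".", "PASS", ".", "GT",
          "0/1", "0/0", sep = "\t"))
  writeLines(c(header, if (body) records), path)
  path
}

# independent brute-force P_ID: enumerate the 3 HWE genotypes and sum
# squared probabilities (prob two independent draws coincide)
brute_p_id <- function(p) {
  g <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum(g^2)
}

# independent brute-force P_IDsib: enumerate ordered parental matings
# (HWE) and, within each, the offspring genotype distribution; the
# probability two siblings match is the sum of squared offspring
# probabilities, averaged over matings
brute_p_idsib <- function(p) {
  geno_alleles <- list(c(1, 1), c(1, 0), c(0, 0))  # 1 = minor allele
  hwe <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  total <- 0
  for (m in 1:3) for (f in 1:3) {
    kid <- numeric(3)  # probs of offspring dosage 2, 1, 0
    for (a in 1:2) for (b in 1:2) {
      dos <- geno_alleles[[m]][a] + geno_alleles[[f]][b]
      kid[3 - dos] <- kid[3 - dos] + 0.25
    }
    total <- total + hwe[m] * hwe[f] * sum(kid^2)
  }
  total
}

# naive genotyper oracle: per read, scan every locus and probe by
# substring search, tallying with explicit loops
naive_allele_counts <- function(reads, panel) {
  loci <- locusIds(panel)
  primer <- as.character(fwdPrimer(panel))
  p1 <- as.character(probeAllele1(panel))
  p2 <- as.character(probeAllele2(panel))
  a1 <- a2 <- stats::setNames(integer(length(loci)), loci)
  for (r in reads) {
    for (l in seq_along(loci)) {
      if (!grepl(primer[l], r, fixed = TRUE)) next
      if (grepl(p1[l], r, fixed = TRUE)) a1[l] <- a1[l] + 1L
      if (grepl(p2[l], r, fixed = TRUE)) a2[l] <- a2[l] + 1L
    }
  }
  list(a1 = a1, a2 = a2)
}
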