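#' Flag overrepresented primers in a pooled read set
#'
#' Computes, per panel primer, the proportion of all reads containing
#' that forward primer, and flags primers whose share exceeds
#' `flagThreshold` — by default ten times the uniform share `1/nLoci`.
#' Overamplifying primers consume a disproportionate share of sequencing
#' effort and are the usual reason loci are dropped during panel
#' optimisation; the report flags them but never drops loci itself.
#'
#' @param reads character vector of pooled read sequences (or FASTQ
#'   path), typically all samples of a library combined.
#' @param panel an [AmpliconPanel-class].
#' @param flagThreshold read-share above which a primer is flagged
#'   (default `10 / nLoci(panel)`).
#' @return A list: `primerFractions` data.frame (`locus_id`, `fraction`,
#'   `flagged`), `flagThreshold`, `nReads`.
#' @export
primerOverrepresentation <- function(reads, panel, flagThreshold = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readFastqSequences(reads)
  if (!length(reads)) stop("no reads supplied")
  if (is.null(flagThreshold)) flagThreshold <- 10 / nLoci(panel)
  primer <- as.character(fwdPrimer(panel))
  frac <- vapply(primer, function(p) mean(grepl(p, reads, fixed = TRUE)),
                 numeric(1L))
  df <- data.frame(locus_id = locusIds(panel), fraction = unname(frac),
                   flagged = unname(frac > flagThreshold))
  list(primerFractions = df, flagThreshold = flagThreshold,
       nReads = length(reads))
}

#' Scan pooled reads for primer-interaction artifacts
#'
#' An artifact read (primer-dimer or similar PCR chimera) is one that
#' contains two or more distinct panel primers — in either orientation,
#' reverse complements included — and no allele probe. Reports the
#' artifact fraction per primer pair and flags pairs whose fraction of
#' all reads exceeds `flagThreshold`. Legitimate amplicon reads
#' (primer + probe) are never counted.
#'
#' @inheritParams primerOverrepresentation
#' @param flagThreshold artifact-read share of all reads above which a
#'   primer pair is flagged (default 0.01).
#' @return A list: `pairFractions` data.frame (`locus_a`, `locus_b`,
#'   `fraction`, `flagged`), `nArtifactReads`, `nReads`,
#'   `flagThreshold`.
#' @export
primerInteractionScan <- function(reads, panel, flagThreshold = 0.01) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readFastqSequences(reads)
  if (!length(reads)) stop("no reads supplied")
  loci <- locusIds(panel)
  primer <- as.character(fwdPrimer(panel))
  primer_rc <- as.character(reverseComplement(fwdPrimer(panel)))
  probes <- c(as.character(probeAllele1(panel)),
              as.character(probeAllele2(panel)))
  has_probe <- rep(FALSE, length(reads))
  for (p in unique(probes))
    has_probe <- has_probe | grepl(p, reads, fixed = TRUE)
  hit <- matrix(FALSE, length(reads), length(loci),
                dimnames = list(NULL, loci))
  for (l in seq_along(loci))
    hit[, l] <- grepl(primer[l], reads, fixed = TRUE) |
      grepl(primer_rc[l], reads, fixed = TRUE)
  artifact <- rowSums(hit) >= 2L & !has_probe
  pairs <- data.frame(locus_a = character(), locus_b = character(),
                      fraction = numeric(), flagged = logical())
  if (any(artifact)) {
    hits_per_read <- apply(hit[artifact, , drop = FALSE], 1L,
                           function(z) loci[z], simplify = FALSE)
    pair_keys <- unlist(lapply(hits_per_read, function(ls)
      apply(utils::combn(sort(ls), 2L), 2L, paste, collapse = "\t")))
    tab <- table(pair_keys)
    ab <- do.call(rbind, strsplit(names(tab), "\t", fixed = TRUE))
    frac <- as.numeric(tab) / length(reads)
    pairs <- data.frame(locus_a = ab[, 1L], locus_b = ab[, 2L],
                        fraction = frac, flagged = frac > flagThreshold,
                        row.names = NULL)
    pairs <- pairs[order(-pairs$fraction), , drop = FALSE]
  }
  list(pairFractions = pairs, nArtifactReads = sum(artifact),
       nReads = length(reads), flagThreshold = flagThreshold)
}
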