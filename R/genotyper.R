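#' Count allele-probe reads per locus for one or more samples
#'
#' Implements the exact-containment counting rule of GT-seq-style
#' genotypers: a read is assigned to a locus if it contains that locus's
#' forward primer as an exact substring; among assigned reads, allele
#' counts increment on exact containment of the respective allele probe.
#' Reads matching a primer but neither probe contribute to the locus's
#' read-depth diagnostics only. A sample's on-target fraction is the
#' share of its reads containing any locus's primer together with one of
#' that locus's probes.
#'
#' @param reads either a character vector of read sequences, a FASTQ
#'   path, or a named list of these (one element per sample).
#' @param panel an [AmpliconPanel-class].
#' @param sampleIds optional sample names (defaults to list names).
#' @return A [GenotypeCallReport-class] with assays `countA1`,
#'   `countA2`, `locusReads` and per-sample `totalReads`,
#'   `onTargetFraction`; no calls yet (see [callGenotypes()]).
#' @export
countAlleles <- function(reads, panel, sampleIds = NULL) {
  if (!is.list(reads)) reads <- list(sample_1 = reads)
  if (!is.null(sampleIds)) names(reads) <- sampleIds
  if (is.null(names(reads)))
    names(reads) <- sprintf("sample_%03d", seq_along(reads))
  loci <- locusIds(panel)
  primer <- as.character(fwdPrimer(panel))
  probe1 <- as.character(probeAllele1(panel))
  probe2 <- as.character(probeAllele2(panel))
  n_s <- length(reads)
  a1 <- a2 <- lr <- matrix(0L, length(loci), n_s,
                           dimnames = list(loci, names(reads)))
  total <- integer(n_s)
  on_frac <- numeric(n_s)
  for (j in seq_len(n_s)) {
    r <- reads[[j]]
    if (is.character(r) && length(r) == 1L && file.exists(r) &&
        grepl("\\.(fastq|fq)(\\.gz)?$", r))
      r <- readFastqSequences(r)
    total[j] <- length(r)
    if (!length(r)) { on_frac[j] <- 0; next }
    on_target <- logical(length(r))
    for (l in seq_along(loci)) {
      hit <- grepl(primer[l], r, fixed = TRUE)
      if (!any(hit)) next
      sub <- r[hit]
      h1 <- grepl(probe1[l], sub, fixed = TRUE)
      h2 <- grepl(probe2[l], sub, fixed = TRUE)
      a1[l, j] <- sum(h1)
      a2[l, j] <- sum(h2)
      lr[l, j] <- length(sub)
      on_target[hit][h1 | h2] <- TRUE
    }
    on_frac[j] <- mean(on_target)
  }
  se <- SummarizedExperiment(
    assays = list(countA1 = a1, countA2 = a2, locusReads = lr),
    colData = DataFrame(totalReads = total, onTargetFraction = on_frac,
                        row.names = names(reads)))
  new("GenotypeCallReport", se)
}

#' Call genotypes from allele counts by allele ratio
#'
#' Applies the allele-ratio rule of the GT-seq genotyper family. With
#' `ratio = countA1 / max(countA2, 0.1)` (the denominator floors at 0.1
#' so a zero allele-2 count maps to `10 * countA1`): homozygous allele 1
#' if `ratio >= homRatio`, homozygous allele 2 if `ratio <= 1/homRatio`,
#' heterozygous if `ratio` lies inside `hetBand`, otherwise missing.
#' Loci with allele depth (`countA1 + countA2`) below `minDepth` are
#' missing regardless of ratio.
#'
#' @param report a [GenotypeCallReport-class] from [countAlleles()].
#' @param minDepth minimum allele depth for a call (default 10).
#' @param homRatio homozygote ratio threshold (default 10).
#' @param hetBand two-element heterozygote ratio band (default
#'   `c(0.2, 5)`).
#' @return The report with `ratio` and `call` assays added; thresholds
#'   are recorded in `metadata()`.
#' @export
callGenotypes <- function(report, minDepth = 10L, homRatio = 10,
                          hetBand = c(0.2, 5)) {
  a1 <- assay(report, "countA1")
  a2 <- assay(report, "countA2")
  ratio <- a1 / pmax(a2, 0.1)
  depth <- a1 + a2
  call <- matrix("missing", nrow(a1), ncol(a1), dimnames = dimnames(a1))
  call[ratio >= homRatio] <- "hom1"
  call[ratio <= 1 / homRatio] <- "hom2"
  call[ratio >= hetBand[1L] & ratio <= hetBand[2L]] <- "het"
  call[depth < minDepth] <- "missing"
  assays(report)$ratio <- ratio
  assays(report)$call <- call
  metadata(report)$thresholds <-
    list(minDepth = minDepth, homRatio = homRatio, hetBand = hetBand,
         ratioDenominatorFloor = 0.1)
  report
}

#' @rdname GenotypeCallReport
#' @export
setMethod("genotypeCalls", "GenotypeCallReport", function(object) {
  if (!"call" %in% assayNames(object))
    stop("no calls yet; run callGenotypes() first")
  assay(object, "call")
})

setMethod("show", "GenotypeCallReport", function(object) {
  cat(sprintf("GenotypeCallReport: %d loci x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  mean on-target fraction: %.3f\n",
              mean(colData(object)$onTargetFraction)))
  if ("call" %in% assayNames(object)) {
    cl <- assay(object, "call")
    cat(sprintf("  calls: %.1f%% non-missing\n",
                100 * mean(cl != "missing")))
  }
})

#' Convert called genotypes to a GenotypeMatrix
#'
#' `hom1` maps to dosage 2, `het` to 1, `hom2` to 0, `missing` to `NA`.
#'
#' @param report a called [GenotypeCallReport-class].
#' @return A [GenotypeMatrix-class].
#' @export
callsToGenotypeMatrix <- function(report) {
  cl <- genotypeCalls(report)
  d <- matrix(NA_integer_, nrow(cl), ncol(cl), dimnames = dimnames(cl))
  d[cl == "hom1"] <- 2L
  d[cl == "het"] <- 1L
  d[cl == "hom2"] <- 0L
  GenotypeMatrix(d)
}

#' Merge two technical runs of the same sample set
#'
#' Combines sequencing runs performed with separate index primers by
#' summing allele and locus read counts cell-wise before calling, so a
#' locus under-covered in each single run can still reach the calling
#' depth in the merged data.
#'
#' @param report1,report2 [GenotypeCallReport-class] objects over the
#'   same loci and samples (counts only; call assays are dropped).
#' @return A merged [GenotypeCallReport-class].
#' @export
mergeTechnicalRuns <- function(report1, report2) {
  if (!identical(rownames(report1), rownames(report2)) ||
      !identical(colnames(report1), colnames(report2)))
    stop("reports disagree on panel loci or samples; cannot merge")
  tot <- colData(report1)$totalReads + colData(report2)$totalReads
  w <- ifelse(tot > 0,
              (colData(report1)$onTargetFraction *
                 colData(report1)$totalReads +
               colData(report2)$onTargetFraction *
                 colData(report2)$totalReads) / tot, 0)
  se <- SummarizedExperiment(
    assays = list(
      countA1 = assay(report1, "countA1") + assay(report2, "countA1"),
      countA2 = assay(report1, "countA2") + assay(report2, "countA2"),
      locusReads = assay(report1, "locusReads") +
        assay(report2, "locusReads")),
    colData = DataFrame(totalReads = tot, onTargetFraction = w,
                        row.names = colnames(report1)))
  new("GenotypeCallReport", se)
}
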