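#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<- assays<- colData<-
#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

#' Per-locus biallelic allele frequencies, optionally stratified
#'
#' Stores, for each locus, the population frequency of a tracked allele
#' ("allele 1"); the second allele's frequency is its complement, so the
#' two always sum to one. An optional matrix carries allele-1 frequencies
#' per stratum (e.g. male/female), used for sex-marker screening. In
#' unstratified tables built from a minor-allele-frequency spectrum,
#' allele 1 is the minor allele.
#'
#' @slot locusId character, unique locus identifiers.
#' @slot p1 numeric in \[0,1\], allele-1 frequency per locus.
#' @slot strata numeric matrix (loci x strata) of allele-1 frequencies per
#'   stratum; zero columns when unstratified.
#' @exportClass AlleleFrequencyTable
setClass("AlleleFrequencyTable",
  slots = c(locusId = "character", p1 = "numeric", strata = "matrix"))

setValidity("AlleleFrequencyTable", function(object) {
  msg <- character()
  n <- length(object@locusId)
  if (length(object@p1) != n)
    msg <- c(msg, "locusId and p1 lengths differ")
  if (anyDuplicated(object@locusId))
    msg <- c(msg, "locus ids must be unique")
  if (any(!is.finite(object@p1)) || any(object@p1 < 0 | object@p1 > 1))
    msg <- c(msg, "allele frequencies must lie in [0, 1]")
  if (ncol(object@strata) > 0L) {
    if (nrow(object@strata) != n)
      msg <- c(msg, "strata matrix must have one row per locus")
    if (is.null(colnames(object@strata)))
      msg <- c(msg, "strata columns must be named")
    if (any(!is.finite(object@strata)) ||
        any(object@strata < 0 | object@strata > 1))
      msg <- c(msg, "stratum frequencies must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Samples-by-loci diploid genotype container
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `"dosage"` assay
#' holds, per locus (row) and sample (column), the count of allele 1
#' carried by the sample: 0, 1, 2, or `NA` for a missing call. Column
#' metadata may carry `sampleType` (tissue / hair / colon_feces /
#' field_feces), `method` (radseq / gtseq), `individualId` (links
#' replicates and paired samples) and `sex`. Row metadata carries the two
#' allele labels used when genotypes are written as allele pairs.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% assayNames(object))
    return("must contain a 'dosage' assay")
  d <- assay(object, "dosage")
  ok <- is.na(d) | d == 0L | d == 1L | d == 2L
  if (!all(ok)) return("dosage values must be 0, 1, 2 or NA")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("loci (rows) and samples (columns) must be named")
  TRUE
})

#' Amplicon panel: per-locus forward primer and two allele probes
#'
#' Each locus is genotyped by exact containment: a read belongs to a locus
#' if it contains the forward primer, and supports an allele if it also
#' contains that allele's probe. Probes are matched in read orientation
#' only and must differ from each other at one or more positions.
#'
#' @slot locusId character, unique locus identifiers.
#' @slot fwdPrimer,probeAllele1,probeAllele2 [Biostrings::DNAStringSet]
#'   of the forward primer and the two allele-specific probes, in read
#'   orientation, named by locus.
#' @exportClass AmpliconPanel
setClass("AmpliconPanel",
  slots = c(locusId = "character", fwdPrimer = "DNAStringSet",
            probeAllele1 = "DNAStringSet", probeAllele2 = "DNAStringSet"))

setValidity("AmpliconPanel", function(object) {
  msg <- character()
  n <- length(object@locusId)
  if (anyDuplicated(object@locusId)) msg <- c(msg, "locus ids must be unique")
  for (nm in c("fwdPrimer", "probeAllele1", "probeAllele2")) {
    s <- slot(object, nm)
    if (length(s) != n) msg <- c(msg, sprintf("%s length != number of loci", nm))
    if (n && any(Biostrings::width(s) == 0L))
      msg <- c(msg, sprintf("%s contains an empty sequence", nm))
    if (n && !all(grepl("^[ACGT]*$", as.character(s))))
      msg <- c(msg, sprintf("%s must be uppercase ACGT", nm))
  }
  if (n && length(object@probeAllele1) == n &&
      length(object@probeAllele2) == n &&
      any(as.character(object@probeAllele1) ==
          as.character(object@probeAllele2)))
    msg <- c(msg, "allele probes must differ at >= 1 position")
  if (length(msg)) msg else TRUE
})

#' Per-sample, per-locus allele counts, ratios and genotype calls
#'
#' A [SummarizedExperiment::SummarizedExperiment] with loci as rows and
#' samples as columns. Assays: `countA1` and `countA2` (reads containing
#' the forward primer plus the respective allele probe), `locusReads`
#' (reads containing the forward primer, probe or not), and after
#' [callGenotypes()] also `ratio` (`countA1 / max(countA2, 0.1)`) and
#' `call` (`"hom1"`, `"het"`, `"hom2"`, `"missing"`). Column metadata:
#' `totalReads` and `onTargetFraction` per sample.
#'
#' @exportClass GenotypeCallReport
setClass("GenotypeCallReport", contains = "SummarizedExperiment")

setValidity("GenotypeCallReport", function(object) {
  need <- c("countA1", "countA2", "locusReads")
  if (!all(need %in% assayNames(object)))
    return(paste("missing assay(s):",
                 paste(setdiff(need, assayNames(object)), collapse = ", ")))
  for (nm in need)
    if (any(assay(object, nm) < 0)) return("counts must be >= 0")
  cd <- colData(object)
  if (!all(c("totalReads", "onTargetFraction") %in% colnames(cd)))
    return("colData must carry totalReads and onTargetFraction")
  f <- cd$onTargetFraction
  if (any(!is.na(f) & (f < 0 | f > 1)))
    return("onTargetFraction must lie in [0, 1]")
  TRUE
})

#' Noninvasive sample-quality tier for read simulation
#'
#' Bundles the knobs that distinguish pristine tissue from degraded field
#' feces when simulating amplicon reads: the fraction of reads that are
#' on target, the mean per-locus sequencing depth, the per-locus
#' amplification-failure (dropout) probability, and the per-base
#' substitution error rate.
#'
#' @slot name character scalar, tier label.
#' @slot onTargetFraction numeric in \[0,1\].
#' @slot meanDepth positive numeric, expected reads per locus.
#' @slot dropoutProb numeric in \[0,1\].
#' @slot errorRate numeric in \[0,1\].
#' @exportClass SampleQualityTier
setClass("SampleQualityTier",
  slots = c(name = "character", onTargetFraction = "numeric",
            meanDepth = "numeric", dropoutProb = "numeric",
            errorRate = "numeric"))

setValidity("SampleQualityTier", function(object) {
  msg <- character()
  for (nm in c("onTargetFraction", "dropoutProb", "errorRate")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single value in [0, 1]", nm))
  }
  if (length(object@meanDepth) != 1L || !is.finite(object@meanDepth) ||
      object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Result of a relationship-labelled dyad simulation
#'
#' Holds, per relationship category (PO, FS, HS, FC, UR), the vector of
#' kinship estimates over simulated dyads, the 5x5 misclassification
#' matrix of the maximum-likelihood relationship classifier (rows = true
#' category, proportions summing to one), per-category assignment
#' accuracy, and accuracy collapsed to relatedness degree (PO and FS
#' jointly as first-degree).
#'
#' @slot estimates named list of numeric kinship-estimate vectors.
#' @slot confusion 5x5 numeric matrix of row-normalised proportions.
#' @slot accuracy named numeric, per-category proportion correct.
#' @slot degreeAccuracy named numeric, per-degree proportion correct.
#' @slot nLoci,nDyads integer, problem size.
#' @exportClass DyadSimulationResult
setClass("DyadSimulationResult",
  slots = c(estimates = "list", confusion = "matrix", accuracy = "numeric",
            degreeAccuracy = "numeric", nLoci = "integer",
            nDyads = "integer"))

setValidity("DyadSimulationResult", function(object) {
  msg <- character()
  if (!all(dim(object@confusion) == c(5L, 5L)))
    msg <- c(msg, "confusion matrix must be 5x5")
  else if (any(abs(rowSums(object@confusion) - 1) > 1e-9))
    msg <- c(msg, "confusion matrix rows must sum to 1")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cumulative identity-power curve
#'
#' Cumulative probability of identity for unrelated individuals (P_ID)
#' and for full siblings (P_IDsib) as loci are added to a panel, together
#' with the smallest panel sizes at which each falls below a threshold
#' (typically the reciprocal of the census sample size).
#'
#' @slot curve data.frame with columns `n`, `locusId`, `pId`, `pIdSib`
#'   (cumulative products over the first `n` loci).
#' @slot threshold numeric scalar.
#' @slot minLociPId,minLociPIdSib integer, smallest `n` with a cumulative
#'   value strictly below `threshold`; `NA` when not reached.
#' @exportClass IdentityPowerCurve
setClass("IdentityPowerCurve",
  slots = c(curve = "data.frame", threshold = "numeric",
            minLociPId = "integer", minLociPIdSib = "integer"))

setValidity("IdentityPowerCurve", function(object) {
  cv <- object@curve
  if (!all(c("n", "pId", "pIdSib") %in% names(cv)))
    return("curve must have columns n, pId, pIdSib")
  if (any(diff(cv$pId) > 1e-12) || any(diff(cv$pIdSib) > 1e-12))
    return("cumulative curves must be non-increasing")
  if (any(cv$pIdSib < cv$pId - 1e-12))
    return("P_IDsib must be >= P_ID at every panel size")
  TRUE
})
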