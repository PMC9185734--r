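#' Construct a sample-quality tier
#'
#' @param name tier label.
#' @param onTargetFraction expected fraction of reads that are on target.
#' @param meanDepth expected reads per locus (negative-binomial mean).
#' @param dropoutProb per-locus amplification-failure probability.
#' @param errorRate per-base substitution probability.
#' @return A [SampleQualityTier-class].
#' @export
sampleQualityTier <- function(name, onTargetFraction, meanDepth,
                              dropoutProb, errorRate) {
  new("SampleQualityTier", name = as.character(name),
      onTargetFraction = onTargetFraction, meanDepth = meanDepth,
      dropoutProb = dropoutProb, errorRate = errorRate)
}

setMethod("show", "SampleQualityTier", function(object) {
  cat(sprintf(paste0("SampleQualityTier '%s': on-target %.2f, ",
                     "mean depth %.0f, dropout %.3f, error %.4f\n"),
              object@name, object@onTargetFraction, object@meanDepth,
              object@dropoutProb, object@errorRate))
})

#' Preset quality tiers for the four sample types
#'
#' Four tiers emulating the quality gradient from pristine ear tissue
#' through plucked hair and colon-collected feces down to field-collected
#' fecal pellets. Mean depths follow the per-type depths reported for an
#' optimised noninvasive amplicon panel (hair 176, colon feces 119, field
#' feces 96 reads/locus); dropout probabilities increase down the
#' gradient so that genotyping success orders tissue > hair > colon
#' feces > field feces; error rates are typical Illumina substitution
#' scales inflated slightly for degraded templates.
#'
#' @param name optional tier name to return; default returns the named
#'   list of all four.
#' @return A named list of [SampleQualityTier-class], or one tier.
#' @examples
#' qualityTierPresets("field_feces")
#' @export
qualityTierPresets <- function(name = NULL) {
  presets <- list(
    tissue      = sampleQualityTier("tissue",      0.80, 250, 0.010, 0.001),
    hair        = sampleQualityTier("hair",        0.60, 176, 0.040, 0.002),
    colon_feces = sampleQualityTier("colon_feces", 0.55, 119, 0.080, 0.002),
    field_feces = sampleQualityTier("field_feces", 0.50,  96, 0.120, 0.003))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown tier '", name, "'; valid tiers: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Relationship categories and their IBD-sharing distributions
#'
#' The five dyad categories used throughout panel design: parent-
#' offspring (PO), full siblings (FS), half siblings (HS), first cousins
#' (FC) and unrelated (UR). For each, the probability that a locus shares
#' 0, 1 or 2 alleles identical by descent, and the expected kinship
#' coefficient (half the expected IBD alleles / 2).
#'
#' @param code optional category code; default returns the full table.
#' @return A data.frame with columns `code`, `ibd0`, `ibd1`, `ibd2`,
#'   `expectedKinship`, or the single matching row.
#' @examples
#' relationshipCategories("FS")
#' @export
relationshipCategories <- function(code = NULL) {
  tab <- data.frame(
    code = c("PO", "FS", "HS", "FC", "UR"),
    ibd0 = c(0, 0.25, 0.50, 0.75, 1),
    ibd1 = c(1, 0.50, 0.50, 0.25, 0),
    ibd2 = c(0, 0.25, 0,    0,    0),
    expectedKinship = c(0.25, 0.25, 0.125, 0.0625, 0),
    stringsAsFactors = FALSE)
  if (is.null(code)) return(tab)
  hit <- tab[tab$code == code, , drop = FALSE]
  if (!nrow(hit))
    stop("unknown relationship category '", code, "'; valid: ",
         paste(tab$code, collapse = ", "))
  hit
}

# degree labels used when PO/FS are pooled as first-degree relatives
relatednessDegree <- function(code) {
  c(PO = "first", FS = "first", HS = "second", FC = "third",
    UR = "unrelated")[code]
}
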