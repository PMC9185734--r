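#' Screen loci for sex-associated allele-frequency differentials
#'
#' Flags loci whose allele-frequency difference between males and
#' females meets or exceeds `cutoff` (default 0.20, the conventional
#' screening differential for sex-associated SNP candidates). Both sex
#' strata must be present for every locus.
#'
#' @param freqs an [AlleleFrequencyTable-class] with `male` and `female`
#'   strata (as produced by [alleleFrequencies()] with a sex grouping or
#'   by [simulateSexLoci()]).
#' @param cutoff minimum absolute differential for selection.
#' @param maleStratum,femaleStratum stratum column names.
#' @return A data.frame (`locus_id`, `pMale`, `pFemale`, `differential`,
#'   `selected`), one row per locus.
#' @examples
#' aft <- AlleleFrequencyTable("L1", 0.4,
#'                             cbind(male = 0.55, female = 0.30))
#' screenSexMarkers(aft)
#' @export
screenSexMarkers <- function(freqs, cutoff = 0.20, maleStratum = "male",
                             femaleStratum = "female") {
  sm <- strataFreq(freqs)
  for (nm in c(maleStratum, femaleStratum))
    if (!nm %in% colnames(sm))
      stop("frequency table lacks stratum '", nm, "'")
  pm <- sm[, maleStratum]
  pf <- sm[, femaleStratum]
  bad <- which(!is.finite(pm) | !is.finite(pf))
  if (length(bad))
    stop("locus missing a sex stratum frequency: ",
         paste(locusIds(freqs)[utils::head(bad, 5L)], collapse = ", "))
  d <- abs(pm - pf)
  data.frame(locus_id = locusIds(freqs), pMale = unname(pm),
             pFemale = unname(pf), differential = unname(d),
             selected = unname(d >= cutoff))
}
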