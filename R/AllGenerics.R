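#' @rdname AlleleFrequencyTable
#' @param object an object.
#' @export
setGeneric("locusIds", function(object) standardGeneric("locusIds"))

#' @rdname AlleleFrequencyTable
#' @export
setGeneric("alleleFreq", function(object) standardGeneric("alleleFreq"))

#' @rdname AlleleFrequencyTable
#' @export
setGeneric("pMinor", function(object) standardGeneric("pMinor"))

#' @rdname AlleleFrequencyTable
#' @export
setGeneric("strataFreq", function(object) standardGeneric("strataFreq"))

#' @rdname AlleleFrequencyTable
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))

#' @rdname GenotypeMatrix
#' @param object an object.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("sampleType", function(object) standardGeneric("sampleType"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("individualId", function(object) standardGeneric("individualId"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("missingFraction",
           function(object, by = c("sample", "locus"))
             standardGeneric("missingFraction"))

#' @rdname AmpliconPanel
#' @param object an object.
#' @export
setGeneric("fwdPrimer", function(object) standardGeneric("fwdPrimer"))

#' @rdname AmpliconPanel
#' @export
setGeneric("probeAllele1", function(object) standardGeneric("probeAllele1"))

#' @rdname AmpliconPanel
#' @export
setGeneric("probeAllele2", function(object) standardGeneric("probeAllele2"))

#' @rdname GenotypeCallReport
#' @param object an object.
#' @export
setGeneric("genotypeCalls", function(object) standardGeneric("genotypeCalls"))

#' @rdname DyadSimulationResult
#' @param object an object.
#' @export
setGeneric("confusionMatrix",
           function(object) standardGeneric("confusionMatrix"))

#' @rdname DyadSimulationResult
#' @export
setGeneric("assignmentAccuracy",
           function(object, by = c("category", "degree"))
             standardGeneric("assignmentAccuracy"))

#' @rdname IdentityPowerCurve
#' @param object an object.
#' @export
setGeneric("minPanelSize", function(object) standardGeneric("minPanelSize"))

#' @rdname IdentityPowerCurve
#' @export
setGeneric("powerCurve", function(object) standardGeneric("powerCurve"))
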