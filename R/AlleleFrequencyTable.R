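#' Construct an AlleleFrequencyTable
#'
#' @param locusId character vector of unique locus identifiers.
#' @param p1 numeric vector of allele-1 frequencies in \[0,1\]. In tables
#'   produced by [drawFrequencySpectrum()] allele 1 is the minor allele.
#' @param strata optional numeric matrix (loci x strata, named columns)
#'   of allele-1 frequencies per stratum, e.g. `male` / `female`.
#' @return An [AlleleFrequencyTable-class] object.
#' @examples
#' aft <- AlleleFrequencyTable(c("L1", "L2"), c(0.45, 0.10))
#' pMinor(aft)
#' @export
AlleleFrequencyTable <- function(locusId, p1, strata = NULL) {
  if (is.null(strata))
    strata <- matrix(numeric(), nrow = length(locusId), ncol = 0L)
  strata <- as.matrix(strata)
  if (is.null(rownames(strata)) && nrow(strata) == length(locusId) &&
      ncol(strata) > 0L)
    rownames(strata) <- locusId
  new("AlleleFrequencyTable", locusId = as.character(locusId),
      p1 = as.numeric(p1), strata = strata)
}

#' @rdname AlleleFrequencyTable
#' @export
setMethod("locusIds", "AlleleFrequencyTable", function(object) object@locusId)

#' @rdname AlleleFrequencyTable
#' @export
setMethod("alleleFreq", "AlleleFrequencyTable", function(object) {
  stats::setNames(object@p1, object@locusId)
})

#' @rdname AlleleFrequencyTable
#' @export
setMethod("pMinor", "AlleleFrequencyTable", function(object) {
  stats::setNames(pmin(object@p1, 1 - object@p1), object@locusId)
})

#' @rdname AlleleFrequencyTable
#' @export
setMethod("strataFreq", "AlleleFrequencyTable", function(object) object@strata)

#' @rdname AlleleFrequencyTable
#' @export
setMethod("nLoci", "AlleleFrequencyTable",
          function(object) length(object@locusId))

#' @rdname AlleleFrequencyTable
#' @param x an AlleleFrequencyTable.
#' @param i index or locus-id subset.
#' @export
setMethod("[", "AlleleFrequencyTable", function(x, i) {
  if (is.character(i)) i <- match(i, x@locusId)
  AlleleFrequencyTable(x@locusId[i], x@p1[i],
                       if (ncol(x@strata)) x@strata[i, , drop = FALSE])
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  cat(sprintf("AlleleFrequencyTable: %d loci", nLoci(object)))
  if (ncol(object@strata))
    cat(sprintf(", strata: %s", paste(colnames(object@strata),
                                      collapse = ", ")))
  cat("\n")
  pm <- pMinor(object)
  if (length(pm))
    cat(sprintf("  minor-allele frequency: %.3f - %.3f (median %.3f)\n",
                min(pm), max(pm), stats::median(pm)))
})

#' Write / read an allele-frequency table as TSV
#'
#' Columns: `locus_id`, `p1`, then one column per stratum. Round-trips
#' through [readAlleleFrequencyTable()] losslessly.
#'
#' @param aft an [AlleleFrequencyTable-class].
#' @param path file path.
#' @return `writeAlleleFrequencyTable` returns `path` invisibly;
#'   `readAlleleFrequencyTable` returns an [AlleleFrequencyTable-class].
#' @export
writeAlleleFrequencyTable <- function(aft, path) {
  df <- data.frame(locus_id = locusIds(aft), p1 = aft@p1)
  if (ncol(aft@strata)) df <- cbind(df, as.data.frame(aft@strata))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlleleFrequencyTable
#' @export
readAlleleFrequencyTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("locus_id", "p1") %in% names(df)))
    stop("frequency TSV must have columns locus_id and p1")
  extra <- setdiff(names(df), c("locus_id", "p1"))
  strata <- if (length(extra)) as.matrix(df[extra]) else NULL
  AlleleFrequencyTable(df$locus_id, df$p1, strata)
}
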