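#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix (loci x samples) of allele-1 copy counts
#'   (0/1/2, `NA` = missing), with row and column names.
#' @param sampleType,method,individualId,sex optional per-sample metadata
#'   vectors (recycled if length 1).
#' @param allele1,allele2 per-locus allele labels used when genotypes are
#'   serialised as allele pairs (default "A"/"B").
#' @return A [GenotypeMatrix-class].
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' gm <- GenotypeMatrix(d)
#' missingFraction(gm, "sample")
#' @export
GenotypeMatrix <- function(dosage, sampleType = NULL, method = NULL,
                           individualId = NULL, sex = NULL,
                           allele1 = "A", allele2 = "B") {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("locus_%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("sample_%03d", seq_len(ncol(dosage)))
  cd <- DataFrame(row.names = colnames(dosage))
  for (nm in c("sampleType", "method", "individualId", "sex")) {
    v <- get(nm)
    if (!is.null(v)) cd[[nm]] <- rep(v, length.out = ncol(dosage))
  }
  rd <- DataFrame(allele1 = rep(allele1, length.out = nrow(dosage)),
                  allele2 = rep(allele2, length.out = nrow(dosage)),
                  row.names = rownames(dosage))
  new("GenotypeMatrix",
      SummarizedExperiment(assays = list(dosage = dosage),
                           colData = cd, rowData = rd))
}

#' @rdname GenotypeMatrix
#' @export
setMethod("dosage", "GenotypeMatrix",
          function(object) assay(object, "dosage"))

#' @rdname GenotypeMatrix
#' @export
setMethod("sampleType", "GenotypeMatrix", function(object) {
  cd <- colData(object)
  if ("sampleType" %in% colnames(cd)) cd$sampleType else NULL
})

#' @rdname GenotypeMatrix
#' @export
setMethod("individualId", "GenotypeMatrix", function(object) {
  cd <- colData(object)
  if ("individualId" %in% colnames(cd)) cd$individualId else NULL
})

#' @rdname GenotypeMatrix
#' @param by `"sample"` or `"locus"`.
#' @export
setMethod("missingFraction", "GenotypeMatrix", function(object, by) {
  by <- match.arg(by, c("sample", "locus"))
  d <- dosage(object)
  if (by == "sample") colMeans(is.na(d)) else rowMeans(is.na(d))
})

#' @rdname GenotypeMatrix
#' @export
setMethod("nLoci", "GenotypeMatrix", function(object) nrow(object))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dosage(object)
  cat(sprintf("GenotypeMatrix: %d loci x %d samples, %.1f%% missing\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  extras <- intersect(c("sampleType", "method", "individualId", "sex"),
                      colnames(colData(object)))
  if (length(extras))
    cat("  sample metadata:", paste(extras, collapse = ", "), "\n")
})

#' Allele frequencies observed in a genotype matrix
#'
#' Computes per-locus allele-1 frequencies from called genotypes,
#' optionally stratified by a per-sample grouping (e.g. sex). Loci with
#' no called genotype get frequency `NA`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param strata optional per-sample grouping vector (length = samples).
#' @return An [AlleleFrequencyTable-class].
#' @export
alleleFrequencies <- function(gm, strata = NULL) {
  d <- dosage(gm)
  p1 <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  sm <- NULL
  if (!is.null(strata)) {
    strata <- as.character(strata)
    stopifnot(length(strata) == ncol(d))
    lv <- unique(strata)
    sm <- vapply(lv, function(g) {
      dg <- d[, strata == g, drop = FALSE]
      rowSums(dg, na.rm = TRUE) / (2 * rowSums(!is.na(dg)))
    }, numeric(nrow(d)))
    colnames(sm) <- lv
  }
  AlleleFrequencyTable(rownames(d), p1, sm)
}

#' Write / read a GenotypeMatrix as TSV
#'
#' Loci are rows and samples are columns, following population-genetics
#' convention. Each cell is an allele pair such as `"A/B"` built from the
#' locus's allele labels (allele 1 listed first), `NA` for missing. A
#' `dosage` column repeats the allele-1 copy count of the first sample
#' for quick eyeballing. Sample metadata columns, when present, are
#' written to `<path>.samples.tsv` alongside, and picked up again by
#' [readGenotypeMatrix()].
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output TSV path.
#' @return `writeGenotypeMatrix` returns `path` invisibly;
#'   `readGenotypeMatrix` returns a [GenotypeMatrix-class].
#' @export
writeGenotypeMatrix <- function(gm, path) {
  d <- dosage(gm)
  rd <- rowData(gm)
  pair <- function(dos, a1, a2)
    ifelse(is.na(dos), NA_character_,
           ifelse(dos == 2L, paste0(a1, "/", a1),
                  ifelse(dos == 1L, paste0(a1, "/", a2),
                         paste0(a2, "/", a2))))
  cells <- vapply(seq_len(ncol(d)),
                  function(j) pair(d[, j], rd$allele1, rd$allele2),
                  character(nrow(d)))
  cells <- matrix(cells, nrow = nrow(d), dimnames = dimnames(d))
  df <- data.frame(locus_id = rownames(d), allele1 = rd$allele1,
                   allele2 = rd$allele2, dosage = d[, 1L],
                   cells, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  cd <- colData(gm)
  if (ncol(cd)) {
    sdf <- cbind(data.frame(sample_id = rownames(cd)), as.data.frame(cd))
    utils::write.table(sdf, paste0(path, ".samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  fixed <- c("locus_id", "allele1", "allele2", "dosage")
  if (!all(fixed %in% names(df)))
    stop("genotype TSV lacks required columns: ",
         paste(setdiff(fixed, names(df)), collapse = ", "))
  samples <- setdiff(names(df), fixed)
  d <- matrix(NA_integer_, nrow(df), length(samples),
              dimnames = list(df$locus_id, samples))
  for (j in seq_along(samples)) {
    cell <- df[[samples[j]]]
    a1 <- df$allele1
    left  <- sub("/.*", "", cell)
    right <- sub(".*/", "", cell)
    d[, j] <- ifelse(is.na(cell), NA_integer_,
                     (left == a1) + (right == a1))
  }
  gm <- GenotypeMatrix(d, allele1 = df$allele1, allele2 = df$allele2)
  spath <- paste0(path, ".samples.tsv")
  if (file.exists(spath)) {
    sdf <- utils::read.table(spath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "NA")
    sdf <- sdf[match(colnames(d), sdf$sample_id), , drop = FALSE]
    for (nm in setdiff(names(sdf), "sample_id"))
      colData(gm)[[nm]] <- sdf[[nm]]
  }
  gm
}
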