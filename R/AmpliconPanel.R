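#' Construct an AmpliconPanel
#'
#' @param locusId character vector of unique locus ids.
#' @param fwdPrimer,probeAllele1,probeAllele2 character vectors or
#'   [Biostrings::DNAStringSet]s (uppercase ACGT) of the forward primer
#'   and the two allele probes, in read orientation.
#' @return An [AmpliconPanel-class].
#' @export
AmpliconPanel <- function(locusId, fwdPrimer, probeAllele1, probeAllele2) {
  as_set <- function(x) {
    s <- DNAStringSet(toupper(as.character(x)))
    names(s) <- locusId
    s
  }
  new("AmpliconPanel", locusId = as.character(locusId),
      fwdPrimer = as_set(fwdPrimer), probeAllele1 = as_set(probeAllele1),
      probeAllele2 = as_set(probeAllele2))
}

#' @rdname AmpliconPanel
#' @export
setMethod("locusIds", "AmpliconPanel", function(object) object@locusId)

#' @rdname AmpliconPanel
#' @export
setMethod("nLoci", "AmpliconPanel", function(object) length(object@locusId))

#' @rdname AmpliconPanel
#' @export
setMethod("fwdPrimer", "AmpliconPanel", function(object) object@fwdPrimer)

#' @rdname AmpliconPanel
#' @export
setMethod("probeAllele1", "AmpliconPanel",
          function(object) object@probeAllele1)

#' @rdname AmpliconPanel
#' @export
setMethod("probeAllele2", "AmpliconPanel",
          function(object) object@probeAllele2)

setMethod("show", "AmpliconPanel", function(object) {
  cat(sprintf("AmpliconPanel: %d loci, primer widths %s\n", nLoci(object),
              paste(range(Biostrings::width(object@fwdPrimer)),
                    collapse = "-")))
})

#' Write / read a panel definition TSV
#'
#' Columns: `locus_id`, `fwd_primer`, `probe_allele1`, `probe_allele2`.
#'
#' @param panel an [AmpliconPanel-class].
#' @param path file path.
#' @export
writeAmpliconPanel <- function(panel, path) {
  df <- data.frame(locus_id = locusIds(panel),
                   fwd_primer = as.character(fwdPrimer(panel)),
                   probe_allele1 = as.character(probeAllele1(panel)),
                   probe_allele2 = as.character(probeAllele2(panel)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAmpliconPanel
#' @export
readAmpliconPanel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("locus_id", "fwd_primer", "probe_allele1", "probe_allele2")
  if (!all(need %in% names(df)))
    stop("panel TSV lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  AmpliconPanel(df$locus_id, df$fwd_primer, df$probe_allele1,
                df$probe_allele2)
}

#' Generate a synthetic amplicon panel for a set of loci
#'
#' Draws, per locus, a random forward primer (15-17 bp, the width range
#' typical of highly multiplexed amplicon designs) and a probe backbone
#' with the SNP at its centre, emitting the two allele-specific probe
#' variants. Primer and probe sequences are drawn until unique across the
#' panel so that exact-substring genotyping is unambiguous.
#'
#' @param locusId character vector of locus ids.
#' @param seed integer seed.
#' @param primerWidth integer vector of admissible primer widths.
#' @param probeWidth odd probe width (SNP at the centre base).
#' @return An [AmpliconPanel-class].
#' @export
simulateAmpliconPanel <- function(locusId, seed, primerWidth = 15:17,
                                  probeWidth = 13L) {
  stopifnot(probeWidth %% 2L == 1L)
  withr::with_seed(seed, {
    n <- length(locusId)
    rand_seq <- function(w) paste(sample(c("A", "C", "G", "T"), w,
                                         replace = TRUE), collapse = "")
    draw_unique <- function(n, widths, taken = character()) {
      out <- character(0)
      while (length(out) < n) {
        cand <- rand_seq(sample(rep(widths, 2L), 1L))
        if (!cand %in% c(out, taken)) out <- c(out, cand)
      }
      out
    }
    primers <- draw_unique(n, primerWidth)
    backbones <- draw_unique(n, probeWidth, primers)
    mid <- (probeWidth + 1L) / 2L
    p1 <- p2 <- backbones
    for (i in seq_len(n)) {
      ref <- substr(backbones[i], mid, mid)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      substr(p2[i], mid, mid) <- alt
    }
    AmpliconPanel(locusId, primers, p1, p2)
  })
}
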