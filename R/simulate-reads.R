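#' Simulate per-sample amplicon read sets
#'
#' For every sample and panel locus, sequencing depth is drawn negative-
#' binomially around the tier's mean depth (dispersion `nbDispersion`),
#' set to zero with the tier's dropout probability. Each on-target read
#' is the locus's forward primer followed by one allele probe and random
#' filler up to `readLength`, with per-base substitution errors at the
#' tier's error rate; heterozygotes emit allele 1 with probability
#' `alleleBias`. Off-target reads are uniform random nucleotides, added
#' so that the expected on-target share equals the tier's
#' `onTargetFraction`. An emission ledger records the true allele counts
#' per sample and locus, which downstream tests use as an exact oracle.
#'
#' @param panel an [AmpliconPanel-class]; every genotype locus must be
#'   present in it.
#' @param genotypes a [GenotypeMatrix-class] (loci x samples).
#' @param tier a [SampleQualityTier-class].
#' @param seed integer seed.
#' @param readLength read length in bases (default 75, single-end).
#' @param alleleBias probability a heterozygote read carries allele 1.
#' @param nbDispersion negative-binomial dispersion (size) of depth;
#'   `Inf` gives Poisson depths.
#' @return A list: `reads`, a named list of per-sample read character
#'   vectors; `ledger`, a data.frame (`sample`, `locus`, `trueDosage`,
#'   `emittedA1`, `emittedA2`, `depth`); `offTarget`, named integer of
#'   off-target read counts per sample; and the simulation parameters.
#' @export
simulateAmpliconReads <- function(panel, genotypes, tier, seed,
                                  readLength = 75L, alleleBias = 0.5,
                                  nbDispersion = 5) {
  if (nLoci(panel) == 0L) stop("panel is empty")
  d <- dosage(genotypes)
  if (!all(rownames(d) %in% locusIds(panel)))
    stop("genotype loci absent from panel: ",
         paste(utils::head(setdiff(rownames(d), locusIds(panel)), 5L),
               collapse = ", "))
  primer <- as.character(fwdPrimer(panel))
  probe1 <- as.character(probeAllele1(panel))
  probe2 <- as.character(probeAllele2(panel))
  names(primer) <- names(probe1) <- names(probe2) <- locusIds(panel)
  bases <- c("A", "C", "G", "T")

  rand_filler <- function(n, w) {
    if (n == 0L || w <= 0L) return(rep("", n))
    vapply(seq_len(n), function(i)
      paste(sample(bases, w, replace = TRUE), collapse = ""), character(1L))
  }
  mutate_reads <- function(reads, rate) {
    if (rate <= 0 || !length(reads)) return(reads)
    nerr <- stats::rbinom(length(reads), nchar(reads), rate)
    idx <- which(nerr > 0L)
    for (i in idx) {
      pos <- sample.int(nchar(reads[i]), nerr[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      ch[pos] <- vapply(ch[pos],
                        function(b) sample(setdiff(bases, b), 1L),
                        character(1L))
      reads[i] <- paste(ch, collapse = "")
    }
    reads
  }

  withr::with_seed(seed, {
    reads <- vector("list", ncol(d))
    names(reads) <- colnames(d)
    off_target <- stats::setNames(integer(ncol(d)), colnames(d))
    ledger <- vector("list", ncol(d))
    for (j in seq_len(ncol(d))) {
      loci <- rownames(d)
      depth <- if (is.infinite(nbDispersion))
        stats::rpois(length(loci), tier@meanDepth)
      else
        stats::rnbinom(length(loci), size = nbDispersion,
                       mu = tier@meanDepth)
      depth[stats::runif(length(loci)) < tier@dropoutProb] <- 0L
      n_a1 <- integer(length(loci))
      sample_reads <- vector("list", length(loci))
      for (l in seq_along(loci)) {
        if (depth[l] == 0L) next
        g <- d[l, j]
        p_a1 <- if (is.na(g)) { depth[l] <- 0L; next
        } else if (g == 2L) 1 else if (g == 0L) 0 else alleleBias
        n_a1[l] <- stats::rbinom(1L, depth[l], p_a1)
        probes <- c(rep(probe1[loci[l]], n_a1[l]),
                    rep(probe2[loci[l]], depth[l] - n_a1[l]))
        core <- paste0(primer[loci[l]], probes)
        fill <- pmax(readLength - nchar(core), 0L)
        sample_reads[[l]] <- substr(paste0(core, rand_filler(depth[l],
                                                             max(fill))),
                                    1L, readLength)
      }
      on <- unlist(sample_reads, use.names = FALSE)
      on <- mutate_reads(on, tier@errorRate)
      n_off <- if (tier@onTargetFraction >= 1 || !length(on)) 0L
      else stats::rnbinom(1L, size = length(on),
                          prob = tier@onTargetFraction)
      off <- rand_filler(n_off, readLength)
      all_reads <- c(on, off)
      if (length(all_reads)) all_reads <- sample(all_reads)
      reads[[j]] <- all_reads
      off_target[j] <- n_off
      ledger[[j]] <- data.frame(sample = colnames(d)[j], locus = loci,
                                trueDosage = d[, j], emittedA1 = n_a1,
                                emittedA2 = depth - n_a1, depth = depth,
                                row.names = NULL)
    }
  })
  list(reads = reads, ledger = do.call(rbind, ledger),
       offTarget = off_target, tier = tier, readLength = readLength,
       seed = seed)
}

#' Write simulated reads as 4-line FASTQ files
#'
#' One `<sample>.fastq` per sample, plain text, with dummy Phred+33
#' qualities (`I` = Q40).
#'
#' @param sim result of [simulateAmpliconReads()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
writeSimulatedFastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, paste0(names(sim$reads),
                                                 ".fastq")),
                           names(sim$reads))
  for (s in names(sim$reads)) {
    r <- sim$reads[[s]]
    if (length(r)) {
      rec <- rbind(sprintf("@%s_read%06d", s, seq_along(r)), r, "+",
                   strrep("I", nchar(r)))
      writeLines(as.vector(rec), paths[[s]])
    } else writeLines(character(0), paths[[s]])
  }
  paths
}

#' Read a 4-line FASTQ file into a character vector of sequences
#'
#' Accepts plain or gzip-compressed files. Each record is validated
#' (header starting `@`, separator starting `+`, sequence/quality length
#' agreement); a malformed record raises an error naming its index.
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return Character vector of read sequences.
#' @export
readFastqSequences <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: record ", length(lines) %/% 4L + 1L,
         " is incomplete in ", path)
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- which(!startsWith(lines[idx], "@"))
  if (length(bad_hdr))
    stop("malformed FASTQ record ", bad_hdr[1L], " in ", path,
         ": header does not start with '@'")
  bad_sep <- which(!startsWith(lines[idx + 2L], "+"))
  if (length(bad_sep))
    stop("malformed FASTQ record ", bad_sep[1L], " in ", path,
         ": separator does not start with '+'")
  bad_len <- which(nchar(lines[idx + 1L]) != nchar(lines[idx + 3L]))
  if (length(bad_len))
    stop("malformed FASTQ record ", bad_len[1L], " in ", path,
         ": sequence and quality lengths differ")
  toupper(lines[idx + 1L])
}
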