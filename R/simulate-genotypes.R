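#' Minor-allele-frequency bins used in panel design
#'
#' @return A named list of `c(lo, hi)` frequency bounds for the `low`,
#'   `moderate` and `high` bins; the `proportional` bin mixes the three.
#' @export
mafBins <- function() {
  list(low = c(0.00, 0.10), moderate = c(0.20, 0.30), high = c(0.40, 0.49))
}

#' Draw a minor-allele-frequency spectrum
#'
#' Draws per-locus minor-allele frequencies uniformly within a MAF bin
#' (`low` = 0.00-0.10, `moderate` = 0.20-0.30, `high` = 0.40-0.49), or,
#' for `proportional`, assigns each locus to one of the three bins with
#' configurable weights before drawing within it.
#'
#' @param nLoci number of loci (>= 1).
#' @param bin one of `"low"`, `"moderate"`, `"high"`, `"proportional"`.
#' @param seed integer seed.
#' @param weights bin mixing weights for `proportional` (default equal
#'   thirds), in the order low, moderate, high.
#' @return An [AlleleFrequencyTable-class]; allele 1 is the minor allele.
#' @examples
#' pMinor(drawFrequencySpectrum(5, "high", seed = 1))
#' @export
drawFrequencySpectrum <- function(nLoci, bin, seed,
                                  weights = c(1, 1, 1) / 3) {
  if (nLoci < 1) stop("nLoci must be >= 1")
  bins <- mafBins()
  valid <- c(names(bins), "proportional")
  if (!bin %in% valid)
    stop("unknown MAF bin '", bin, "'; valid bins: ",
         paste(valid, collapse = ", "))
  withr::with_seed(seed, {
    if (bin == "proportional") {
      member <- sample(names(bins), nLoci, replace = TRUE,
                       prob = weights / sum(weights))
      p <- vapply(member, function(b)
        stats::runif(1L, bins[[b]][1L], bins[[b]][2L]), numeric(1L))
    } else {
      p <- stats::runif(nLoci, bins[[bin]][1L], bins[[bin]][2L])
    }
    AlleleFrequencyTable(sprintf("locus_%04d", seq_len(nLoci)),
                         unname(p))
  })
}

#' Simulate unrelated genotypes under Hardy-Weinberg equilibrium
#'
#' At each locus, genotype dosages are drawn Binomial(2, p): genotype
#' frequencies p^2, 2pq, q^2. No missingness is introduced.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param nSamples number of individuals (>= 1).
#' @param seed integer seed.
#' @param sampleIds optional sample names.
#' @return A [GenotypeMatrix-class] (loci x samples).
#' @export
simulatePopulationGenotypes <- function(freqs, nSamples, seed,
                                        sampleIds = NULL) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  p <- alleleFreq(freqs)
  withr::with_seed(seed, {
    d <- matrix(stats::rbinom(length(p) * nSamples, 2L, rep(p, nSamples)),
                nrow = length(p), ncol = nSamples)
  })
  rownames(d) <- locusIds(freqs)
  colnames(d) <- sampleIds %||% sprintf("ind_%04d", seq_len(nSamples))
  GenotypeMatrix(d)
}

# Vectorised dyad simulation: n dyads at L loci for one relationship
# category. Individual 1 is drawn HWE; at each locus k ~ IBD distribution
# alleles of individual 2 are copied from individual 1 (a random one of
# its two if k = 1, both if k = 2), the rest drawn from the population.
# Returns dosage matrices (dyads x loci) plus the realised IBD states.
.simulateDyadBatch <- function(p, category, nDyads, seed) {
  cat_row <- relationshipCategories(category)
  L <- length(p)
  withr::with_seed(seed, {
    P <- matrix(p, nrow = nDyads, ncol = L, byrow = TRUE)
    a11 <- matrix(stats::rbinom(nDyads * L, 1L, P), nDyads, L)
    a12 <- matrix(stats::rbinom(nDyads * L, 1L, P), nDyads, L)
    k <- matrix(sample(0:2, nDyads * L, replace = TRUE,
                       prob = c(cat_row$ibd0, cat_row$ibd1, cat_row$ibd2)),
                nDyads, L)
    pick1 <- matrix(stats::rbinom(nDyads * L, 1L, 0.5), nDyads, L)
    shared <- ifelse(pick1 == 1L, a11, a12)
    other  <- ifelse(pick1 == 1L, a12, a11)
    fresh1 <- matrix(stats::rbinom(nDyads * L, 1L, P), nDyads, L)
    fresh2 <- matrix(stats::rbinom(nDyads * L, 1L, P), nDyads, L)
    b1 <- ifelse(k >= 1L, shared, fresh1)
    b2 <- ifelse(k == 2L, other, fresh2)
    list(g1 = a11 + a12, g2 = b1 + b2, ibd = k)
  })
}

#' Simulate one relationship-labelled dyad
#'
#' Individual 1 is drawn under Hardy-Weinberg equilibrium; at each locus
#' the number of alleles individual 2 shares identical-by-descent with
#' individual 1 is drawn from the category's IBD distribution (one
#' randomly chosen allele is copied when one is shared, both when two),
#' and the remaining alleles are drawn from the population frequencies.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param category one of `"PO"`, `"FS"`, `"HS"`, `"FC"`, `"UR"`.
#' @param seed integer seed.
#' @return A list with dosage vectors `g1` and `g2` (named by locus) and
#'   `ibd`, the realised per-locus IBD allele counts.
#' @examples
#' dy <- simulateDyad(drawFrequencySpectrum(20, "high", 1), "PO", seed = 2)
#' all(dy$ibd == 1)  # parent-offspring share exactly one allele per locus
#' @export
simulateDyad <- function(freqs, category, seed) {
  b <- .simulateDyadBatch(alleleFreq(freqs), category, 1L, seed)
  list(g1 = stats::setNames(as.integer(b$g1[1L, ]), locusIds(freqs)),
       g2 = stats::setNames(as.integer(b$g2[1L, ]), locusIds(freqs)),
       ibd = stats::setNames(as.integer(b$ibd[1L, ]), locusIds(freqs)))
}

#' Simulate a batch of dyads of one relationship category
#'
#' Vectorised form of [simulateDyad()] used by the kinship sensitivity
#' analysis.
#'
#' @inheritParams simulateDyad
#' @param nDyads number of dyads.
#' @return A list of `nDyads` x `nLoci` matrices `g1`, `g2` (dosages) and
#'   `ibd` (realised IBD allele counts).
#' @export
simulateDyads <- function(freqs, category, nDyads, seed) {
  .simulateDyadBatch(alleleFreq(freqs), category, nDyads, seed)
}

#' Simulate sex-differentiated loci
#'
#' Constructs loci whose allele-1 frequency differs between the sexes by
#' exactly `differential`: the female frequency is drawn uniformly on
#' \[0, 1 - differential\] and the male frequency is offset upward by
#' `differential`. Genotypes are drawn per sex under Hardy-Weinberg
#' equilibrium at the sex-specific frequency. A differential of 1 yields
#' fixed differences (gametolog-like markers: all females 0, all males
#' 2); intermediate values model partial sex linkage.
#'
#' @param nLoci number of sex-informative loci (default 8, the screening
#'   yield typical of a RADseq scan at a 0.20 differential cutoff).
#' @param differential per-sex allele-frequency difference in (0, 1\].
#' @param nMales,nFemales cohort sizes (>= 1).
#' @param seed integer seed.
#' @return A list: `genotypes` (a [GenotypeMatrix-class] with a `sex`
#'   column), `sex` (per-sample labels) and `freqs` (an
#'   [AlleleFrequencyTable-class] with `male` / `female` strata holding
#'   the construction frequencies).
#' @export
simulateSexLoci <- function(nLoci = 8L, differential = 0.20, nMales,
                            nFemales, seed) {
  if (differential <= 0 || differential > 1)
    stop("differential must lie in (0, 1]")
  if (nMales < 1 || nFemales < 1)
    stop("nMales and nFemales must be >= 1")
  withr::with_seed(seed, {
    pf <- stats::runif(nLoci, 0, 1 - differential)
    pm <- pmin(pf + differential, 1)
    dm <- matrix(stats::rbinom(nLoci * nMales, 2L, rep(pm, nMales)),
                 nLoci, nMales)
    df <- matrix(stats::rbinom(nLoci * nFemales, 2L, rep(pf, nFemales)),
                 nLoci, nFemales)
  })
  d <- cbind(dm, df)
  rownames(d) <- sprintf("sexlocus_%02d", seq_len(nLoci))
  colnames(d) <- c(sprintf("male_%03d", seq_len(nMales)),
                   sprintf("female_%03d", seq_len(nFemales)))
  sex <- c(rep("male", nMales), rep("female", nFemales))
  freqs <- AlleleFrequencyTable(rownames(d), (pm + pf) / 2,
                                cbind(male = pm, female = pf))
  list(genotypes = GenotypeMatrix(d, sex = sex), sex = sex, freqs = freqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
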