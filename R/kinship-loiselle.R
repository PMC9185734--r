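#' Pairwise kinship by the Loiselle allele-frequency-correlation estimator
#'
#' Estimates, for every pair of samples, the correlation of allele
#' frequencies within individuals relative to a reference population —
#' the relative probability of allelic identity by descent. Per locus
#' and allele, with `x` an individual's allele dosage divided by two and
#' `p` the reference allele frequency, the pair contributes
#' `(x_i - p)(x_j - p) + p(1-p)/(n-1)` to the numerator (the second term
#' is the original small-sample bias correction, with `n` the number of
#' gene copies behind the reference frequencies) and `p(1-p)` to the
#' denominator; locus contributions are pooled as a ratio of sums, which
#' weights loci by their polymorphism as in the original estimator.
#' Expected values are 0.25 for parent-offspring and full siblings,
#' 0.125 for half siblings, 0.0625 for first cousins and 0 for unrelated
#' pairs.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param freqs optional external reference [AlleleFrequencyTable-class]
#'   covering every locus; by default frequencies are computed from `gm`
#'   itself, as population programs do.
#' @param refGeneCopies gene-copy count `n` for the bias term. Defaults
#'   to twice the sample count when frequencies come from `gm`, and to
#'   `Inf` (no bias term) for externally supplied frequencies.
#' @return A symmetric samples-by-samples matrix of kinship estimates
#'   with `NA` on the diagonal (self-kinship is not reported) and for
#'   pairs sharing no called polymorphic locus. The reference
#'   frequencies used are attached as attribute `"freqs"`.
#' @export
loiselleKinship <- function(gm, freqs = NULL, refGeneCopies = NULL) {
  internal <- is.null(freqs)
  if (internal) freqs <- alleleFrequencies(gm)
  if (is.null(refGeneCopies))
    refGeneCopies <- if (internal) 2 * ncol(gm) else Inf
  d <- dosage(gm)
  if (!all(rownames(d) %in% locusIds(freqs)))
    stop("reference frequencies missing for locus: ",
         paste(utils::head(setdiff(rownames(d), locusIds(freqs)), 5L),
               collapse = ", "))
  p <- alleleFreq(freqs)[rownames(d)]
  poly <- is.finite(p) & p > 0 & p < 1
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  bias <- if (is.finite(refGeneCopies)) p * (1 - p) / (refGeneCopies - 1)
          else rep(0, length(p))
  S <- ncol(d)
  x <- sweep(d / 2, 1L, p)  # loci x samples, centred half-dosages
  K <- matrix(NA_real_, S, S, dimnames = list(colnames(d), colnames(d)))
  den_l <- p * (1 - p)
  called <- !is.na(x)
  x0 <- ifelse(called, x, 0)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j <= i) next
      both <- called[, i] & called[, j]
      if (!any(both)) next
      num <- sum(x0[both, i] * x0[both, j] + bias[both])
      den <- sum(den_l[both])
      K[i, j] <- K[j, i] <- num / den
    }
  }
  attr(K, "freqs") <- freqs
  K
}

#' Loiselle kinship for simulated dyad batches
#'
#' Vectorised form of [loiselleKinship()] for the output of
#' [simulateDyads()]: one estimate per dyad against the known generating
#' frequencies. The reference frequencies are exact, so no small-sample
#' bias term is applied.
#'
#' @param dyads result of [simulateDyads()] (or any list with dosage
#'   matrices `g1`, `g2`, dyads x loci).
#' @param freqs the generating [AlleleFrequencyTable-class].
#' @return Numeric vector of kinship estimates, one per dyad.
#' @export
dyadKinship <- function(dyads, freqs) {
  p <- alleleFreq(freqs)
  keep <- p > 0 & p < 1
  .loiselleDyads(dyads$g1[, keep, drop = FALSE],
                 dyads$g2[, keep, drop = FALSE], p[keep])
}

# Fast path for simulated dyad batches: g1, g2 are dyads x loci dosage
# matrices with no missingness, p the known generating frequencies (no
# bias term: the reference is exact). Returns one estimate per dyad.
.loiselleDyads <- function(g1, g2, p) {
  P <- matrix(p, nrow = nrow(g1), ncol = length(p), byrow = TRUE)
  num <- rowSums((g1 / 2 - P) * (g2 / 2 - P))
  num / sum(p * (1 - p))
}
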