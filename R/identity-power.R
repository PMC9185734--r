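#' Per-locus probability of identity for unrelated individuals
#'
#' The probability that two unrelated individuals drawn from a
#' Hardy-Weinberg population share the same genotype at a biallelic
#' locus with minor-allele frequency `p`:
#' `P_ID = p^4 + q^4 + (2pq)^2`.
#'
#' @param p minor-allele frequency (or frequencies), each in \[0,1\].
#' @return Numeric vector of per-locus P_ID values.
#' @examples
#' pIdLocus(0.5)   # 0.375
#' pIdLocus(0.45)  # 0.3775375
#' @export
pIdLocus <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("allele frequency must lie in [0, 1]")
  q <- 1 - p
  p^4 + q^4 + (2 * p * q)^2
}

#' Per-locus probability of identity for full siblings
#'
#' The sibling analogue of [pIdLocus()], the standard conservative bound
#' used when a sampled population contains close relatives:
#' `P_IDsib = 0.25 + 0.5 * S2 + 0.5 * S2^2 - 0.25 * S4` with
#' `S2 = sum(p_i^2)` and `S4 = sum(p_i^4)` over the two alleles.
#' Always at least as large as P_ID.
#'
#' @inheritParams pIdLocus
#' @return Numeric vector of per-locus P_IDsib values.
#' @examples
#' pIdSibLocus(0.5)   # 0.59375
#' pIdSibLocus(0.45)  # 0.596884375
#' @export
pIdSibLocus <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("allele frequency must lie in [0, 1]")
  q <- 1 - p
  s2 <- p^2 + q^2
  s4 <- p^4 + q^4
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Cumulative identity-power curve and minimum panel sizes
#'
#' Accumulates per-locus P_ID and P_IDsib multiplicatively (in log space
#' for numerical stability) as loci are added to the panel, and reports
#' the smallest panel size at which each cumulative probability falls
#' strictly below `threshold` — conventionally the reciprocal of the
#' census sample size, so that a chance multilocus match among the
#' sampled animals is unexpected.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param threshold acceptable probability of a chance identical
#'   multilocus genotype, in (0, 1); either given directly or via
#'   `nIndividuals`.
#' @param nIndividuals census size from which `threshold = 1 /
#'   nIndividuals` is derived when `threshold` is not given.
#' @param order `"informative"` (default) sorts loci most informative
#'   first (ascending per-locus P_ID) before accumulating, the
#'   presentation convention of increasing-locus-combination plots;
#'   `"input"` keeps the input order.
#' @return An [IdentityPowerCurve-class].
#' @examples
#' aft <- AlleleFrequencyTable(sprintf("L%02d", 1:12), rep(0.45, 12))
#' minPanelSize(identityPowerCurve(aft, threshold = 0.007))
#' @export
identityPowerCurve <- function(freqs, threshold = NULL,
                               nIndividuals = NULL,
                               order = c("informative", "input")) {
  if (nLoci(freqs) == 0L) stop("empty allele-frequency table")
  if (is.null(threshold)) {
    if (is.null(nIndividuals))
      stop("supply threshold or nIndividuals")
    threshold <- 1 / nIndividuals
  }
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  order <- match.arg(order)
  p <- pMinor(freqs)
  pid <- pIdLocus(p)
  psib <- pIdSibLocus(p)
  idx <- if (order == "informative") base::order(pid) else seq_along(pid)
  cum_id <- exp(cumsum(log(pid[idx])))
  cum_sib <- exp(cumsum(log(psib[idx])))
  first_below <- function(x) {
    i <- which(x < threshold)
    if (length(i)) as.integer(i[1L]) else NA_integer_
  }
  new("IdentityPowerCurve",
      curve = data.frame(n = seq_along(idx),
                         locusId = locusIds(freqs)[idx],
                         pId = cum_id, pIdSib = cum_sib,
                         row.names = NULL),
      threshold = threshold,
      minLociPId = first_below(cum_id),
      minLociPIdSib = first_below(cum_sib))
}

#' @rdname IdentityPowerCurve
#' @export
setMethod("minPanelSize", "IdentityPowerCurve", function(object) {
  c(pId = object@minLociPId, pIdSib = object@minLociPIdSib)
})

#' @rdname IdentityPowerCurve
#' @export
setMethod("powerCurve", "IdentityPowerCurve", function(object) {
  object@curve
})

setMethod("show", "IdentityPowerCurve", function(object) {
  m <- minPanelSize(object)
  fmt <- function(v) if (is.na(v)) "not reached" else as.character(v)
  cat(sprintf(paste0("IdentityPowerCurve: %d loci, threshold %.4g\n",
                     "  min panel size: P_ID %s, P_IDsib %s\n"),
              nrow(object@curve), object@threshold, fmt(m["pId"]),
              fmt(m["pIdSib"])))
})

#' Empirical multilocus P_ID / P_IDsib of a genotype set
#'
#' Convenience wrapper: computes allele frequencies from the supplied
#' genotypes and returns the full-panel cumulative P_ID and P_IDsib,
#' reported alongside unique-genotype counts for interpretability.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return Named numeric: `pId`, `pIdSib`.
#' @export
empiricalIdentityPower <- function(gm) {
  p <- pMinor(alleleFrequencies(gm))
  p <- p[is.finite(p)]
  c(pId = prod(pIdLocus(p)), pIdSib = prod(pIdSibLocus(p)))
}
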