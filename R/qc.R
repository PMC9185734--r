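#' Remove samples exceeding a missing-data threshold
#'
#' Drops samples whose fraction of missing genotype calls is strictly
#' greater than `maxMissing` (a sample at exactly the threshold is
#' retained). Sample order is preserved. The conventional noninvasive-QC
#' cutoff is 0.5 (">50% missing data").
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maxMissing maximum tolerated missing fraction in \[0,1\].
#' @return A list: `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `removed` (character vector of dropped sample ids).
#' @export
filterSamples <- function(gm, maxMissing = 0.5) {
  stopifnot(maxMissing >= 0, maxMissing <= 1)
  mf <- missingFraction(gm, "sample")
  drop <- mf > maxMissing
  list(genotypes = gm[, !drop], removed = colnames(gm)[drop])
}

#' Remove loci exceeding a missing-data threshold
#'
#' Locus-wise mirror of [filterSamples()]; strictly-greater comparison,
#' locus order preserved. In the standard workflow the sample filter is
#' applied before the locus filter.
#'
#' @inheritParams filterSamples
#' @return A list: `genotypes` and `removed` (dropped locus ids).
#' @export
filterLoci <- function(gm, maxMissing = 0.5) {
  stopifnot(maxMissing >= 0, maxMissing <= 1)
  mf <- missingFraction(gm, "locus")
  drop <- mf > maxMissing
  list(genotypes = gm[!drop, ], removed = rownames(gm)[drop])
}

#' Per-stratum genotyping success
#'
#' Genotyping success of a sample is one minus its missing fraction;
#' stratum success is the mean over its samples. With `strata = NULL`
#' a single overall stratum is reported. Strata with no samples are
#' absent from the result rather than reported as zero.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param strata per-sample grouping vector, a `colData` column name
#'   (e.g. `"sampleType"`), or `NULL`.
#' @return A data.frame: `stratum`, `nSamples`, `success` (proportion in
#'   \[0,1\]).
#' @export
genotypingSuccess <- function(gm, strata = NULL) {
  if (ncol(gm) == 0L) stop("no samples")
  if (is.character(strata) && length(strata) == 1L &&
      strata %in% colnames(colData(gm)))
    strata <- colData(gm)[[strata]]
  if (is.null(strata)) strata <- rep("overall", ncol(gm))
  stopifnot(length(strata) == ncol(gm))
  succ <- 1 - missingFraction(gm, "sample")
  agg <- tapply(succ, as.character(strata), mean)
  data.frame(stratum = names(agg),
             nSamples = as.integer(table(as.character(strata))[names(agg)]),
             success = as.numeric(agg), row.names = NULL)
}

# shared pairwise-comparison core: genotypes differ as unordered allele
# pairs, i.e. dosage inequality; cells missing in either member are not
# comparable
.pairwiseDiscordance <- function(d_a, d_b, pair_ids) {
  per_pair <- data.frame(pair = pair_ids,
                         nComparable = integer(length(pair_ids)),
                         nDiscordant = integer(length(pair_ids)))
  for (k in seq_along(pair_ids)) {
    comp <- !is.na(d_a[, k]) & !is.na(d_b[, k])
    per_pair$nComparable[k] <- sum(comp)
    per_pair$nDiscordant[k] <- sum(d_a[comp, k] != d_b[comp, k])
  }
  per_pair
}

#' Genotype discordance between paired samples
#'
#' For each pair, comparable cells are loci called in both members;
#' discordant cells are those where the genotypes differ as unordered
#' allele pairs (a heterozygote and a homozygote are discordant even
#' when they share an allele). The headline rate pools counts across
#' pairs (total discordant / total comparable) — the convention behind a
#' single panel-level percentage — with per-pair rates also returned.
#' Pairs with zero comparable loci are excluded from the pooled rate and
#' listed.
#'
#' @param gm a [GenotypeMatrix-class] containing both members of every
#'   pair.
#' @param pairs data.frame with columns `sample_a`, `sample_b` (sample
#'   ids in `gm`), optionally `relation`.
#' @return A list: `nPairs`, `nComparableCalls`, `nDiscordant`,
#'   `discordance` (pooled), `perPair` (data.frame with per-pair rates),
#'   `excludedPairs`.
#' @export
discordance <- function(gm, pairs) {
  stopifnot(all(c("sample_a", "sample_b") %in% names(pairs)))
  missing_samples <- setdiff(c(pairs$sample_a, pairs$sample_b),
                             colnames(gm))
  if (length(missing_samples))
    stop("pair sample(s) not in genotype matrix: ",
         paste(utils::head(missing_samples, 5L), collapse = ", "))
  d <- dosage(gm)
  pp <- .pairwiseDiscordance(d[, pairs$sample_a, drop = FALSE],
                             d[, pairs$sample_b, drop = FALSE],
                             paste(pairs$sample_a, pairs$sample_b,
                                   sep = " vs "))
  if ("relation" %in% names(pairs)) pp$relation <- pairs$relation
  pp$rate <- ifelse(pp$nComparable > 0,
                    pp$nDiscordant / pp$nComparable, NA_real_)
  usable <- pp$nComparable > 0
  list(nPairs = sum(usable),
       nComparableCalls = sum(pp$nComparable),
       nDiscordant = sum(pp$nDiscordant),
       discordance = if (any(usable))
         sum(pp$nDiscordant) / sum(pp$nComparable) else NA_real_,
       perPair = pp,
       excludedPairs = pp$pair[!usable])
}

#' Genotype concordance between two genotyping methods
#'
#' Compares two genotype matrices (e.g. amplicon panel vs RADseq) at
#' their shared loci, matching samples by `individualId` when present in
#' both and by shared sample names otherwise. Comparison semantics are
#' those of [discordance()].
#'
#' @param gm_a,gm_b [GenotypeMatrix-class] objects.
#' @param sharedLoci optional locus subset; default is the intersection
#'   of locus ids (which must be non-empty).
#' @return As [discordance()], plus `nSharedLoci`.
#' @export
crossMethodConcordance <- function(gm_a, gm_b, sharedLoci = NULL) {
  if (is.null(sharedLoci))
    sharedLoci <- intersect(rownames(gm_a), rownames(gm_b))
  if (!length(sharedLoci)) stop("no shared loci between the two datasets")
  ia <- individualId(gm_a)
  ib <- individualId(gm_b)
  if (!is.null(ia) && !is.null(ib)) {
    shared_ind <- intersect(ia, ib)
    col_a <- match(shared_ind, ia)
    col_b <- match(shared_ind, ib)
    labels <- shared_ind
  } else {
    labels <- intersect(colnames(gm_a), colnames(gm_b))
    col_a <- match(labels, colnames(gm_a))
    col_b <- match(labels, colnames(gm_b))
  }
  if (!length(labels)) stop("no matched samples between the two datasets")
  d_a <- dosage(gm_a)[sharedLoci, col_a, drop = FALSE]
  d_b <- dosage(gm_b)[sharedLoci, col_b, drop = FALSE]
  pp <- .pairwiseDiscordance(d_a, d_b, labels)
  pp$rate <- ifelse(pp$nComparable > 0,
                    pp$nDiscordant / pp$nComparable, NA_real_)
  usable <- pp$nComparable > 0
  list(nPairs = sum(usable),
       nSharedLoci = length(sharedLoci),
       nComparableCalls = sum(pp$nComparable),
       nDiscordant = sum(pp$nDiscordant),
       discordance = if (any(usable))
         sum(pp$nDiscordant) / sum(pp$nComparable) else NA_real_,
       perPair = pp,
       excludedPairs = pp$pair[!usable])
}
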