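#' Train per-sex genotype-class frequencies at sex-associated loci
#'
#' Estimates, for each sex and locus, the frequencies of the three
#' genotype classes (dosage 0, 1, 2) among known-sex training
#' individuals, smoothed with a pseudocount of 0.5 per class. A
#' supervised model is used deliberately: Hardy-Weinberg proportions
#' cannot be assumed at gametolog-like sex-linked loci, so class
#' frequencies are learned rather than derived from allele frequencies.
#'
#' @param gm a [GenotypeMatrix-class] restricted to sex-associated loci.
#' @param sex per-sample labels (`"male"` / `"female"`), aligned with
#'   `gm` columns; both sexes must be represented.
#' @return A list with a loci x 3 x 2 frequency array (`classFreq`),
#'   the training counts, and locus ids.
#' @export
sexTrainingFrequencies <- function(gm, sex) {
  sex <- as.character(sex)
  stopifnot(length(sex) == ncol(gm))
  sexes <- c("male", "female")
  if (!all(sexes %in% sex))
    stop("training set must contain both males and females")
  d <- dosage(gm)
  arr <- array(NA_real_, dim = c(nrow(d), 3L, 2L),
               dimnames = list(rownames(d), c("0", "1", "2"), sexes))
  for (s in sexes) {
    ds <- d[, sex == s, drop = FALSE]
    for (g in 0:2) {
      cnt <- rowSums(ds == g, na.rm = TRUE)
      ncall <- rowSums(!is.na(ds))
      arr[, g + 1L, s] <- (cnt + 0.5) / (ncall + 1.5)
    }
  }
  list(classFreq = arr, nMale = sum(sex == "male"),
       nFemale = sum(sex == "female"), loci = rownames(d))
}

#' Assign sex from sex-associated genotypes by naive-Bayes posterior
#'
#' Each sample's posterior probability of being male is computed under
#' equal priors as the product, over its called sex loci, of the
#' per-sex genotype-class frequencies from
#' [sexTrainingFrequencies()]. A sample is called `male` or `female`
#' when the winning posterior reaches `posteriorCutoff`, `unassigned`
#' otherwise; samples with no called sex locus are always unassigned.
#'
#' @param gm a [GenotypeMatrix-class] at the training loci.
#' @param training result of [sexTrainingFrequencies()].
#' @param posteriorCutoff minimum winning posterior for a call
#'   (default 0.9).
#' @return A data.frame: `sample`, `posteriorMale`, `call`,
#'   `nInformativeLoci`.
#' @export
assignSex <- function(gm, training, posteriorCutoff = 0.9) {
  loci <- intersect(rownames(gm), training$loci)
  if (!length(loci)) stop("no training sex locus present in genotypes")
  d <- dosage(gm)[loci, , drop = FALSE]
  cf <- training$classFreq
  out <- data.frame(sample = colnames(d),
                    posteriorMale = NA_real_,
                    call = "unassigned",
                    nInformativeLoci = 0L)
  for (j in seq_len(ncol(d))) {
    called <- which(!is.na(d[, j]))
    out$nInformativeLoci[j] <- length(called)
    if (!length(called)) next
    cls <- as.character(d[called, j])
    ll_m <- sum(log(cf[cbind(loci[called], cls,
                             rep("male", length(called)))]))
    ll_f <- sum(log(cf[cbind(loci[called], cls,
                             rep("female", length(called)))]))
    post_m <- 1 / (1 + exp(ll_f - ll_m))
    out$posteriorMale[j] <- post_m
    if (post_m >= posteriorCutoff) out$call[j] <- "male"
    else if (1 - post_m >= posteriorCutoff) out$call[j] <- "female"
  }
  out
}
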