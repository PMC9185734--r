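test_that("identical multilocus genotypes collapse to one individual", {
  freqs <- drawFrequencySpectrum(200, "high", seed = 90)
  gm <- simulatePopulationGenotypes(freqs, 1, seed = 91)
  d <- cbind(dosage(gm), dosage(gm))
  colnames(d) <- c("rep1", "rep2")
  res <- clusterIndividuals(GenotypeMatrix(d), minOverlap = 50)
  expect_equal(res$nUnique, 1L)
  expect_equal(unname(res$decisions$decision), "same_individual")
  expect_named(res$identityPower, c("pId", "pIdSib"))
})

test_that("zero tolerance splits on a single discordant call", {
  freqs <- drawFrequencySpectrum(100, "high", seed = 92)
  gm <- simulatePopulationGenotypes(freqs, 1, seed = 93)
  d <- cbind(dosage(gm), dosage(gm))
  d[1, 2] <- (d[1, 2] + 1L) %% 3L
  colnames(d) <- c("a", "b")
  strict <- clusterIndividuals(GenotypeMatrix(d), matchTolerance = 0,
                               minOverlap = 50)
  expect_equal(strict$nUnique, 2L)
  loose <- clusterIndividuals(GenotypeMatrix(d), matchTolerance = 0.02,
                              minOverlap = 50)
  expect_equal(loose$nUnique, 1L)
})

test_that("cluster count is order-invariant and monotone in tolerance", {
  freqs <- drawFrequencySpectrum(150, "high", seed = 94)
  base <- simulatePopulationGenotypes(freqs, 6, seed = 95)
  d <- cbind(dosage(base), dosage(base)[, c(2, 4)])
  colnames(d) <- c(colnames(base), "dup2", "dup4")
  gm <- GenotypeMatrix(d)
  res <- clusterIndividuals(gm, minOverlap = 50)
  expect_equal(res$nUnique, 6L)
  perm <- withr::with_seed(96, sample(ncol(d)))
  res_p <- clusterIndividuals(gm[, perm], minOverlap = 50)
  expect_equal(res_p$nUnique, res$nUnique)
  counts <- vapply(c(0, 0.05, 0.2, 0.5, 1),
                   function(tol) clusterIndividuals(gm, tol,
                                                    50)$nUnique,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(clusterIndividuals(gm, minOverlap = 1000), "exceeds")
})

test_that("33 degraded samples from 20 individuals give 20 genotypes", {
  freqs <- drawFrequencySpectrum(200, "high", seed = 97)
  inds <- simulatePopulationGenotypes(freqs, 20, seed = 98)
  capture_of <- withr::with_seed(99, c(seq_len(20),
                                       sample(20, 13, replace = TRUE)))
  d <- dosage(inds)[, capture_of]
  colnames(d) <- sprintf("pellet_%02d", seq_len(33))
  # field-tier degradation: 12% dropout and 0.5% call errors per cell
  d <- withr::with_seed(100, {
    drop <- matrix(stats::runif(length(d)) < 0.12, nrow(d))
    err <- matrix(stats::runif(length(d)) < 0.005, nrow(d))
    d[err] <- (d[err] + 1L) %% 3L
    d[drop] <- NA_integer_
    d
  })
  res <- clusterIndividuals(GenotypeMatrix(d), matchTolerance = 0.02,
                            minOverlap = 50)
  expect_equal(res$nUnique, 20L)
  # every pellet of the same true individual lands in one cluster
  splits <- tapply(res$clusters, capture_of,
                   function(x) length(unique(x)))
  expect_true(all(splits == 1L))
})

test_that("Loiselle kinship agrees with a hand-rolled double loop", {
  freqs <- drawFrequencySpectrum(30, "moderate", seed = 101)
  gm <- simulatePopulationGenotypes(freqs, 5, seed = 102)
  d <- dosage(gm)
  d[1:3, 2] <- NA_integer_
  gm <- GenotypeMatrix(d)
  K <- loiselleKinship(gm)
  p <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  n_copies <- 2 * ncol(d)
  oracle <- function(i, j) {
    num <- den <- 0
    for (l in seq_len(nrow(d))) {
      if (is.na(d[l, i]) || is.na(d[l, j])) next
      if (p[l] <= 0 || p[l] >= 1) next
      for (al in 1:2) {  # allele 1 then allele 2
        pa <- if (al == 1) p[l] else 1 - p[l]
        xi <- if (al == 1) d[l, i] / 2 else 1 - d[l, i] / 2
        xj <- if (al == 1) d[l, j] / 2 else 1 - d[l, j] / 2
        num <- num + (xi - pa) * (xj - pa) + pa * (1 - pa) / (n_copies - 1)
        den <- den + pa * (1 - pa)
      }
    }
    unname(num / den)
  }
  for (pair in list(c(1, 2), c(2, 3), c(4, 5)))
    expect_equal(K[pair[1], pair[2]], oracle(pair[1], pair[2]),
                 tolerance = 1e-12)
  expect_true(all(is.na(diag(K))))
  expect_equal(K, t(K))
})

test_that("dyadKinship matches the matrix estimator on shared input", {
  freqs <- drawFrequencySpectrum(50, "high", seed = 103)
  b <- simulateDyads(freqs, "HS", 3, seed = 104)
  fast <- dyadKinship(b, freqs)
  for (k in 1:3) {
    d <- rbind(b$g1[k, ], b$g2[k, ])
    gm <- GenotypeMatrix(t(d))
    rownames(gm) <- locusIds(freqs)
    K <- loiselleKinship(gm, freqs = freqs)
    expect_equal(unname(K[1, 2]), fast[k], tolerance = 1e-12)
  }
})

test_that("kinship estimates are unbiased for each relationship", {
  aft <- AlleleFrequencyTable(sprintf("L%03d", 1:500), rep(0.3, 500))
  cats <- relationshipCategories()
  for (k in seq_len(nrow(cats))) {
    est <- dyadKinship(simulateDyads(aft, cats$code[k], 1000,
                                     seed = 110 + k), aft)
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - cats$expectedKinship[k]), 3 * se,
              label = sprintf("category %s mean %0.4f", cats$code[k],
                              mean(est)))
  }
})

test_that("UR kinship centres on zero with high-MAF panels", {
  freqs <- drawFrequencySpectrum(200, "high", seed = 115)
  est <- dyadKinship(simulateDyads(freqs, "UR", 2000, seed = 116), freqs)
  expect_equal(mean(est), 0, tolerance = 0.01)
})

test_that("sex assignment is perfect at fixed differences", {
  for (s in 1:20) {
    sx <- simulateSexLoci(7, 1.0, nMales = 15, nFemales = 15, seed = s)
    idx <- c(1:8, 16:23)
    tr <- sexTrainingFrequencies(sx$genotypes[, idx], sx$sex[idx])
    hold <- setdiff(seq_len(30), idx)
    calls <- assignSex(sx$genotypes[, hold], tr)
    expect_equal(calls$call, sx$sex[hold])
    expect_true(all(pmax(calls$posteriorMale,
                         1 - calls$posteriorMale) > 0.99))
  }
})

test_that("samples with no called sex locus are unassigned", {
  sx <- simulateSexLoci(7, 1.0, nMales = 10, nFemales = 10, seed = 120)
  tr <- sexTrainingFrequencies(sx$genotypes, sx$sex)
  d <- dosage(sx$genotypes)
  d[, 1] <- NA_integer_
  calls <- assignSex(GenotypeMatrix(d), tr)
  expect_equal(calls$call[1], "unassigned")
  expect_equal(calls$nInformativeLoci[1], 0L)
  expect_true(is.na(calls$posteriorMale[1]))
  expect_error(sexTrainingFrequencies(sx$genotypes,
                                      rep("male", 20)), "both")
})

test_that("a 9-female, 11-male cohort is sexed to the exact tally", {
  sx <- simulateSexLoci(7, 0.95, nMales = 40, nFemales = 40, seed = 121)
  tr <- sexTrainingFrequencies(sx$genotypes, sx$sex)
  cohort <- simulateSexLoci(7, 0.95, nMales = 11, nFemales = 9,
                            seed = 122)
  # genotype the cohort against the training model of the same loci
  d <- dosage(cohort$genotypes)
  rownames(d) <- tr$loci
  calls <- assignSex(GenotypeMatrix(d), tr)
  expect_equal(sum(calls$call == "male"), 11L)
  expect_equal(sum(calls$call == "female"), 9L)
})

test_that("mark-recapture summarises captures and distances", {
  membership <- c(p1 = "ind1", p2 = "ind1", p3 = "ind2")
  coords <- data.frame(sample = c("p1", "p2", "p3"),
                       x = c(0, 300, 50), y = c(0, 400, 50))
  mr <- markRecaptureSummary(membership, coords)
  expect_equal(mr$captures$nCaptures[mr$captures$individual == "ind1"],
               2L)
  expect_equal(mr$distances$distance, 500)  # 3-4-5 triangle
  # singleton cluster: capture count 1, no distances
  expect_false("ind2" %in% mr$distances$individual)
  # identical coordinates give distance zero
  mr0 <- markRecaptureSummary(membership,
                              data.frame(sample = c("p1", "p2"),
                                         x = c(10, 10), y = c(2, 2)))
  expect_equal(mr0$distances$distance, 0)
  # no coordinates: distances omitted entirely
  expect_null(markRecaptureSummary(membership)$distances)
})
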