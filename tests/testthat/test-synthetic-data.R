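test_that("frequency spectra respect bin bounds and reject bad input", {
  bins <- mafBins()
  for (s in 1:100) {
    bin <- sample(names(bins), 1)
    p <- pMinor(drawFrequencySpectrum(20, bin, seed = s))
    expect_true(all(p >= bins[[bin]][1] & p <= bins[[bin]][2]),
                info = sprintf("bin %s seed %d", bin, s))
  }
  p3 <- pMinor(drawFrequencySpectrum(3, "high", seed = 1))
  expect_length(p3, 3)
  expect_true(all(p3 >= 0.40 & p3 <= 0.49))
  expect_error(drawFrequencySpectrum(0, "high", seed = 1), "nLoci")
  expect_error(drawFrequencySpectrum(5, "extreme", seed = 1),
               "low, moderate, high, proportional")
})

test_that("low-bin frequency draws average to the uniform mean", {
  p <- pMinor(drawFrequencySpectrum(1000, "low", seed = 2))
  expect_equal(mean(p), 0.05, tolerance = 0.01 / 0.05)
})

test_that("proportional bin mixes the three bins by the given weights", {
  p <- pMinor(drawFrequencySpectrum(3000, "proportional", seed = 4))
  bins <- mafBins()
  share <- vapply(bins, function(b) mean(p >= b[1] & p <= b[2]),
                  numeric(1))
  expect_equal(unname(share), rep(1 / 3, 3), tolerance = 0.1)
  p_skew <- pMinor(drawFrequencySpectrum(3000, "proportional", seed = 4,
                                         weights = c(0, 0, 1)))
  expect_true(all(p_skew >= 0.40 & p_skew <= 0.49))
})

test_that("population genotypes follow Hardy-Weinberg proportions", {
  aft <- AlleleFrequencyTable("L1", 0.3)
  gm <- simulatePopulationGenotypes(aft, 10000, seed = 7)
  counts <- table(factor(dosage(gm)[1, ], levels = 0:2))
  expected <- c(0.7^2, 2 * 0.3 * 0.7, 0.3^2)  # dosage 0, 1, 2
  gof <- suppressWarnings(chisq.test(as.numeric(counts), p = expected))
  expect_gt(gof$p.value, 0.001)
  expect_false(anyNA(dosage(gm)))
})

test_that("heterozygote fraction at p = 0.5 matches 2pq", {
  gm <- simulatePopulationGenotypes(AlleleFrequencyTable("L1", 0.5),
                                    10000, seed = 8)
  expect_equal(mean(dosage(gm)[1, ] == 1L), 0.5, tolerance = 0.015 / 0.5)
})

test_that("degenerate population cases behave", {
  fixed <- simulatePopulationGenotypes(AlleleFrequencyTable("L1", 0),
                                       50, seed = 1)
  expect_true(all(dosage(fixed) == 0L))
  one <- simulatePopulationGenotypes(drawFrequencySpectrum(5, "high", 1),
                                     1, seed = 2)
  expect_equal(dim(dosage(one)), c(5L, 1L))
  expect_true(all(dosage(one) %in% 0:2))
  expect_error(simulatePopulationGenotypes(fixed <- AlleleFrequencyTable("L1", 0.5),
                                           0, seed = 1), "nSamples")
})

test_that("dyad simulation honours category IBD distributions", {
  aft <- AlleleFrequencyTable(sprintf("L%05d", 1:10000), rep(0.5, 10000))
  dy <- simulateDyad(aft, "FS", seed = 3)
  expect_equal(mean(dy$ibd), 1.0, tolerance = 0.02 / 1.0)
  # realized IBD means for all categories within 3 SE of expectation
  cats <- relationshipCategories()
  for (k in seq_len(nrow(cats))) {
    b <- simulateDyads(aft[1:2000], cats$code[k], 50, seed = 10 + k)
    e_k <- cats$ibd1[k] + 2 * cats$ibd2[k]
    v_k <- cats$ibd1[k] + 4 * cats$ibd2[k] - e_k^2
    se <- sqrt(v_k / length(b$ibd))
    expect_lt(abs(mean(b$ibd) - e_k), max(3 * se, 1e-12))
  }
})

test_that("parent-offspring dyads share an obligate allele", {
  aft <- drawFrequencySpectrum(500, "high", seed = 9)
  dy <- simulateDyad(aft, "PO", seed = 10)
  expect_true(all(dy$g2[dy$g1 == 2L] >= 1L))
  expect_true(all(dy$g2[dy$g1 == 0L] <= 1L))
  expect_true(all(dy$ibd == 1L))
})

test_that("unrelated dyads are independent HWE draws", {
  aft <- AlleleFrequencyTable(sprintf("L%04d", 1:5000), rep(0.5, 5000))
  dy <- simulateDyad(aft, "UR", seed = 11)
  expect_true(all(dy$ibd == 0L))
  expect_lt(abs(cor(dy$g1, dy$g2)), 0.05)
})

test_that("sex-locus construction hits the requested differential", {
  sx <- simulateSexLoci(10, 0.20, nMales = 10000, nFemales = 10000,
                        seed = 12)
  obs <- alleleFrequencies(sx$genotypes, sx$sex)
  gap <- strataFreq(obs)[, "male"] - strataFreq(obs)[, "female"]
  expect_equal(unname(gap), rep(0.20, 10), tolerance = 0.01 / 0.20)
  expect_equal(strataFreq(sx$freqs)[, "male"] -
                 strataFreq(sx$freqs)[, "female"],
               stats::setNames(rep(0.20, 10), locusIds(sx$freqs)))
})

test_that("fixed sex differences separate the sexes completely", {
  sx <- simulateSexLoci(4, 1.0, nMales = 30, nFemales = 30, seed = 13)
  d <- dosage(sx$genotypes)
  expect_true(all(d[, sx$sex == "male"] == 2L))
  expect_true(all(d[, sx$sex == "female"] == 0L))
})

test_that("sex-locus defaults and input checks match the design", {
  sx <- simulateSexLoci(nMales = 5, nFemales = 5, seed = 14)
  expect_equal(nrow(dosage(sx$genotypes)), 8L)  # default screening yield
  expect_error(simulateSexLoci(3, 0, 5, 5, seed = 1), "differential")
  expect_error(simulateSexLoci(3, 0.5, 0, 5, seed = 1), ">= 1")
})

test_that("total dropout yields empty read sets", {
  freqs <- drawFrequencySpectrum(6, "high", seed = 15)
  truth <- simulatePopulationGenotypes(freqs, 3, seed = 16)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 17)
  dead <- sampleQualityTier("dead", 1, 100, dropoutProb = 1, errorRate = 0)
  sim <- simulateAmpliconReads(panel, truth, dead, seed = 18)
  expect_true(all(lengths(sim$reads) == 0L))
  expect_true(all(sim$ledger$depth == 0L))
})

test_that("homozygous loci emit only their own allele probe", {
  panel <- toy_panel()
  hom <- GenotypeMatrix(matrix(2L, 1, 1, dimnames = list("locA", "s1")))
  sim <- simulateAmpliconReads(panel, hom, clean_tier(), seed = 20)
  reads <- sim$reads[[1]]
  expect_gt(length(reads), 0)
  expect_true(all(grepl("ACGTACGTACGTACGGGGAAACCC", reads, fixed = TRUE)))
  expect_false(any(grepl("GGGAAACCG", reads, fixed = TRUE)))
})

test_that("off-target share matches the tier by exact string counting", {
  freqs <- drawFrequencySpectrum(40, "high", seed = 21)
  truth <- simulatePopulationGenotypes(freqs, 10, seed = 22)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 23)
  half <- sampleQualityTier("half", 0.5, 300, 0, 0)
  sim <- simulateAmpliconReads(panel, truth, half, seed = 24)
  reads <- unlist(sim$reads, use.names = FALSE)
  expect_gt(length(reads), 1e5)
  primers <- as.character(fwdPrimer(panel))
  on <- rep(FALSE, length(reads))
  for (p in primers) on <- on | grepl(p, reads, fixed = TRUE)
  expect_equal(mean(on), 0.5, tolerance = 0.01 / 0.5)
})

test_that("FASTQ round trip preserves simulated reads", {
  freqs <- drawFrequencySpectrum(4, "moderate", seed = 25)
  truth <- simulatePopulationGenotypes(freqs, 2, seed = 26)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 27)
  sim <- simulateAmpliconReads(panel, truth, clean_tier(40), seed = 28)
  dir <- withr::local_tempdir()
  paths <- writeSimulatedFastq(sim, dir)
  expect_identical(readFastqSequences(paths[[1]]), sim$reads[[1]])
  # malformed records carry the record index
  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2", "ACGT", "+", "IIII"), bad)
  expect_error(readFastqSequences(bad), "record 2")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)
  expect_error(readFastqSequences(bad), "lengths differ")
})

test_that("empty panels and foreign loci are rejected", {
  panel <- toy_panel()
  gm <- GenotypeMatrix(matrix(1L, 1, 1, dimnames = list("locX", "s1")))
  expect_error(simulateAmpliconReads(panel, gm, clean_tier(), seed = 1),
               "locX")
})
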