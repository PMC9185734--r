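test_that("reads are counted by exact primer and probe containment", {
  panel <- toy_panel()
  reads <- c(
    paste0("ACGTACGTACGTACG", "GGGAAACCC", "TTTT"),  # locA allele 1
    paste0("ACGTACGTACGTACG", "GGGAAACCG"),          # locA allele 2
    paste0("NNNN", "TTGCATTGCATTGCA", "TTTCCCAAA"),  # locB allele 1
    paste0("TTGCATTGCATTGCA", "GGGGGGGG"),           # locB, no probe
    "ACGTACGTACGTAC")                                # off target
  rep <- countAlleles(reads, panel, sampleIds = "s1")
  a1 <- SummarizedExperiment::assay(rep, "countA1")
  a2 <- SummarizedExperiment::assay(rep, "countA2")
  lr <- SummarizedExperiment::assay(rep, "locusReads")
  expect_equal(unname(a1[, 1]), c(1L, 1L))
  expect_equal(unname(a2[, 1]), c(1L, 0L))
  expect_equal(unname(lr[, 1]), c(2L, 2L))
  expect_equal(SummarizedExperiment::colData(rep)$onTargetFraction,
               3 / 5)
})

test_that("empty read sets give zero counts and zero on-target", {
  rep <- countAlleles(character(0), toy_panel())
  expect_true(all(SummarizedExperiment::assay(rep, "countA1") == 0L))
  expect_equal(SummarizedExperiment::colData(rep)$onTargetFraction, 0)
  expect_equal(SummarizedExperiment::colData(rep)$totalReads, 0L)
})

test_that("counts equal the simulator's emission ledger exactly", {
  freqs <- drawFrequencySpectrum(15, "high", seed = 40)
  truth <- simulatePopulationGenotypes(freqs, 6, seed = 41)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 42)
  sim <- simulateAmpliconReads(panel, truth, clean_tier(80), seed = 43)
  rep <- countAlleles(sim$reads, panel)
  led <- sim$ledger
  idx <- cbind(led$locus, led$sample)
  expect_equal(SummarizedExperiment::assay(rep, "countA1")[idx],
               led$emittedA1)
  expect_equal(SummarizedExperiment::assay(rep, "countA2")[idx],
               led$emittedA2)
})

test_that("string-matching core agrees with the naive scan oracle", {
  freqs <- drawFrequencySpectrum(8, "moderate", seed = 44)
  truth <- simulatePopulationGenotypes(freqs, 2, seed = 45)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 46)
  noisy <- sampleQualityTier("noisy", 0.7, 60, 0.05, 0.01)
  sim <- simulateAmpliconReads(panel, truth, noisy, seed = 47)
  reads <- sim$reads[[1]]
  expect_lte(length(reads), 1000)
  oracle <- naive_allele_counts(reads, panel)
  rep <- countAlleles(reads, panel)
  expect_equal(unname(SummarizedExperiment::assay(rep, "countA1")[, 1]),
               unname(oracle$a1))
  expect_equal(unname(SummarizedExperiment::assay(rep, "countA2")[, 1]),
               unname(oracle$a2))
})

test_that("allele-ratio calling follows the threshold arithmetic", {
  counts <- function(a1, a2) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(countA1 = matrix(a1, 1, 1, dimnames = list("L", "s")),
                    countA2 = matrix(a2, 1, 1, dimnames = list("L", "s")),
                    locusReads = matrix(a1 + a2, 1, 1,
                                        dimnames = list("L", "s"))),
      colData = S4Vectors::DataFrame(totalReads = a1 + a2,
                                     onTargetFraction = 1,
                                     row.names = "s"))
    new("GenotypeCallReport", se)
  }
  call_of <- function(a1, a2, ...)
    SummarizedExperiment::assay(callGenotypes(counts(a1, a2), ...),
                                "call")[1, 1]
  expect_equal(call_of(100, 2), "hom1")    # ratio 50 >= 10
  expect_equal(call_of(2, 100), "hom2")    # ratio 0.02 <= 0.1
  expect_equal(call_of(40, 38), "het")     # ratio ~1.05 in [0.2, 5]
  expect_equal(call_of(5, 4), "missing")   # depth 9 < 10
  expect_equal(call_of(5, 4, minDepth = 5), "het")
  expect_equal(call_of(8, 1), "missing")   # ratio 8: between bands
  # denominator floor: a2 = 0 maps to ratio 10 * a1
  rep <- callGenotypes(counts(1, 0), minDepth = 1)
  expect_equal(SummarizedExperiment::assay(rep, "ratio")[1, 1], 10)
  expect_equal(SummarizedExperiment::assay(rep, "call")[1, 1], "hom1")
})

test_that("calls are invariant to read order", {
  freqs <- drawFrequencySpectrum(10, "high", seed = 48)
  truth <- simulatePopulationGenotypes(freqs, 2, seed = 49)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 50)
  sim <- simulateAmpliconReads(panel, truth, clean_tier(60), seed = 51)
  fwd <- callGenotypes(countAlleles(sim$reads, panel))
  shuffled <- lapply(sim$reads, function(r) rev(sample(r)))
  bwd <- callGenotypes(countAlleles(shuffled, panel))
  expect_identical(SummarizedExperiment::assay(fwd, "call"),
                   SummarizedExperiment::assay(bwd, "call"))
})

test_that("count conservation holds per locus", {
  freqs <- drawFrequencySpectrum(12, "moderate", seed = 52)
  truth <- simulatePopulationGenotypes(freqs, 4, seed = 53)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 54)
  noisy <- sampleQualityTier("noisy", 0.6, 50, 0.1, 0.02)
  sim <- simulateAmpliconReads(panel, truth, noisy, seed = 55)
  rep <- countAlleles(sim$reads, panel)
  a1 <- SummarizedExperiment::assay(rep, "countA1")
  a2 <- SummarizedExperiment::assay(rep, "countA2")
  lr <- SummarizedExperiment::assay(rep, "locusReads")
  expect_true(all(a1 + a2 <= lr))
})

test_that("merging technical runs sums counts and rescues thin loci", {
  freqs <- drawFrequencySpectrum(10, "high", seed = 56)
  truth <- simulatePopulationGenotypes(freqs, 3, seed = 57)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 58)
  thin <- sampleQualityTier("thin", 1, 6, 0, 0)
  run1 <- countAlleles(simulateAmpliconReads(panel, truth, thin,
                                             seed = 59)$reads, panel)
  run2 <- countAlleles(simulateAmpliconReads(panel, truth, thin,
                                             seed = 60)$reads, panel)
  merged <- mergeTechnicalRuns(run1, run2)
  expect_equal(SummarizedExperiment::assay(merged, "countA1"),
               SummarizedExperiment::assay(run1, "countA1") +
                 SummarizedExperiment::assay(run2, "countA1"))
  # commutative
  merged_rev <- mergeTechnicalRuns(run2, run1)
  expect_equal(SummarizedExperiment::assay(merged, "countA2"),
               SummarizedExperiment::assay(merged_rev, "countA2"))
  # identity under an empty run
  empty <- countAlleles(stats::setNames(rep(list(character(0)),
                                            ncol(run1)),
                                        colnames(run1)), panel)
  with_empty <- mergeTechnicalRuns(run1, empty)
  expect_equal(SummarizedExperiment::assay(with_empty, "countA1"),
               SummarizedExperiment::assay(run1, "countA1"))
  # a locus missing in each thin run can be called after merging
  call1 <- SummarizedExperiment::assay(callGenotypes(run1), "call")
  call_m <- SummarizedExperiment::assay(callGenotypes(merged), "call")
  expect_gte(sum(call_m != "missing"), sum(call1 != "missing"))
  rescued <- call1 == "missing" & call_m != "missing"
  expect_gt(sum(rescued), 0)
  # panel mismatch is rejected
  other <- countAlleles(list(sA = character(0)), toy_panel())
  expect_error(mergeTechnicalRuns(run1, other), "disagree")
})

test_that("noiseless simulation round-trips to the true genotypes", {
  freqs <- drawFrequencySpectrum(25, "proportional", seed = 61)
  truth <- simulatePopulationGenotypes(freqs, 8, seed = 62)
  panel <- simulateAmpliconPanel(locusIds(freqs), seed = 63)
  sim <- simulateAmpliconReads(panel, truth, clean_tier(150), seed = 64)
  called <- callsToGenotypeMatrix(callGenotypes(countAlleles(sim$reads,
                                                             panel)))
  expect_identical(dosage(called)[rownames(truth), colnames(truth)],
                   dosage(truth))
})
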