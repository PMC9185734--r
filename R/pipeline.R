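#' Default end-to-end demonstration configuration
#'
#' A small, fully specified run configuration exercising every pipeline
#' stage: frequency simulation, panel design, read simulation, amplicon
#' genotyping, QC and forensics. All seeds are explicit so a rerun with
#' the same configuration reproduces identical outputs.
#'
#' @param outDir output directory for the run.
#' @param seed master seed; stage seeds derive from it.
#' @return A named list understood by [runPipeline()].
#' @export
demoRunConfig <- function(outDir = tempfile("panelrun"), seed = 1L) {
  list(
    out_dir = outDir,
    seed = seed,
    simulate = list(n_loci = 60L, maf_bin = "high", n_samples = 12L,
                    tier = "hair", read_length = 75L),
    design = list(threshold = 0.007,
                  sex = list(n_loci = 8L, differential = 0.9,
                             n_males = 20L, n_females = 20L)),
    genotype = list(min_depth = 10L, hom_ratio = 10, het_band = c(0.2, 5)),
    qc = list(max_missing_sample = 0.5, max_missing_locus = 0.5),
    forensics = list(match_tolerance = 0.02, min_overlap = 20L,
                     posterior_cutoff = 0.9))
}

#' Run the simulate-design-genotype-qc-forensics pipeline
#'
#' Executes the full workflow on synthetic data as specified by a
#' configuration list (or YAML path): draws an allele-frequency
#' spectrum, simulates a population and amplicon reads at the chosen
#' quality tier, genotypes the reads with the allele-ratio caller,
#' applies sample-then-locus missingness filters, and runs the forensic
#' layer (unique-genotype clustering, Loiselle kinship, sex screening
#' and assignment). All artifacts are written to `out_dir` as TSV/JSON
#' together with a provenance manifest (seeds, parameters, package
#' version, output checksums). Stage failures abort with the stage name.
#'
#' @param config configuration list as from [demoRunConfig()], or a
#'   YAML file path.
#' @return Invisibly, a list with the principal in-memory results and
#'   the manifest.
#' @export
runPipeline <- function(config = demoRunConfig()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  need <- c("out_dir", "seed", "simulate", "design", "genotype", "qc",
            "forensics")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("configuration is missing field(s): ",
         paste(miss, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- config$simulate
  freqs <- stage("simulate", {
    drawFrequencySpectrum(sim$n_loci, sim$maf_bin, seed = seed)
  })
  truth <- stage("simulate", {
    simulatePopulationGenotypes(freqs, sim$n_samples, seed = seed + 1L)
  })
  panel <- stage("simulate", {
    simulateAmpliconPanel(locusIds(freqs), seed = seed + 2L)
  })
  tier <- stage("simulate", qualityTierPresets(sim$tier))
  reads <- stage("simulate", {
    simulateAmpliconReads(panel, truth, tier, seed = seed + 3L,
                          readLength = sim$read_length)
  })

  curve <- stage("design", {
    identityPowerCurve(freqs, threshold = config$design$threshold)
  })
  sx <- config$design$sex
  sex_sim <- stage("design", {
    simulateSexLoci(sx$n_loci, sx$differential, sx$n_males,
                    sx$n_females, seed = seed + 4L)
  })
  sex_screen <- stage("design", {
    screenSexMarkers(alleleFrequencies(sex_sim$genotypes, sex_sim$sex),
                     cutoff = 0.20)
  })

  gt <- config$genotype
  report <- stage("genotype", {
    callGenotypes(countAlleles(reads$reads, panel),
                  minDepth = gt$min_depth, homRatio = gt$hom_ratio,
                  hetBand = gt$het_band)
  })
  called <- callsToGenotypeMatrix(report)

  qc_cfg <- config$qc
  fs <- stage("qc", filterSamples(called, qc_cfg$max_missing_sample))
  fl <- stage("qc", filterLoci(fs$genotypes, qc_cfg$max_missing_locus))
  success <- stage("qc", genotypingSuccess(fl$genotypes))

  fr <- config$forensics
  clusters <- stage("forensics", {
    clusterIndividuals(fl$genotypes, matchTolerance = fr$match_tolerance,
                       minOverlap = fr$min_overlap)
  })
  kin <- stage("forensics", loiselleKinship(fl$genotypes))
  training <- stage("forensics", {
    sexTrainingFrequencies(sex_sim$genotypes, sex_sim$sex)
  })
  sex_calls <- stage("forensics", {
    assignSex(sex_sim$genotypes, training,
              posteriorCutoff = fr$posterior_cutoff)
  })

  od <- config$out_dir
  writeAlleleFrequencyTable(freqs, file.path(od, "frequencies.tsv"))
  writeAmpliconPanel(panel, file.path(od, "panel.tsv"))
  writeGenotypeMatrix(truth, file.path(od, "true_genotypes.tsv"))
  writeGenotypeMatrix(fl$genotypes, file.path(od, "called_genotypes.tsv"))
  utils::write.table(powerCurve(curve), file.path(od, "identity_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sex_screen, file.path(od, "sex_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sex_calls, file.path(od, "sex_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(clusters$clusters),
                                individual = clusters$clusters),
                     file.path(od, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(kin), file.path(od, "kinship.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  jsonlite::write_json(
    list(nUnique = clusters$nUnique,
         minPanelSize = as.list(minPanelSize(curve)),
         genotypingSuccess = success,
         removedSamples = fs$removed, removedLoci = fl$removed),
    file.path(od, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  outputs <- list.files(od, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package = "PanelForge",
    version = as.character(utils::packageVersion("PanelForge")),
    seed = seed,
    stage_seeds = list(frequencies = seed, genotypes = seed + 1L,
                       panel = seed + 2L, reads = seed + 3L,
                       sex_loci = seed + 4L),
    config = config[setdiff(names(config), "out_dir")],
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(freqs = freqs, truth = truth, panel = panel,
                 report = report, genotypes = fl$genotypes,
                 curve = curve, sexScreen = sex_screen,
                 sexCalls = sex_calls, clusters = clusters,
                 kinship = kin, manifest = manifest))
}
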