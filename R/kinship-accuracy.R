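.CATEGORIES <- c("PO", "FS", "HS", "FC", "UR")
# relatedness rank used for "less related wins" tie-breaking
.RELATEDNESS_RANK <- c(PO = 5L, FS = 4L, HS = 3L, FC = 2L, UR = 1L)

#' Relationship-assignment accuracy by dyad simulation
#'
#' Simulates `nDyadsPerCategory` dyads for each of the five relationship
#' categories (PO, FS, HS, FC, UR), estimates each dyad's kinship with
#' the Loiselle estimator against the known generating frequencies, and
#' classifies every dyad by maximum likelihood under per-category normal
#' approximations whose means and variances are fit on an independent
#' training simulation of the same size (training seed = `seed + 1`).
#' Exact likelihood ties go to the less-related category. PO and FS
#' share an expected kinship of 0.25 and differ only in estimate
#' variance, so their mutual confusion dominates the 5x5
#' misclassification matrix; accuracies collapsed to relatedness degree
#' (PO + FS = first degree) are reported alongside.
#'
#' @param freqs an [AlleleFrequencyTable-class]; at least two
#'   polymorphic loci.
#' @param nDyadsPerCategory dyads per category (>= 100).
#' @param seed integer seed (training uses `seed + 1`).
#' @return A [DyadSimulationResult-class].
#' @export
kinshipAssignmentAccuracy <- function(freqs, nDyadsPerCategory, seed) {
  if (nDyadsPerCategory < 100L)
    stop("nDyadsPerCategory must be >= 100")
  p <- alleleFreq(freqs)
  if (sum(p > 0 & p < 1) < 2L)
    stop("need at least 2 polymorphic loci to classify relationships")
  poly <- p[p > 0 & p < 1]

  sim_estimates <- function(base_seed) {
    out <- vector("list", length(.CATEGORIES))
    names(out) <- .CATEGORIES
    for (k in seq_along(.CATEGORIES)) {
      b <- .simulateDyadBatch(poly, .CATEGORIES[k], nDyadsPerCategory,
                              base_seed + 10L * k)
      out[[k]] <- .loiselleDyads(b$g1, b$g2, poly)
    }
    out
  }

  train <- sim_estimates(seed + 1L)
  mu <- vapply(train, mean, numeric(1L))
  sigma <- vapply(train, stats::sd, numeric(1L))
  sigma <- pmax(sigma, 1e-8)  # guard degenerate fits

  test <- sim_estimates(seed)
  assigned <- lapply(test, function(x) .classifyKinship(x, mu, sigma))

  confusion <- t(vapply(.CATEGORIES, function(tr)
    as.numeric(table(factor(assigned[[tr]], levels = .CATEGORIES))) /
      nDyadsPerCategory, numeric(5L)))
  dimnames(confusion) <- list(true = .CATEGORIES,
                              assigned = .CATEGORIES)
  accuracy <- stats::setNames(diag(confusion), .CATEGORIES)
  deg_true <- relatednessDegree(.CATEGORIES)
  degrees <- unique(deg_true)
  degreeAccuracy <- stats::setNames(vapply(degrees, function(dg) {
    cats <- .CATEGORIES[deg_true == dg]
    hits <- vapply(cats, function(tr)
      mean(relatednessDegree(assigned[[tr]]) == dg), numeric(1L))
    mean(hits)
  }, numeric(1L)), degrees)

  new("DyadSimulationResult", estimates = test, confusion = confusion,
      accuracy = accuracy, degreeAccuracy = degreeAccuracy,
      nLoci = length(poly), nDyads = as.integer(nDyadsPerCategory))
}

# max-likelihood assignment under per-category normals; ties go to the
# less-related category
.classifyKinship <- function(x, mu, sigma) {
  ll <- vapply(.CATEGORIES, function(ct)
    stats::dnorm(x, mu[ct], sigma[ct], log = TRUE),
    numeric(length(x)))
  ll <- matrix(ll, ncol = length(.CATEGORIES),
               dimnames = list(NULL, .CATEGORIES))
  rank_order <- order(.RELATEDNESS_RANK[.CATEGORIES])  # least related first
  ll <- ll[, .CATEGORIES[rank_order], drop = FALSE]
  colnames(ll)[max.col(ll, ties.method = "first")]
}

#' @rdname DyadSimulationResult
#' @export
setMethod("confusionMatrix", "DyadSimulationResult",
          function(object) object@confusion)

#' @rdname DyadSimulationResult
#' @param by `"category"` for the five-category accuracies or
#'   `"degree"` for accuracies with PO/FS pooled as first-degree.
#' @export
setMethod("assignmentAccuracy", "DyadSimulationResult",
          function(object, by) {
  by <- match.arg(by, c("category", "degree"))
  if (by == "category") object@accuracy else object@degreeAccuracy
})

setMethod("show", "DyadSimulationResult", function(object) {
  cat(sprintf("DyadSimulationResult: %d dyads/category at %d loci\n",
              object@nDyads, object@nLoci))
  cat("  accuracy by degree:",
      paste(sprintf("%s %.3f", names(object@degreeAccuracy),
                    object@degreeAccuracy), collapse = ", "), "\n")
})

#' Kinship sensitivity analysis over MAF bins and panel sizes
#'
#' Runs [kinshipAssignmentAccuracy()] over a grid of MAF bins and panel
#' sizes, redrawing the frequency panel per replicate and averaging the
#' replicate accuracies, and returns a tidy table. The default grid
#' (panel sizes 50, 100, 200, 400; four replicates) mirrors the
#' standard sensitivity design for amplicon panel selection.
#'
#' @param bins character vector of MAF bin names.
#' @param sizes integer vector of panel sizes.
#' @param nDyadsPerCategory dyads per category per run.
#' @param seed integer seed; replicate r of a grid cell derives its
#'   seeds from `seed + 1000 * r` plus a cell offset.
#' @param replicates independent frequency-panel redraws averaged per
#'   cell (default 4).
#' @return A data.frame with one row per bin x size x category:
#'   `bin`, `nLoci`, `category`, `degree`, `accuracy` (mean five-way
#'   accuracy over replicates), `degreeAccuracy` (mean degree-level
#'   accuracy of the category's degree).
#' @export
kinshipSensitivity <- function(bins = c("low", "moderate", "high",
                                        "proportional"),
                               sizes = c(50L, 100L, 200L, 400L),
                               nDyadsPerCategory = 1000L, seed = 1L,
                               replicates = 4L) {
  rows <- list()
  cell <- 0L
  for (bin in bins) for (n in sizes) {
    cell <- cell + 1L
    acc <- matrix(0, replicates, 5L,
                  dimnames = list(NULL, .CATEGORIES))
    dacc <- matrix(0, replicates, 4L,
                   dimnames = list(NULL,
                                   unique(relatednessDegree(.CATEGORIES))))
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * r + 37L * cell
      freqs <- drawFrequencySpectrum(n, bin, seed = s)
      res <- kinshipAssignmentAccuracy(freqs, nDyadsPerCategory,
                                       seed = s + 1L)
      acc[r, ] <- assignmentAccuracy(res, "category")
      dacc[r, ] <- assignmentAccuracy(res, "degree")
    }
    deg <- relatednessDegree(.CATEGORIES)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = bin, nLoci = n, category = .CATEGORIES, degree = unname(deg),
      accuracy = unname(colMeans(acc)),
      degreeAccuracy = unname(colMeans(dacc)[deg]), row.names = NULL)
  }
  do.call(rbind, rows)
}
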