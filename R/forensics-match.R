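#' @importFrom igraph graph_from_data_frame components make_empty_graph
NULL

#' Collapse samples to unique individuals by multilocus genotype matching
#'
#' Makes a pairwise same-individual decision for every sample pair —
#' `same_individual` when the genotype mismatch rate over co-called loci
#' is at most `matchTolerance` and at least `minOverlap` loci are
#' co-called, `undetermined` when the overlap is insufficient,
#' `different` otherwise — and joins samples into individuals by
#' single-linkage over the same-individual decisions, so chains of
#' degraded samples still merge. A small nonzero tolerance absorbs the
#' residual genotyping discordance of noninvasive samples. The empirical
#' multilocus P_ID / P_IDsib of the locus set is attached for
#' interpretability.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param matchTolerance maximum mismatch rate still treated as the same
#'   individual (default 0.02).
#' @param minOverlap minimum co-called loci for a decision (default 50;
#'   must not exceed the locus count).
#' @param linkage `"single"` (default) or `"complete"` — with complete
#'   linkage a sample joins a cluster only if it matches every member.
#' @return A list: `nUnique`, `clusters` (named membership vector:
#'   sample -> individual label), `decisions` (data.frame of pairwise
#'   `sample_a`, `sample_b`, `nCompared`, `nMismatch`, `mismatchRate`,
#'   `decision`), `identityPower` (named numeric `pId`, `pIdSib`).
#' @export
clusterIndividuals <- function(gm, matchTolerance = 0.02,
                               minOverlap = 50L,
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (ncol(gm) < 1L) stop("no samples")
  if (minOverlap > nrow(gm))
    stop("minOverlap (", minOverlap, ") exceeds the locus count (",
         nrow(gm), ")")
  d <- dosage(gm)
  S <- ncol(d)
  ids <- colnames(d)
  combos <- if (S > 1L) utils::combn(S, 2L) else
    matrix(integer(0), nrow = 2L)
  dec <- data.frame(sample_a = ids[combos[1L, ]],
                    sample_b = ids[combos[2L, ]],
                    nCompared = integer(ncol(combos)),
                    nMismatch = integer(ncol(combos)),
                    mismatchRate = numeric(ncol(combos)),
                    decision = character(ncol(combos)))
  for (k in seq_len(ncol(combos))) {
    i <- combos[1L, k]; j <- combos[2L, k]
    comp <- !is.na(d[, i]) & !is.na(d[, j])
    n <- sum(comp)
    mm <- sum(d[comp, i] != d[comp, j])
    dec$nCompared[k] <- n
    dec$nMismatch[k] <- mm
    dec$mismatchRate[k] <- if (n > 0) mm / n else NA_real_
    dec$decision[k] <- if (n < minOverlap) "undetermined"
      else if (mm / n <= matchTolerance) "same_individual"
      else "different"
  }
  same <- dec[dec$decision == "same_individual", c("sample_a", "sample_b"),
              drop = FALSE]
  membership <- .linkClusters(ids, same, linkage,
                              stats::setNames(dec$mismatchRate,
                                              paste(dec$sample_a,
                                                    dec$sample_b)),
                              matchTolerance, dec)
  cluster_labels <- sprintf("individual_%03d",
                            as.integer(factor(membership,
                                              levels = unique(membership))))
  names(cluster_labels) <- ids
  list(nUnique = length(unique(membership)),
       clusters = cluster_labels,
       decisions = dec,
       identityPower = empiricalIdentityPower(gm))
}

# single linkage: connected components over same-individual edges.
# complete linkage: greedy agglomeration requiring every cross-pair to
# be a same-individual decision.
.linkClusters <- function(ids, same_edges, linkage, rates, tol, dec) {
  if (linkage == "single") {
    g <- if (nrow(same_edges))
      graph_from_data_frame(same_edges, directed = FALSE,
                            vertices = data.frame(name = ids))
    else graph_from_data_frame(data.frame(from = character(),
                                          to = character()),
                               directed = FALSE,
                               vertices = data.frame(name = ids))
    comp <- components(g)
    return(comp$membership[ids])
  }
  # complete linkage
  is_same <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(dec)))
    assign(paste(dec$sample_a[k], dec$sample_b[k]),
           dec$decision[k] == "same_individual", envir = is_same)
  linked <- function(a, b) {
    key1 <- paste(a, b); key2 <- paste(b, a)
    if (exists(key1, envir = is_same)) get(key1, envir = is_same)
    else if (exists(key2, envir = is_same)) get(key2, envir = is_same)
    else FALSE
  }
  clusters <- lapply(ids, identity)
  changed <- TRUE
  while (changed && length(clusters) > 1L) {
    changed <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        ok <- all(outer(clusters[[i]], clusters[[j]], Vectorize(linked)))
        if (ok) {
          clusters[[i]] <- c(clusters[[i]], clusters[[j]])
          clusters[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  membership <- integer(length(ids))
  names(membership) <- ids
  for (c_i in seq_along(clusters)) membership[clusters[[c_i]]] <- c_i
  membership
}

#' Summarise genetic mark-recapture from genotype clusters
#'
#' Tallies captures per identified individual and, when capture
#' coordinates are supplied, the pairwise distances between captures of
#' the same individual — Euclidean for projected `x`/`y` coordinates (in
#' the units supplied, typically metres), great-circle for `lon`/`lat`.
#'
#' @param clusters result of [clusterIndividuals()] (or a named
#'   sample -> individual membership vector).
#' @param coordinates optional data.frame with `sample` plus `x`,`y` or
#'   `lon`,`lat` columns.
#' @param mode `"euclidean"` or `"greatcircle"`; the default picks by
#'   the coordinate columns present.
#' @return A list: `captures` (data.frame `individual`, `nCaptures`,
#'   `samples`), `distances` (data.frame `individual`, `sample_a`,
#'   `sample_b`, `distance`; omitted when no coordinates are given).
#' @export
markRecaptureSummary <- function(clusters, coordinates = NULL,
                                 mode = NULL) {
  membership <- if (is.list(clusters)) clusters$clusters else clusters
  caps <- split(names(membership), membership)
  captures <- data.frame(individual = names(caps),
                         nCaptures = lengths(caps),
                         samples = vapply(caps, paste, character(1L),
                                          collapse = ","),
                         row.names = NULL)
  out <- list(captures = captures[order(-captures$nCaptures), ,
                                  drop = FALSE])
  if (!is.null(coordinates)) {
    stopifnot("sample" %in% names(coordinates))
    geo <- all(c("lon", "lat") %in% names(coordinates))
    if (is.null(mode)) mode <- if (geo) "greatcircle" else "euclidean"
    mode <- match.arg(mode, c("euclidean", "greatcircle"))
    rows <- list()
    for (ind in names(caps)) {
      ss <- intersect(caps[[ind]], coordinates$sample)
      if (length(ss) < 2L) next
      cc <- coordinates[match(ss, coordinates$sample), , drop = FALSE]
      cb <- utils::combn(seq_along(ss), 2L)
      dist <- vapply(seq_len(ncol(cb)), function(k) {
        i <- cb[1L, k]; j <- cb[2L, k]
        if (mode == "greatcircle")
          geosphere::distHaversine(c(cc$lon[i], cc$lat[i]),
                                   c(cc$lon[j], cc$lat[j]))
        else sqrt((cc$x[i] - cc$x[j])^2 + (cc$y[i] - cc$y[j])^2)
      }, numeric(1L))
      rows[[ind]] <- data.frame(individual = ind,
                                sample_a = ss[cb[1L, ]],
                                sample_b = ss[cb[2L, ]],
                                distance = dist, row.names = NULL)
    }
    out$distances <- if (length(rows)) do.call(rbind, rows) else
      data.frame(individual = character(), sample_a = character(),
                 sample_b = character(), distance = numeric())
    rownames(out$distances) <- NULL
  }
  out
}
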