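#' Interaction counts between insect and plant taxa
#'
#' Counts `W[i, j]`, the number of network edges joining insects of taxon
#' `i` (at `insectLevel`) to plants of family (or other `plantLevel`) `j`.
#' Edges with an endpoint that cannot be resolved at the requested level are
#' excluded and their count reported via a message and the `"droppedEdges"`
#' attribute.
#'
#' @param net a [PlantHerbivoreNetwork-class].
#' @param insectTaxonomy,plantTaxonomy [TaxonomyMap-class] objects for the
#'   two sides.
#' @param insectLevel,plantLevel taxonomic level names (`"family"`,
#'   `"subfamily"`, ...).
#' @return integer matrix of counts (insect taxa x plant taxa).
#' @export
interactionCounts <- function(net, insectTaxonomy, plantTaxonomy,
                              insectLevel = "family",
                              plantLevel = "family") {
  M <- asIncidenceMatrix(net)
  iInd <- .taxonIndicator(rownames(M), insectTaxonomy, insectLevel)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, plantLevel)
  W <- t(iInd) %*% M %*% pInd
  dropped <- sum(M) - sum(W)
  if (dropped > 0)
    message(dropped, " edge(s) dropped: endpoint unresolved at requested level")
  storage.mode(W) <- "integer"
  attr(W, "droppedEdges") <- as.integer(dropped)
  W
}

#' Z-scores of insect-plant taxon interaction frequencies
#'
#' Scores every `W[i, j]` cell of [interactionCounts()] against its
#' distribution over randomized networks. Positive Z marks an
#' over-represented (attraction-like) feeding relationship, negative Z an
#' under-represented (avoidance-like) one. Cells whose null distribution
#' has zero spread are flagged degenerate rather than dropped.
#'
#' @inheritParams interactionCounts
#' @param config a [NullModelConfig-class].
#' @return long-format `data.frame` with columns `insectTaxon`,
#'   `plantTaxon`, `W`, `nullMean`, `nullSd`, `z`, `degenerate`.
#' @export
familyZScores <- function(net, insectTaxonomy, plantTaxonomy,
                          insectLevel = "family", plantLevel = "family",
                          config = nullModelConfig()) {
  M <- asIncidenceMatrix(net)
  iInd <- .taxonIndicator(rownames(M), insectTaxonomy, insectLevel)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, plantLevel)
  Wobs <- t(iInd) %*% M %*% pInd
  arr <- .nullArray(M, config)
  R <- dim(arr)[3]
  Wnull <- matrix(vapply(seq_len(R),
                         function(r) as.vector(t(iInd) %*% arr[, , r] %*% pInd),
                         numeric(length(Wobs))),
                  nrow = length(Wobs))
  mu <- rowMeans(Wnull)
  sdv <- apply(Wnull, 1, stats::sd)
  degen <- sdv == 0
  z <- ifelse(degen, NA_real_, (as.vector(Wobs) - mu) / sdv)
  data.frame(insectTaxon = rep(rownames(Wobs), times = ncol(Wobs)),
             plantTaxon = rep(colnames(Wobs), each = nrow(Wobs)),
             W = as.vector(Wobs), nullMean = mu, nullSd = sdv, z = z,
             degenerate = degen, stringsAsFactors = FALSE)
}

.categoryMembers <- function(net, insectTaxonomy, category, level) {
  ins <- insectSpecies(net)
  if (level == "species") {
    if (!(category %in% ins)) stop("species not in network: ", category)
    return(category)
  }
  if (is.null(insectTaxonomy))
    stop("insectTaxonomy required for level '", level, "'")
  taxa <- taxonOf(insectTaxonomy, ins, level)
  members <- ins[!is.na(taxa) & taxa == category]
  if (!length(members))
    stop("no network insects in ", level, " '", category, "'")
  members
}

#' Plant family-based evenness of an insect category's diet
#'
#' Shannon evenness of an insect category's host plants across plant
#' families, normalized by `log` of the number of plant families present in
#' the whole network (`|m_f|`), so values are comparable across categories:
#' 0 when all hosts fall in one plant family, 1 when hosts are spread
#' exactly evenly over every family in the network. Natural logarithms;
#' `0 * log(0)` is taken as 0 and a single-family network has evenness 0.
#'
#' @inheritParams interactionCounts
#' @param category a species name, or a subfamily/family name resolved via
#'   `insectTaxonomy`.
#' @param level `"species"`, `"subfamily"` or `"family"`.
#' @return one-row `data.frame`: `category`, `level`, `hosts` (number of
#'   distinct host plants with known family), `nFamiliesUsed`, `E`.
#' @export
evenness <- function(net, plantTaxonomy, category, level = "species",
                     insectTaxonomy = NULL) {
  if (!(level %in% c("species", "subfamily", "family")))
    stop("unknown level: ", level)
  members <- .categoryMembers(net, insectTaxonomy, category, level)
  M <- asIncidenceMatrix(net)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, "family")
  counts <- .categoryFamilyCounts(M, match(members, rownames(M)), pInd)
  E <- .evennessFromCounts(counts, ncol(pInd))
  if (is.na(E)) stop("category has no host plant with known family: ", category)
  data.frame(category = category, level = level,
             hosts = as.integer(sum(counts)),
             nFamiliesUsed = as.integer(sum(counts > 0)), E = E,
             stringsAsFactors = FALSE)
}

#' Average species-level evenness of a network
#'
#' Unweighted mean of the plant family-based evenness over all insect
#' species in the network (species with no family-resolvable host are
#' excluded).
#'
#' @inheritParams interactionCounts
#' @return a single number in `[0, 1]`.
#' @export
averageEvenness <- function(net, plantTaxonomy) {
  M <- asIncidenceMatrix(net)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, "family")
  mean(.rowEvenness(M, pInd), na.rm = TRUE)
}

#' Feed-on-family test: evenness against the degree-preserving null
#'
#' Scores the network-average species-level evenness, and the pooled
#' evenness of each insect family/subfamily, against randomized networks.
#' A strongly negative global Z says diets are concentrated on fewer plant
#' families than degree-matched chance allows - the signature of
#' taxonomy-driven host selection. All statistics are evaluated on one
#' shared replicate stream so per-category scores are coherent.
#'
#' @inheritParams familyZScores
#' @param levels insect levels for per-category scores.
#' @return list with `global` (a [ZScoreResult-class]) and `perCategory`
#'   (`data.frame`: `level`, `category`, `observed`, `nullMean`, `nullSd`,
#'   `z`, `degenerate`).
#' @export
evennessTest <- function(net, plantTaxonomy, insectTaxonomy = NULL,
                         config = nullModelConfig(),
                         levels = c("family", "subfamily")) {
  M <- asIncidenceMatrix(net)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, "family")
  arr <- .nullArray(M, config)
  suite <- .zTestSuite(M, arr, pInd, insectTaxonomy = insectTaxonomy,
                       levels = levels, doEvenness = TRUE, doNs = FALSE)
  list(global = suite$evenGlobal, perCategory = suite$evenPerCategory)
}

#' Average neighbour degree of a plant
#'
#' For a plant species, the mean - over the butterflies that feed on it -
#' of the number of distinct host-plant families each butterfly uses. Low
#' values mean the plant is eaten mostly by mono-family-phagous herbivores.
#'
#' @inheritParams interactionCounts
#' @param plant a plant species present in the network.
#' @return a single number >= 1.
#' @export
averageNeighbourDegree <- function(net, plantTaxonomy, plant) {
  M <- asIncidenceMatrix(net)
  if (!(plant %in% colnames(M))) stop("plant not in network: ", plant)
  herbs <- M[, plant] > 0
  if (!any(herbs)) stop("plant has no herbivore: ", plant)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, "family")
  mean(.insectFamilyBreadth(M, pInd)[herbs])
}

#' Pearson similarity of ecozone family compositions
#'
#' Converts each ecozone's family counts to relative proportions (columns
#' sum to 1) and returns the matrix of pairwise Pearson correlations, so
#' the measure is invariant to total species richness per ecozone.
#'
#' @param composition numeric matrix of non-negative counts, rows =
#'   herbivore families, columns = ecozones.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
ecozoneSimilarity <- function(composition) {
  composition <- as.matrix(composition)
  if (nrow(composition) < 2L || ncol(composition) < 2L)
    stop("need at least 2 families and 2 ecozones")
  if (any(composition < 0)) stop("counts must be non-negative")
  tot <- colSums(composition)
  if (any(tot == 0)) stop("ecozone with zero total: proportions undefined")
  stats::cor(sweep(composition, 2, tot, "/"))
}
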