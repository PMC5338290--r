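#' Number of compounds shared by two plants
#'
#' @param catalog a [CompoundCatalog-class].
#' @param a,b plant species names; a plant absent from the catalog has an
#'   empty compound set.
#' @return `|C_a` \eqn{\cap} `C_b|`, a non-negative integer; symmetric in
#'   its arguments.
#' @export
sharedCompoundCount <- function(catalog, a, b) {
  length(intersect(compoundsOf(catalog, a), compoundsOf(catalog, b)))
}

#' Food-pairing statistic N_s: mean compounds shared among host plants
#'
#' For a butterfly with `n >= 2` host plants, `N_s` is the mean of the
#' shared-compound count over all unordered pairs of its hosts. Butterflies
#' with fewer than two hosts have no pair average and are excluded, not
#' zero-filled; the exclusion count is attached as attribute
#' `"excluded"` on batch output.
#'
#' @param net a [PlantHerbivoreNetwork-class] (normally the
#'   compound-filtered network, so every host is annotated).
#' @param catalog a [CompoundCatalog-class].
#' @param butterfly a single species name, or `NULL` (default) for all
#'   insect species in the network.
#' @return `data.frame` with columns `butterfly`, `nHosts`, `Ns` (one row
#'   per included species).
#' @export
foodPairingNs <- function(net, catalog, butterfly = NULL) {
  M <- asIncidenceMatrix(net)
  if (!is.null(butterfly)) {
    if (!(butterfly %in% rownames(M)))
      stop("butterfly not in network: ", butterfly)
    M <- M[butterfly, , drop = FALSE]
  }
  O <- .overlapMatrix(catalog, colnames(M))
  ns <- .rowNs(M, O)
  keep <- !is.na(ns)
  if (!is.null(butterfly) && !any(keep))
    stop("butterfly has fewer than 2 hosts: ", butterfly)
  out <- data.frame(butterfly = rownames(M)[keep],
                    nHosts = as.integer(rowSums(M)[keep]),
                    Ns = ns[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- as.integer(sum(!keep))
  out
}

#' Feed-on-compound test: N_s against the degree-preserving null
#'
#' Scores the across-species mean of the food-pairing statistic, and its
#' per-family/subfamily means, against randomized networks. A positive
#' global Z says a butterfly's hosts share more compounds than
#' degree-matched chance - the signature of chemistry-driven host
#' selection.
#'
#' @inheritParams selectionTests
#' @return list with `global` (a [ZScoreResult-class]), `perCategory`
#'   (`data.frame` as in [evennessTest()]) and `excluded` (species dropped
#'   for having < 2 hosts).
#' @export
feedOnCompoundTest <- function(net, catalog, insectTaxonomy = NULL,
                               plantTaxonomy = NULL,
                               config = nullModelConfig(),
                               levels = c("family", "subfamily")) {
  M <- asIncidenceMatrix(net)
  if (nEdges(net) == 0L) stop("empty network")
  O <- .overlapMatrix(catalog, colnames(M))
  pInd <- matrix(1, ncol(M), 1, dimnames = list(colnames(M), "all"))
  arr <- .nullArray(M, config)
  suite <- .zTestSuite(M, arr, pInd, O = O, insectTaxonomy = insectTaxonomy,
                       levels = levels, doEvenness = FALSE, doNs = TRUE)
  list(global = suite$nsGlobal, perCategory = suite$nsPerCategory,
       excluded = suite$nsExcluded)
}

#' Coefficient of compound contribution of a plant
#'
#' `chi = T1 - T2`, where `T1` is the mean - over the plant's herbivores
#' with at least two hosts - of the average compound overlap between the
#' plant and the herbivore's other host plants, and `T2` is the average
#' overlap between the plant and every other plant in the network (the
#' expectation under no host-plant selectivity). Positive chi marks a
#' plant whose chemistry pulls its herbivores' diets together.
#'
#' @inheritParams foodPairingNs
#' @param plant a single plant species, or `NULL` (default) for all plants.
#' @return `data.frame` with columns `plant`, `chi`, `fI` (herbivore
#'   count), `degree` (same, kept for plotting), `SI` (mean host count of
#'   the plant's herbivores, reported for transparency; not used by the
#'   statistic).
#' @export
compoundContributionChi <- function(net, catalog, plant = NULL) {
  M <- asIncidenceMatrix(net)
  if (ncol(M) < 2L) stop("need at least 2 plants")
  O <- .overlapMatrix(catalog, colnames(M))
  chi <- .chiVec(M, O)
  fI <- colSums(M)
  n <- rowSums(M)
  SI <- as.vector(crossprod(M, n)) / ifelse(fI > 0, fI, 1)
  SI[fI == 0] <- NA_real_
  out <- data.frame(plant = colnames(M), chi = chi,
                    fI = as.integer(fI), degree = as.integer(fI),
                    SI = SI, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(plant)) {
    if (!(plant %in% out$plant)) stop("plant not in network: ", plant)
    out <- out[out$plant == plant, , drop = FALSE]
    if (out$fI == 0L) stop("plant has no herbivore: ", plant)
    rownames(out) <- NULL
  }
  out
}

#' Compound contribution against degree, with rank correlation
#'
#' One row per plant with its chi, degree and average neighbour degree,
#' plus the Spearman rank correlation of chi against degree (suppressed,
#' with a note, when fewer than 3 plants have defined chi or chi has zero
#' variance).
#'
#' @inheritParams selectionTests
#' @return list with `table` (`data.frame`: `plant`, `plantFamily`, `chi`,
#'   `degree`, `avgNeighbourDegree`) and `spearman` (list `rho`, `p`, or
#'   `NULL` when suppressed).
#' @export
chiDegreeProfile <- function(net, catalog, plantTaxonomy,
                             insectTaxonomy = NULL) {
  M <- asIncidenceMatrix(net)
  if (nEdges(net) == 0L) stop("empty network")
  chiTab <- compoundContributionChi(net, catalog)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, "family")
  breadth <- .insectFamilyBreadth(M, pInd)
  fI <- colSums(M)
  andeg <- as.vector(crossprod(M, breadth)) / ifelse(fI > 0, fI, 1)
  andeg[fI == 0] <- NA_real_
  tab <- data.frame(plant = chiTab$plant,
                    plantFamily = unname(taxonOf(plantTaxonomy, chiTab$plant)),
                    chi = chiTab$chi, degree = chiTab$degree,
                    avgNeighbourDegree = andeg, stringsAsFactors = FALSE)
  ok <- !is.na(tab$chi)
  sp <- NULL
  if (sum(ok) >= 3L && stats::sd(tab$chi[ok]) > 0 &&
      stats::sd(tab$degree[ok]) > 0) {
    ct <- suppressWarnings(stats::cor.test(tab$chi[ok], tab$degree[ok],
                                           method = "spearman",
                                           exact = FALSE))
    sp <- list(rho = unname(ct$estimate), p = ct$p.value)
  } else {
    message("Spearman correlation suppressed: ",
            "fewer than 3 plants with defined chi, or zero variance")
  }
  list(table = tab, spearman = sp)
}

# two-sided exact p for a 2x2 table (conditional hypergeometric)
.fisher2x2 <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
}

.cramersV <- function(a, b, c, d) {
  n <- a + b + c + d
  m1 <- (a + b) * (c + d) * (a + c) * (b + d)
  if (n == 0 || m1 == 0) return(0)
  chi2 <- n * (a * d - b * c)^2 / m1
  sqrt(chi2 / n)
}

#' Screen for compounds specific to a clade's host plants
#'
#' For every compound found on at least one network plant, builds the 2x2
#' contingency table (clade vs non-clade) x (host plant possesses the
#' compound vs not) and computes a two-sided Fisher's exact p together
#' with Cramer's V (from the Pearson chi-square without continuity
#' correction). The default observation unit is the plant-herbivore
#' relationship (edges), matching an analysis whose sample size is the
#' number of relationships; the plant-species unit is offered because
#' relationship rows are not independent - a note reminds the caller of
#' this on every relationship-unit run.
#'
#' @inheritParams selectionTests
#' @param clade insect taxon name (e.g. a subfamily such as `"Pierinae"`).
#' @param level level of `clade`: `"family"` or `"subfamily"`.
#' @param unit `"relationship"` (default) or `"plant"`.
#' @param pThreshold fixed significance threshold for the `pass` flag
#'   (default `1e-6`, an effect-size-calibrated cut rather than an FDR).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values in column `pAdj`.
#' @return `data.frame`, one row per compound: `compound`, `clade`, `a`
#'   (clade & has compound), `b` (clade & lacks it), `c` (non-clade & has),
#'   `d` (non-clade & lacks), `p`, `cramersV`, `direction`, `pass`, sorted
#'   by decreasing `cramersV`.
#' @export
enrichment <- function(net, catalog, insectTaxonomy, clade,
                       level = "family", unit = c("relationship", "plant"),
                       pThreshold = 1e-6, adjust = c("none", "BH")) {
  unit <- match.arg(unit); adjust <- match.arg(adjust)
  if (nEdges(net) == 0L) stop("empty network")
  ed <- interactionEdges(net)
  taxa <- taxonOf(insectTaxonomy, ed$insect, level)
  inClade <- !is.na(taxa) & taxa == clade
  if (!any(inClade)) stop("clade not present in network: ", clade)
  if (unit == "relationship")
    message("enrichment unit = relationship: rows are plant-herbivore ",
            "edges and are not independent observations")

  plants <- plantSpecies(net)
  sets <- compoundsOf(catalog, plants)
  if (length(plants) == 1L) sets <- stats::setNames(list(sets), plants)
  compounds <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(compounds)) stop("no compound found on any network plant")
  has <- matrix(FALSE, length(plants), length(compounds),
                dimnames = list(plants, compounds))
  for (i in seq_along(plants)) has[i, match(sets[[i]], compounds)] <- TRUE

  if (unit == "relationship") {
    hp <- has[match(ed$plant, plants), , drop = FALSE]
    grp <- inClade
  } else {
    # plant unit: a plant counts for the clade if any clade member eats it
    cladePlants <- unique(ed$plant[inClade])
    hp <- has
    grp <- plants %in% cladePlants
  }
  a <- colSums(hp[grp, , drop = FALSE])
  c_ <- colSums(hp[!grp, , drop = FALSE])
  b <- sum(grp) - a
  d <- sum(!grp) - c_

  p <- vapply(seq_along(compounds), function(i)
    .fisher2x2(a[i], b[i], c_[i], d[i]), numeric(1))
  V <- vapply(seq_along(compounds), function(i)
    .cramersV(a[i], b[i], c_[i], d[i]), numeric(1))
  direction <- ifelse(a * d >= b * c_, "enriched", "depleted")
  out <- data.frame(compound = compounds, clade = clade,
                    a = as.integer(a), b = as.integer(b),
                    c = as.integer(c_), d = as.integer(d),
                    p = p, cramersV = V, direction = direction,
                    stringsAsFactors = FALSE)
  if (adjust == "BH") out$pAdj <- stats::p.adjust(out$p, "BH")
  out$pass <- (if (adjust == "BH") out$pAdj else out$p) < pThreshold
  out <- out[order(-out$cramersV, out$p, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition compounds into common / common-specific / other
#'
#' Relative to a focal host set and a disjoint background set of plants:
#' a compound present in every plant of both sets is "common"
#' (chemically uninformative for host selection); one present in every
#' host plant and absent from every background plant is "common specific"
#' (a candidate attractant for the herbivores of the host set); anything
#' else found on these plants is "other".
#'
#' @param catalog a [CompoundCatalog-class].
#' @param hostSet,backgroundSet disjoint, non-empty character vectors of
#'   plant species.
#' @return list with character vectors `common`, `commonSpecific`, `other`.
#' @export
commonVsCommonSpecific <- function(catalog, hostSet, backgroundSet) {
  if (!length(hostSet) || !length(backgroundSet))
    stop("hostSet and backgroundSet must be non-empty")
  if (length(intersect(hostSet, backgroundSet)))
    stop("hostSet and backgroundSet must be disjoint")
  hostSets <- lapply(hostSet, function(p) compoundsOf(catalog, p))
  bgSets <- lapply(backgroundSet, function(p) compoundsOf(catalog, p))
  inAllHosts <- Reduce(intersect, hostSets)
  inAllBg <- Reduce(intersect, bgSets)
  inAnyBg <- unique(unlist(bgSets))
  common <- intersect(inAllHosts, inAllBg)
  commonSpecific <- setdiff(inAllHosts, inAnyBg)
  everything <- unique(c(unlist(hostSets), inAnyBg))
  list(common = sort(common), commonSpecific = sort(commonSpecific),
       other = sort(setdiff(everything, c(common, commonSpecific))))
}
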