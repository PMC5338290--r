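# Shared null-test engine: evaluates the evenness and food-pairing
# statistics (global and per insect category) on one observed incidence
# matrix and one pre-generated array of null replicates, so that all
# Z-scores reported together derive from the same replicate stream.

.memberIndex <- function(M, insectTaxonomy, levels) {
  out <- list()
  if (is.null(insectTaxonomy)) return(out)
  for (lv in levels) {
    taxa <- taxonOf(insectTaxonomy, rownames(M), lv)
    ok <- !is.na(taxa)
    if (!any(ok)) next
    idx <- split(which(ok), taxa[ok])
    for (nm in names(idx))
      out[[length(out) + 1L]] <- list(level = lv, category = nm,
                                      rows = idx[[nm]])
  }
  out
}

.zTestSuite <- function(M, arr, plantFamInd, O = NULL,
                        insectTaxonomy = NULL,
                        levels = c("family", "subfamily"),
                        doEvenness = TRUE, doNs = TRUE) {
  R <- dim(arr)[3]
  members <- .memberIndex(M, insectTaxonomy, levels)
  K <- ncol(plantFamInd)

  evenObs <- nsObs <- NULL
  evenCatObs <- nsCatObs <- numeric(length(members))
  evenNull <- nsNull <- numeric(R)
  evenCatNull <- nsCatNull <- matrix(NA_real_, length(members), R)

  catEven <- function(Mx) vapply(members, function(mb)
    .evennessFromCounts(.categoryFamilyCounts(Mx, mb$rows, plantFamInd), K),
    numeric(1))
  catNs <- function(nsRow) vapply(members, function(mb) {
    v <- nsRow[mb$rows]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))

  if (doEvenness) {
    evenObs <- mean(.rowEvenness(M, plantFamInd), na.rm = TRUE)
    if (length(members)) evenCatObs <- catEven(M)
  }
  nsExcluded <- 0L
  if (doNs) {
    nsRow <- .rowNs(M, O)
    nsExcluded <- sum(is.na(nsRow))
    nsObs <- mean(nsRow, na.rm = TRUE)
    if (length(members)) nsCatObs <- catNs(nsRow)
  }
  for (r in seq_len(R)) {
    Mr <- arr[, , r]
    if (doEvenness) {
      evenNull[r] <- mean(.rowEvenness(Mr, plantFamInd), na.rm = TRUE)
      if (length(members)) evenCatNull[, r] <- catEven(Mr)
    }
    if (doNs) {
      nsRowR <- .rowNs(Mr, O)
      nsNull[r] <- mean(nsRowR, na.rm = TRUE)
      if (length(members)) nsCatNull[, r] <- catNs(nsRowR)
    }
  }

  perCat <- function(obs, nullMat) {
    if (!length(members)) return(.emptyPerCategory())
    mu <- rowMeans(nullMat, na.rm = TRUE)
    sdv <- apply(nullMat, 1, stats::sd, na.rm = TRUE)
    degen <- !is.na(sdv) & sdv == 0
    data.frame(
      level = vapply(members, `[[`, "", "level"),
      category = vapply(members, `[[`, "", "category"),
      observed = obs, nullMean = mu, nullSd = sdv,
      z = ifelse(degen | is.na(sdv), NA_real_, (obs - mu) / sdv),
      degenerate = degen, stringsAsFactors = FALSE)
  }

  out <- list()
  if (doEvenness) {
    out$evenGlobal <- zScore(evenObs, evenNull)
    out$evenPerCategory <- perCat(evenCatObs, evenCatNull)
  }
  if (doNs) {
    out$nsGlobal <- zScore(nsObs, nsNull)
    out$nsPerCategory <- perCat(nsCatObs, nsCatNull)
    out$nsExcluded <- nsExcluded
  }
  out
}

.emptyPerCategory <- function() {
  data.frame(level = character(0), category = character(0),
             observed = numeric(0), nullMean = numeric(0),
             nullSd = numeric(0), z = numeric(0), degenerate = logical(0),
             stringsAsFactors = FALSE)
}

#' Joint feed-on-family / feed-on-compound test
#'
#' Evaluates both the evenness (feed-on-family) and food-pairing
#' (feed-on-compound) statistics against one shared stream of randomized
#' networks, globally and per insect family/subfamily. This is the engine
#' behind [evennessTest()] and [feedOnCompoundTest()] and the natural way
#' to produce the two Z-scores side by side for a scatterplot of
#' taxonomy-driven against chemistry-driven host selection.
#'
#' @inheritParams familyZScores
#' @param catalog a [CompoundCatalog-class].
#' @param levels insect levels for the per-category scores.
#' @return list with elements `evenGlobal`, `evenPerCategory`, `nsGlobal`,
#'   `nsPerCategory` (see [evennessTest()] and [feedOnCompoundTest()]) and
#'   `nsExcluded`, the number of species excluded from the food-pairing
#'   mean for having fewer than two hosts.
#' @export
selectionTests <- function(net, catalog, plantTaxonomy,
                           insectTaxonomy = NULL,
                           config = nullModelConfig(),
                           levels = c("family", "subfamily")) {
  M <- asIncidenceMatrix(net)
  pInd <- .taxonIndicator(colnames(M), plantTaxonomy, "family")
  O <- .overlapMatrix(catalog, colnames(M))
  arr <- .nullArray(M, config)
  .zTestSuite(M, arr, pInd, O = O, insectTaxonomy = insectTaxonomy,
              levels = levels, doEvenness = TRUE, doNs = TRUE)
}
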