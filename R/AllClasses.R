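#' @import methods
NULL

.trimOne <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' PlantHerbivoreNetwork: a bipartite insect-plant interaction network
#'
#' Holds an unweighted, undirected bipartite edge set between herbivorous
#' insect species and plant species. Node sets are stored explicitly so a
#' network may retain isolated species (e.g. after subsetting the edge set).
#'
#' @slot insects character vector of insect species names (canonical
#'   binomials, unique).
#' @slot plants character vector of plant species names (unique).
#' @slot edges two-column `data.frame` (`insect`, `plant`); one row per
#'   interaction, no duplicates, endpoints drawn from the node sets.
#'
#' @seealso [plantHerbivoreNetwork()] for construction,
#'   [readInteractionTable()] to read one from a delimited file.
#' @export
setClass("PlantHerbivoreNetwork",
  representation(insects = "character", plants = "character",
                 edges = "data.frame"))

setValidity("PlantHerbivoreNetwork", function(object) {
  msg <- character(0)
  ins <- object@insects; pls <- object@plants; ed <- object@edges
  if (!identical(colnames(ed), c("insect", "plant")))
    msg <- c(msg, "edges must have columns 'insect', 'plant'")
  chk <- function(x, lab) {
    if (any(!nzchar(x))) msg <<- c(msg, paste(lab, "names must be non-empty"))
    if (any(x != trimws(x)))
      msg <<- c(msg, paste(lab, "names must have no leading/trailing whitespace"))
    if (anyDuplicated(x)) msg <<- c(msg, paste("duplicated", lab, "names"))
  }
  chk(ins, "insect"); chk(pls, "plant")
  if (identical(colnames(ed), c("insect", "plant"))) {
    if (!all(ed$insect %in% ins)) msg <- c(msg, "edge references unknown insect")
    if (!all(ed$plant %in% pls)) msg <- c(msg, "edge references unknown plant")
    if (anyDuplicated(paste(ed$insect, ed$plant, sep = "\r")))
      msg <- c(msg, "duplicated edges")
  }
  if (length(msg)) msg else TRUE
})

#' TaxonomyMap: species-level taxonomy for one side of a network
#'
#' Maps each species to genus, subfamily, family and order. Family is
#' mandatory; the other ranks may be absent (`NA`), e.g. for unplaced taxa.
#'
#' @slot records `data.frame` with columns `species`, `genus`, `subfamily`,
#'   `family`, `order`; one row per species.
#' @slot side `"insect"` or `"plant"`.
#'
#' @seealso [taxonomyMap()], [readTaxonomyTable()]
#' @export
setClass("TaxonomyMap",
  representation(records = "data.frame", side = "character"))

setValidity("TaxonomyMap", function(object) {
  msg <- character(0)
  rec <- object@records
  need <- c("species", "genus", "subfamily", "family", "order")
  if (!all(need %in% colnames(rec)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(rec$species))
      msg <- c(msg, "more than one record for a species")
    if (any(is.na(rec$family) | !nzchar(rec$family)))
      msg <- c(msg, "every species must have a family")
  }
  if (!(length(object@side) == 1L && object@side %in% c("insect", "plant")))
    msg <- c(msg, "side must be 'insect' or 'plant'")
  if (length(msg)) msg else TRUE
})

#' CompoundCatalog: per-plant sets of chemical compound identifiers
#'
#' Maps plant species to the set of compounds reported for them (e.g.
#' KNApSAcK-style identifiers). Compound identifiers are opaque strings;
#' a plant absent from the catalog has, by convention, an empty set.
#'
#' @slot sets named list; names are plant species, elements are character
#'   vectors of compound identifiers (unique within a plant).
#'
#' @seealso [compoundCatalog()], [readCompoundTable()], [compoundsOf()]
#' @export
setClass("CompoundCatalog", representation(sets = "list"))

setValidity("CompoundCatalog", function(object) {
  msg <- character(0)
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      msg <- c(msg, "sets must be named by plant species")
    if (anyDuplicated(names(s))) msg <- c(msg, "duplicated plant names")
    for (i in seq_along(s)) {
      v <- s[[i]]
      if (!is.character(v)) { msg <- c(msg, "each set must be character"); break }
      if (any(!nzchar(v)) || anyNA(v)) { msg <- c(msg, "empty compound identifier"); break }
      if (anyDuplicated(v)) { msg <- c(msg, "duplicated compound within a plant"); break }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ZScoreResult: an observed statistic scored against a null distribution
#'
#' @slot observed observed value of the statistic on the real network.
#' @slot nullMean sample mean of the statistic over null replicates.
#' @slot nullSd sample standard deviation (denominator n - 1) over replicates.
#' @slot z `(observed - nullMean) / nullSd`; `NA` when the null is degenerate.
#' @slot replicates number of null replicates used.
#' @slot degenerate `TRUE` exactly when `nullSd == 0` (Z undefined).
#'
#' @seealso [zScore()]
#' @export
setClass("ZScoreResult",
  representation(observed = "numeric", nullMean = "numeric",
                 nullSd = "numeric", z = "numeric",
                 replicates = "integer", degenerate = "logical"))

setValidity("ZScoreResult", function(object) {
  msg <- character(0)
  if (object@nullSd < 0) msg <- c(msg, "nullSd must be >= 0")
  if (object@degenerate != (object@nullSd == 0))
    msg <- c(msg, "degenerate must flag exactly nullSd == 0")
  if (object@degenerate && !is.na(object@z))
    msg <- c(msg, "z must be NA when degenerate")
  if (length(msg)) msg else TRUE
})

#' NullModelConfig: how to randomize a network
#'
#' @slot model `"fixed_fixed"` (exact degree preservation via checkerboard
#'   trades) or `"probabilistic"` (independent cells, connection probability
#'   proportional to the product of endpoint degrees).
#' @slot replicates number of null replicates (default 1000).
#' @slot seed integer master seed; fixes the whole replicate stream.
#' @slot swapsPerEdge burn-in/thinning intensity for `fixed_fixed`:
#'   `swapsPerEdge * |edges|` attempted exchanges between samples.
#'
#' @seealso [nullModelConfig()]
#' @export
setClass("NullModelConfig",
  representation(model = "character", replicates = "integer",
                 seed = "integer", swapsPerEdge = "integer"))

setValidity("NullModelConfig", function(object) {
  msg <- character(0)
  if (!(object@model %in% c("fixed_fixed", "probabilistic")))
    msg <- c(msg, "model must be 'fixed_fixed' or 'probabilistic'")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@swapsPerEdge < 1L) msg <- c(msg, "swapsPerEdge must be >= 1")
  if (length(msg)) msg else TRUE
})
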