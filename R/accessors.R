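#' Construct a PlantHerbivoreNetwork
#'
#' Species names are whitespace-normalized (internal runs of whitespace
#' collapsed to single spaces, ends trimmed); matching elsewhere in the
#' package is exact after this normalization. Duplicate edges are collapsed:
#' edges are unweighted and observation multiplicity is discarded.
#'
#' @param edges a two-column `data.frame`-like object with columns `insect`
#'   and `plant`, one row per observed interaction.
#' @param insects,plants optional node sets; defaults to the species present
#'   in `edges`. Extra names make isolated nodes, which are retained.
#' @return a [PlantHerbivoreNetwork-class] object.
#' @examples
#' net <- plantHerbivoreNetwork(data.frame(
#'   insect = c("Pieris rapae", "Pieris rapae"),
#'   plant  = c("Brassica oleracea", "Raphanus sativus")))
#' nEdges(net)
#' @export
plantHerbivoreNetwork <- function(edges, insects = NULL, plants = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("insect", "plant") %in% colnames(edges)))
    stop("edges must have columns 'insect' and 'plant'")
  ed <- data.frame(insect = .trimOne(as.character(edges$insect)),
                   plant = .trimOne(as.character(edges$plant)),
                   stringsAsFactors = FALSE)
  ed <- unique(ed)
  rownames(ed) <- NULL
  if (is.null(insects)) insects <- unique(ed$insect) else
    insects <- unique(c(.trimOne(insects), ed$insect))
  if (is.null(plants)) plants <- unique(ed$plant) else
    plants <- unique(c(.trimOne(plants), ed$plant))
  new("PlantHerbivoreNetwork", insects = insects, plants = plants, edges = ed)
}

#' Construct a TaxonomyMap
#'
#' @param records `data.frame` with column `species` and `family` (required)
#'   and optionally `genus`, `subfamily`, `order`; missing columns are filled
#'   with `NA`. Blank strings are treated as absent ranks.
#' @param side `"insect"` or `"plant"`.
#' @return a [TaxonomyMap-class] object.
#' @export
taxonomyMap <- function(records, side = c("insect", "plant")) {
  side <- match.arg(side)
  records <- as.data.frame(records)
  if (!all(c("species", "family") %in% colnames(records)))
    stop("taxonomy records need columns 'species' and 'family'")
  out <- data.frame(species = .trimOne(as.character(records$species)),
                    stringsAsFactors = FALSE)
  for (col in c("genus", "subfamily", "family", "order")) {
    v <- if (col %in% colnames(records)) as.character(records[[col]]) else
      rep(NA_character_, nrow(records))
    v <- .trimOne(v)
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    out[[col]] <- v
  }
  out <- unique(out)
  dup <- unique(out$species[duplicated(out$species)])
  if (length(dup))
    stop("conflicting taxonomy records for species: ",
         paste(dup, collapse = ", "))
  rownames(out) <- NULL
  new("TaxonomyMap", records = out, side = side)
}

#' Construct a CompoundCatalog
#'
#' @param sets named list mapping plant species to character vectors of
#'   compound identifiers; duplicates within a plant are collapsed.
#' @return a [CompoundCatalog-class] object.
#' @export
compoundCatalog <- function(sets = list()) {
  if (length(sets)) {
    names(sets) <- .trimOne(names(sets))
    sets <- lapply(sets, function(v) unique(as.character(v)))
  }
  new("CompoundCatalog", sets = sets)
}

#' Construct a NullModelConfig
#'
#' @param model `"fixed_fixed"` (default) or `"probabilistic"`.
#' @param replicates number of null replicates (default 1000, the
#'   conventional size for permutation-based network significance).
#' @param seed master seed for the replicate stream.
#' @param swapsPerEdge attempted checkerboard exchanges per edge between
#'   successive `fixed_fixed` samples (default 10).
#' @return a [NullModelConfig-class] object.
#' @export
nullModelConfig <- function(model = c("fixed_fixed", "probabilistic"),
                            replicates = 1000L, seed = 1L,
                            swapsPerEdge = 10L) {
  model <- match.arg(model)
  new("NullModelConfig", model = model,
      replicates = as.integer(replicates), seed = as.integer(seed),
      swapsPerEdge = as.integer(swapsPerEdge))
}

#' Accessors for the core classes
#'
#' @param x a [PlantHerbivoreNetwork-class], [TaxonomyMap-class] or
#'   [CompoundCatalog-class] object.
#' @param side which side of the bipartite network.
#' @param species species name(s).
#' @param level taxonomic rank: `"genus"`, `"subfamily"`, `"family"` or
#'   `"order"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("insectSpecies", "PlantHerbivoreNetwork", function(x) x@insects)

#' @rdname accessors
#' @export
setMethod("plantSpecies", "PlantHerbivoreNetwork", function(x) x@plants)

#' @rdname accessors
#' @export
setMethod("interactionEdges", "PlantHerbivoreNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("nEdges", "PlantHerbivoreNetwork", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("speciesDegree", "PlantHerbivoreNetwork",
  function(x, side = c("insect", "plant")) {
    side <- match.arg(side)
    nodes <- if (side == "insect") x@insects else x@plants
    col <- if (side == "insect") x@edges$insect else x@edges$plant
    tab <- table(factor(col, levels = nodes))
    stats::setNames(as.integer(tab), nodes)
  })

#' @rdname accessors
#' @export
setMethod("asIncidenceMatrix", "PlantHerbivoreNetwork", function(x) {
  M <- matrix(0L, length(x@insects), length(x@plants),
              dimnames = list(x@insects, x@plants))
  if (nrow(x@edges))
    M[cbind(match(x@edges$insect, x@insects),
            match(x@edges$plant, x@plants))] <- 1L
  M
})

#' @rdname accessors
#' @export
setMethod("taxonomyRecords", "TaxonomyMap", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("taxonomySide", "TaxonomyMap", function(x) x@side)

#' @rdname accessors
#' @export
setMethod("taxonOf", "TaxonomyMap", function(x, species, level = "family") {
  if (!(level %in% c("species", "genus", "subfamily", "family", "order")))
    stop("unknown taxonomic level: ", level)
  if (level == "species") return(stats::setNames(species, species))
  rec <- x@records
  stats::setNames(rec[[level]][match(species, rec$species)], species)
})

#' @rdname accessors
#' @export
setMethod("compoundsOf", "CompoundCatalog", function(x, species) {
  if (length(species) == 1L) {
    v <- x@sets[[species]]
    if (is.null(v)) character(0) else v
  } else {
    out <- x@sets[species]
    names(out) <- species
    lapply(out, function(v) if (is.null(v)) character(0) else v)
  }
})

#' @rdname accessors
#' @export
setMethod("catalogPlants", "CompoundCatalog", function(x) names(x@sets))

setMethod("show", "PlantHerbivoreNetwork", function(object) {
  cat("PlantHerbivoreNetwork:", length(object@insects), "insects,",
      length(object@plants), "plants,", nrow(object@edges), "edges\n")
})

setMethod("show", "TaxonomyMap", function(object) {
  cat("TaxonomyMap (", object@side, "): ", nrow(object@records),
      " species, ", length(unique(object@records$family)), " families\n",
      sep = "")
})

setMethod("show", "CompoundCatalog", function(object) {
  n <- lengths(object@sets)
  cat("CompoundCatalog:", length(object@sets), "plants,",
      length(unique(unlist(object@sets))), "distinct compounds",
      if (length(n)) sprintf("(median %d per plant)", as.integer(stats::median(n)))
      else "", "\n")
})

setMethod("show", "ZScoreResult", function(object) {
  cat(sprintf(
    "ZScoreResult: observed %.4g, null %.4g +/- %.4g (%d replicates), Z = %s\n",
    object@observed, object@nullMean, object@nullSd, object@replicates,
    if (object@degenerate) "NA (degenerate null)" else sprintf("%.3f", object@z)))
})

setMethod("show", "NullModelConfig", function(object) {
  cat("NullModelConfig:", object@model, "-", object@replicates,
      "replicates, seed", object@seed,
      if (object@model == "fixed_fixed")
        paste0("(", object@swapsPerEdge, " swaps/edge)") else "", "\n")
})
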