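#' @rdname accessors
#' @export
setGeneric("insectSpecies", function(x) standardGeneric("insectSpecies"))

#' @rdname accessors
#' @export
setGeneric("plantSpecies", function(x) standardGeneric("plantSpecies"))

#' @rdname accessors
#' @export
setGeneric("interactionEdges", function(x) standardGeneric("interactionEdges"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("speciesDegree",
  function(x, side = c("insect", "plant")) standardGeneric("speciesDegree"))

#' @rdname accessors
#' @export
setGeneric("asIncidenceMatrix", function(x) standardGeneric("asIncidenceMatrix"))

#' @rdname accessors
#' @export
setGeneric("taxonomyRecords", function(x) standardGeneric("taxonomyRecords"))

#' @rdname accessors
#' @export
setGeneric("taxonomySide", function(x) standardGeneric("taxonomySide"))

#' @rdname accessors
#' @export
setGeneric("taxonOf",
  function(x, species, level = "family") standardGeneric("taxonOf"))

#' @rdname accessors
#' @export
setGeneric("compoundsOf", function(x, species) standardGeneric("compoundsOf"))

#' @rdname accessors
#' @export
setGeneric("catalogPlants", function(x) standardGeneric("catalogPlants"))
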