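.sniffDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

.readDelimited <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) delimiter <- .sniffDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  df
}

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
}

#' Read a plant-herbivore interaction table
#'
#' Reads a delimited file with one row per observed plant-herbivore
#' relationship and assembles the bipartite network. Duplicate rows are
#' collapsed to a single unweighted edge.
#'
#' @param path path to a TSV/CSV file with a header row and columns
#'   `insect` and `plant`.
#' @param delimiter field separator; `NULL` (default) auto-detects between
#'   tab and comma from the header line.
#' @return a [PlantHerbivoreNetwork-class].
#' @export
readInteractionTable <- function(path, delimiter = NULL) {
  df <- .readDelimited(path, delimiter)
  if (nrow(df) == 0L) stop("empty interaction table: ", path)
  .requireColumns(df, c("insect", "plant"), "interaction table")
  net <- plantHerbivoreNetwork(df[, c("insect", "plant")])
  message(sprintf("read %d unique edges (%d insects, %d plants) from %s",
                  nEdges(net), length(insectSpecies(net)),
                  length(plantSpecies(net)), path))
  net
}

#' Read a taxonomy table
#'
#' @param path path to a TSV/CSV file with header columns `species` and
#'   `family` (required) and optionally `genus`, `subfamily`, `order`;
#'   blank cells mark absent ranks.
#' @param side `"insect"` or `"plant"`.
#' @inheritParams readInteractionTable
#' @return a [TaxonomyMap-class]. Two rows assigning one species to two
#'   different families raise a consistency error naming the species.
#' @export
readTaxonomyTable <- function(path, side = c("insect", "plant"),
                              delimiter = NULL) {
  side <- match.arg(side)
  df <- .readDelimited(path, delimiter)
  .requireColumns(df, c("species", "family"), "taxonomy table")
  taxonomyMap(df, side = side)
}

#' Read a plant-compound table
#'
#' @param path path to a TSV/CSV file with header columns `plant` and
#'   `compound`, one row per (plant, compound) pair. Duplicate pairs are
#'   collapsed; an empty compound identifier is a format error.
#' @inheritParams readInteractionTable
#' @return a [CompoundCatalog-class].
#' @export
readCompoundTable <- function(path, delimiter = NULL) {
  df <- .readDelimited(path, delimiter)
  .requireColumns(df, c("plant", "compound"), "compound table")
  cmp <- trimws(df$compound)
  if (any(!nzchar(cmp)))
    stop("compound table contains empty compound identifiers")
  compoundCatalog(split(cmp, .trimOne(df$plant)))
}

#' Restrict a network to compound-annotated host plants
#'
#' Keeps exactly the edges whose plant has at least one compound in the
#' catalog; species left without any edge are dropped. This is the filter
#' that turns a literature interaction network into the chemically
#' annotated "real-world" network analysed by the compound statistics.
#'
#' @param net a [PlantHerbivoreNetwork-class].
#' @param catalog a [CompoundCatalog-class].
#' @return the filtered [PlantHerbivoreNetwork-class] (possibly empty).
#' @export
restrictToCompoundAnnotated <- function(net, catalog) {
  annotated <- names(catalog@sets)[lengths(catalog@sets) > 0L]
  ed <- interactionEdges(net)
  keep <- ed$plant %in% annotated
  out <- new("PlantHerbivoreNetwork",
             insects = unique(ed$insect[keep]),
             plants = unique(ed$plant[keep]),
             edges = `rownames<-`(ed[keep, , drop = FALSE], NULL))
  message(sprintf(
    "compound filter: %d -> %d edges, %d -> %d insects, %d -> %d plants",
    nEdges(net), nEdges(out), length(insectSpecies(net)),
    length(insectSpecies(out)), length(plantSpecies(net)),
    length(plantSpecies(out))))
  out
}

#' Export a network to disk
#'
#' @param net a [PlantHerbivoreNetwork-class].
#' @param path output file path.
#' @param format `"edgelist"` (two-column TSV; re-reading with
#'   [readInteractionTable()] reproduces the edge set exactly) or
#'   `"graphml"` (bipartite graph with taxonomy node attributes).
#' @param insectTaxonomy,plantTaxonomy optional [TaxonomyMap-class] objects;
#'   when given, family is attached as a GraphML node attribute.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("edgelist", "graphml"),
                          insectTaxonomy = NULL, plantTaxonomy = NULL) {
  format <- match.arg(format)
  ed <- interactionEdges(net)
  if (format == "edgelist") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    nodes <- c(insectSpecies(net), plantSpecies(net))
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    igraph::V(g)$type <- nodes %in% plantSpecies(net)
    fam <- rep(NA_character_, length(nodes))
    if (!is.null(insectTaxonomy))
      fam[seq_along(insectSpecies(net))] <-
        unname(taxonOf(insectTaxonomy, insectSpecies(net)))
    if (!is.null(plantTaxonomy))
      fam[length(insectSpecies(net)) + seq_along(plantSpecies(net))] <-
        unname(taxonOf(plantTaxonomy, plantSpecies(net)))
    igraph::V(g)$family <- ifelse(is.na(fam), "", fam)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
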