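.asNetwork <- function(x) if (is.character(x)) readInteractionTable(x) else x
.asTaxonomy <- function(x, side)
  if (is.character(x)) readTaxonomyTable(x, side) else x
.asCatalog <- function(x) if (is.character(x)) readCompoundTable(x) else x

#' Cross-reference the input tables
#'
#' Reports species present in the interaction table but absent from a
#' taxonomy, compound records for plants not in the network, and network
#' plants without any compound record. Orphans are reported, never fatal:
#' the analysis functions drop what they cannot resolve and say so.
#'
#' @param net a [PlantHerbivoreNetwork-class] or path to an interaction
#'   table.
#' @param insectTaxonomy,plantTaxonomy [TaxonomyMap-class] objects or
#'   paths.
#' @param catalog a [CompoundCatalog-class] or path.
#' @return list of character vectors: `insectsWithoutTaxonomy`,
#'   `plantsWithoutTaxonomy`, `compoundPlantsNotInNetwork`,
#'   `plantsWithoutCompounds`.
#' @export
validateInputs <- function(net, insectTaxonomy, plantTaxonomy, catalog) {
  net <- .asNetwork(net)
  insectTaxonomy <- .asTaxonomy(insectTaxonomy, "insect")
  plantTaxonomy <- .asTaxonomy(plantTaxonomy, "plant")
  catalog <- .asCatalog(catalog)
  out <- list(
    insectsWithoutTaxonomy =
      setdiff(insectSpecies(net), taxonomyRecords(insectTaxonomy)$species),
    plantsWithoutTaxonomy =
      setdiff(plantSpecies(net), taxonomyRecords(plantTaxonomy)$species),
    compoundPlantsNotInNetwork =
      setdiff(catalogPlants(catalog), plantSpecies(net)),
    plantsWithoutCompounds =
      setdiff(plantSpecies(net),
              catalogPlants(catalog)[lengths(catalog@sets) > 0]))
  message(sprintf(
    paste0("validation: %d insects / %d plants without taxonomy, ",
           "%d compound-table plants not in network, ",
           "%d network plants without compounds"),
    length(out$insectsWithoutTaxonomy), length(out$plantsWithoutTaxonomy),
    length(out$compoundPlantsNotInNetwork),
    length(out$plantsWithoutCompounds)))
  out
}

.zRow <- function(zr) list(observed = zr@observed, nullMean = zr@nullMean,
                           nullSd = zr@nullSd,
                           z = if (zr@degenerate) NA_real_ else zr@z,
                           degenerate = zr@degenerate,
                           replicates = zr@replicates)

#' Run the full analysis pipeline
#'
#' Executes, in order: network assembly, input validation, the
#' compound-annotation filter, insect-plant family interaction Z-scores,
#' the joint evenness / food-pairing null tests, the per-plant compound
#' contribution table with its chi-vs-degree rank correlation, and the
#' per-clade compound enrichment screen. Everything downstream of the
#' filter operates on the chemically annotated network; all null tests
#' share one seed-fixed replicate stream, so the run is fully reproducible
#' given (inputs, config).
#'
#' @inheritParams validateInputs
#' @param config a [NullModelConfig-class] (model, replicates, seed).
#' @param levels insect levels for per-category Z-scores and family
#'   interaction matrices.
#' @param enrichmentLevel insect level at which clades are screened for
#'   specific compounds (default `"family"`).
#' @param pThreshold fixed p-value threshold for flagging "common
#'   specific" candidate compounds (default `1e-6`).
#' @param enrichmentUnit `"relationship"` or `"plant"`.
#' @param computeFamilyZ set `FALSE` to skip the interaction Z-score
#'   matrices (they need one extra randomization pass per level).
#' @param outDir if non-`NULL`, all tables are persisted there as TSV plus
#'   a `summary.json`, so any stage can be audited independently.
#' @return (invisibly) a list: `validation`, `counts`, `familyZ`,
#'   `evenness`, `foodPairing`, `chi`, `enrichment`, `summary`.
#' @export
runPipeline <- function(net, insectTaxonomy, plantTaxonomy, catalog,
                        config = nullModelConfig(),
                        levels = c("family", "subfamily"),
                        enrichmentLevel = "family", pThreshold = 1e-6,
                        enrichmentUnit = "relationship",
                        computeFamilyZ = TRUE, outDir = NULL) {
  net <- .asNetwork(net)
  insectTaxonomy <- .asTaxonomy(insectTaxonomy, "insect")
  plantTaxonomy <- .asTaxonomy(plantTaxonomy, "plant")
  catalog <- .asCatalog(catalog)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  validation <- stage("validate", validateInputs(net, insectTaxonomy,
                                                 plantTaxonomy, catalog))
  filtered <- stage("compound_filter",
                    restrictToCompoundAnnotated(net, catalog))
  if (nEdges(filtered) == 0L)
    stop("pipeline stage 'compound_filter' failed: no annotated edges")
  counts <- list(
    rawEdges = nEdges(net), rawInsects = length(insectSpecies(net)),
    rawPlants = length(plantSpecies(net)),
    filteredEdges = nEdges(filtered),
    filteredInsects = length(insectSpecies(filtered)),
    filteredPlants = length(plantSpecies(filtered)))

  familyZ <- NULL
  if (computeFamilyZ)
    familyZ <- stage("family_z", {
      out <- lapply(levels, function(lv)
        familyZScores(filtered, insectTaxonomy, plantTaxonomy,
                      insectLevel = lv, plantLevel = "family",
                      config = config))
      stats::setNames(out, levels)
    })

  tests <- stage("selection_tests",
                 selectionTests(filtered, catalog, plantTaxonomy,
                                insectTaxonomy, config = config,
                                levels = levels))
  chi <- stage("chi", chiDegreeProfile(filtered, catalog, plantTaxonomy,
                                       insectTaxonomy))
  cladeTaxa <- sort(unique(stats::na.omit(
    taxonOf(insectTaxonomy, insectSpecies(filtered), enrichmentLevel))))
  enrich <- stage("enrichment", {
    out <- lapply(cladeTaxa, function(cl)
      enrichment(filtered, catalog, insectTaxonomy, cl,
                 level = enrichmentLevel, unit = enrichmentUnit,
                 pThreshold = pThreshold))
    do.call(rbind, out)
  })
  candidates <- enrich[enrich$pass & enrich$direction == "enriched", ,
                       drop = FALSE]

  summary <- list(
    counts = counts,
    evenness = .zRow(tests$evenGlobal),
    foodPairing = c(.zRow(tests$nsGlobal),
                    list(excludedSpecies = tests$nsExcluded)),
    chiSpearman = if (is.null(chi$spearman))
      list(rho = NA_real_, p = NA_real_) else chi$spearman,
    candidateCompounds = split(candidates$compound, candidates$clade),
    nullModel = list(model = config@model, replicates = config@replicates,
                     seed = config@seed, swapsPerEdge = config@swapsPerEdge),
    levels = levels, enrichmentLevel = enrichmentLevel,
    pThreshold = pThreshold, enrichmentUnit = enrichmentUnit)

  result <- list(validation = validation, counts = counts,
                 network = filtered, familyZ = familyZ,
                 evenness = list(global = tests$evenGlobal,
                                 perCategory = tests$evenPerCategory),
                 foodPairing = list(global = tests$nsGlobal,
                                    perCategory = tests$nsPerCategory,
                                    excluded = tests$nsExcluded),
                 chi = chi, enrichment = enrich, summary = summary)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    exportNetwork(filtered, file.path(outDir, "network_filtered.tsv"))
    if (!is.null(familyZ))
      for (lv in names(familyZ))
        .writeTsv(familyZ[[lv]], file.path(outDir,
                                           paste0("family_z_", lv, ".tsv")))
    .writeTsv(tests$evenPerCategory, file.path(outDir, "evenness_z.tsv"))
    .writeTsv(tests$nsPerCategory, file.path(outDir, "ns_z.tsv"))
    .writeTsv(foodPairingNs(filtered, catalog),
              file.path(outDir, "ns.tsv"))
    .writeTsv(chi$table, file.path(outDir, "chi.tsv"))
    .writeTsv(enrich, file.path(outDir, "enrichment.tsv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  }
  invisible(result)
}

#' Run the pipeline from a YAML configuration file
#'
#' The file must provide `interactions`, `insect_taxonomy`,
#' `plant_taxonomy` and `compounds` (paths, resolved relative to the YAML
#' file), and may provide `out_dir`, `levels`, a `null_model` block
#' (`model`, `replicates`, `seed`, `swaps_per_edge`) and an `enrichment`
#' block (`level`, `p_threshold`, `unit`).
#'
#' @param path path to the YAML configuration.
#' @return the [runPipeline()] result, invisibly.
#' @export
runPipelineFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("interactions", "insect_taxonomy", "plant_taxonomy", "compounds")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("pipeline config is missing: ", paste(missing, collapse = ", "))
  base <- dirname(normalizePath(path))
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  nm <- cfg$null_model
  config <- nullModelConfig(
    model = if (is.null(nm$model)) "fixed_fixed" else nm$model,
    replicates = if (is.null(nm$replicates)) 1000L else nm$replicates,
    seed = if (is.null(nm$seed)) 1L else nm$seed,
    swapsPerEdge = if (is.null(nm$swaps_per_edge)) 10L else nm$swaps_per_edge)
  en <- cfg$enrichment
  runPipeline(rel(cfg$interactions), rel(cfg$insect_taxonomy),
              rel(cfg$plant_taxonomy), rel(cfg$compounds),
              config = config,
              levels = if (is.null(cfg$levels)) c("family", "subfamily")
                       else unlist(cfg$levels),
              enrichmentLevel = if (is.null(en$level)) "family" else en$level,
              pThreshold = if (is.null(en$p_threshold)) 1e-6
                           else en$p_threshold,
              enrichmentUnit = if (is.null(en$unit)) "relationship"
                               else en$unit,
              outDir = cfg$out_dir)
}
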