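#' Configuration for the synthetic study generator
#'
#' Describes a balanced, taxonomically structured bipartite community with
#' planted host-selection effects. Feeding preferences act as exponential
#' tilts on log-weights, giving one smooth family of models from uniform
#' random feeding (`lambdaFamily = betaCompound = 0`) to deterministic
#' preference (large values), which is what makes monotonic
#' parameter-recovery checks possible.
#'
#' @param nPlantFamilies,plantsPerFamily plant-side sizes (default 4 x 25).
#' @param nInsectFamilies,subfamiliesPerFamily,speciesPerSubfamily
#'   insect-side sizes (default 5 x 2 x 5).
#' @param hostsPerSpecies hosts drawn per insect species, without
#'   replacement (default 5).
#' @param lambdaFamily strength of attraction to the clade's preferred
#'   plant family (>= 0); scalar or one value per insect family.
#' @param betaCompound strength of attraction to plants carrying the
#'   clade's planted compounds (>= 0); scalar or one value per insect
#'   family.
#' @param nCoreCompoundsPerPlantFamily compounds shared by every plant of a
#'   family ("common" within the family; default 3).
#' @param nCladeSpecificCompounds planted "common specific" compounds per
#'   insect clade (default 3), present in every plant of the clade's target
#'   plant families and absent elsewhere.
#' @param cladeCompoundFamilies number of plant families carrying each
#'   clade's planted compounds (default 1; 2 makes compound-driven feeding
#'   cut across plant taxonomy).
#' @param cladeCompoundPlacement `"family"` (default) places each clade's
#'   compounds in every plant of its target families, so chemistry tracks
#'   taxonomy as it does for real secondary metabolites;
#'   `"scattered"` places them in a random subset of plants drawn
#'   irrespective of family, decoupling the compound channel from the
#'   taxonomy channel (useful for parameter-recovery designs).
#' @param cladeCompoundCoverage under scattered placement, the fraction of
#'   all plants carrying each clade's compounds (default 0.25).
#' @param nBackgroundCompounds noise compounds sprinkled independently over
#'   plants (default 30).
#' @param compoundNoise per-plant presence probability of each background
#'   compound (default 0.1).
#' @param includeGlobalCommon add one compound present in all plants
#'   (default `TRUE`), the analogue of a ubiquitous primary metabolite.
#' @param seed master seed; all randomness in the generator derives from it.
#' @return a validated `GeneratorConfig` list.
#' @export
generatorConfig <- function(nPlantFamilies = 4L, plantsPerFamily = 25L,
                            nInsectFamilies = 5L, subfamiliesPerFamily = 2L,
                            speciesPerSubfamily = 5L, hostsPerSpecies = 5L,
                            lambdaFamily = 0, betaCompound = 0,
                            nCoreCompoundsPerPlantFamily = 3L,
                            nCladeSpecificCompounds = 3L,
                            cladeCompoundFamilies = 1L,
                            cladeCompoundPlacement = c("family", "scattered"),
                            cladeCompoundCoverage = 0.25,
                            nBackgroundCompounds = 30L,
                            compoundNoise = 0.1,
                            includeGlobalCommon = TRUE, seed = 1L) {
  cfg <- list(nPlantFamilies = as.integer(nPlantFamilies),
              plantsPerFamily = as.integer(plantsPerFamily),
              nInsectFamilies = as.integer(nInsectFamilies),
              subfamiliesPerFamily = as.integer(subfamiliesPerFamily),
              speciesPerSubfamily = as.integer(speciesPerSubfamily),
              hostsPerSpecies = as.integer(hostsPerSpecies),
              lambdaFamily = as.numeric(lambdaFamily),
              betaCompound = as.numeric(betaCompound),
              nCoreCompoundsPerPlantFamily =
                as.integer(nCoreCompoundsPerPlantFamily),
              nCladeSpecificCompounds = as.integer(nCladeSpecificCompounds),
              cladeCompoundFamilies = as.integer(cladeCompoundFamilies),
              cladeCompoundPlacement = match.arg(cladeCompoundPlacement),
              cladeCompoundCoverage = as.numeric(cladeCompoundCoverage),
              nBackgroundCompounds = as.integer(nBackgroundCompounds),
              compoundNoise = as.numeric(compoundNoise),
              includeGlobalCommon = isTRUE(includeGlobalCommon),
              seed = as.integer(seed))
  for (f in c("nPlantFamilies", "plantsPerFamily", "nInsectFamilies",
              "subfamiliesPerFamily", "speciesPerSubfamily",
              "hostsPerSpecies"))
    if (cfg[[f]] < 1L) stop(f, " must be a positive integer")
  for (f in c("lambdaFamily", "betaCompound"))
    if (any(cfg[[f]] < 0)) stop(f, " must be >= 0")
  for (f in c("nCoreCompoundsPerPlantFamily", "nCladeSpecificCompounds",
              "nBackgroundCompounds"))
    if (cfg[[f]] < 0L) stop(f, " must be non-negative")
  if (cfg$cladeCompoundFamilies < 1L ||
      cfg$cladeCompoundFamilies > cfg$nPlantFamilies)
    stop("cladeCompoundFamilies must be in 1..nPlantFamilies")
  if (cfg$compoundNoise < 0 || cfg$compoundNoise > 1)
    stop("compoundNoise must be a probability")
  if (cfg$cladeCompoundCoverage <= 0 || cfg$cladeCompoundCoverage > 1)
    stop("cladeCompoundCoverage must be in (0, 1]")
  if (cfg$hostsPerSpecies > cfg$nPlantFamilies * cfg$plantsPerFamily)
    stop("hostsPerSpecies exceeds the number of plants")
  class(cfg) <- "GeneratorConfig"
  cfg
}

.perClade <- function(x, nClades) {
  if (length(x) == 1L) rep(x, nClades)
  else if (length(x) == nClades) x
  else stop("preference strength must be scalar or one value per insect family")
}

.preferredFamily <- function(clade, nPlantFamilies)
  ((clade - 1L) %% nPlantFamilies) + 1L

.targetFamilies <- function(clade, cfg)
  ((.preferredFamily(clade, cfg$nPlantFamilies) - 1L +
      seq_len(cfg$cladeCompoundFamilies) - 1L) %% cfg$nPlantFamilies) + 1L

#' Generate balanced synthetic taxonomies
#'
#' Deterministic naming (family, subfamily and species indices embedded in
#' the names) so fixtures diff cleanly across runs.
#'
#' @param config a [generatorConfig()].
#' @return list with elements `insect` and `plant`, both
#'   [TaxonomyMap-class] objects.
#' @export
generateTaxonomy <- function(config) {
  pf <- seq_len(config$nPlantFamilies)
  plant <- do.call(rbind, lapply(pf, function(f) {
    genus <- sprintf("Plantus%02d", f)
    data.frame(species = paste(genus,
                               sprintf("sp%02d", seq_len(config$plantsPerFamily))),
               genus = genus, subfamily = NA_character_,
               family = sprintf("Plantaceae%02d", f),
               order = "Plantales", stringsAsFactors = FALSE)
  }))
  insect <- do.call(rbind, lapply(seq_len(config$nInsectFamilies), function(f) {
    do.call(rbind, lapply(seq_len(config$subfamiliesPerFamily), function(s) {
      genus <- sprintf("Insectus%02d%s", f, letters[s])
      data.frame(species = paste(genus,
                                 sprintf("sp%02d", seq_len(config$speciesPerSubfamily))),
                 genus = genus,
                 subfamily = sprintf("Insectinae%02d%s", f, letters[s]),
                 family = sprintf("Insectidae%02d", f),
                 order = "Lepidoptera", stringsAsFactors = FALSE)
    }))
  }))
  list(insect = taxonomyMap(insect, "insect"),
       plant = taxonomyMap(plant, "plant"))
}

#' Generate a synthetic compound catalog with planted structure
#'
#' Every plant receives its family's core compounds; each insect clade's
#' planted "common specific" compounds go to all plants of the clade's
#' target plant families and nowhere else; background compounds are
#' sprinkled independently with probability `compoundNoise`; optionally one
#' globally common compound is present in every plant.
#'
#' @param config a [generatorConfig()].
#' @param plantTaxonomy the plant [TaxonomyMap-class] from
#'   [generateTaxonomy()].
#' @param seed seed for the background sprinkling (defaults to
#'   `config$seed`).
#' @return list with `catalog` (a [CompoundCatalog-class]) and `truth`
#'   (list: `cladePreferredFamily`, `cladeCompounds`, `compoundRoles`).
#' @export
generateCompounds <- function(config, plantTaxonomy, seed = config$seed) {
  rec <- taxonomyRecords(plantTaxonomy)
  plants <- rec$species
  famIdx <- match(rec$family, sort(unique(rec$family)))
  sets <- stats::setNames(vector("list", length(plants)), plants)
  roles <- list()
  counter <- 0L
  newId <- function() {
    counter <<- counter + 1L
    sprintf("C%07d", counter)
  }
  addTo <- function(idx, id) for (p in idx)
    sets[[p]] <<- c(sets[[p]], id)

  if (config$includeGlobalCommon) {
    id <- newId()
    addTo(seq_along(plants), id)
    roles[[length(roles) + 1L]] <- data.frame(
      compound = id, role = "global_common", target = "all",
      stringsAsFactors = FALSE)
  }
  for (f in seq_len(config$nPlantFamilies))
    for (k in seq_len(config$nCoreCompoundsPerPlantFamily)) {
      id <- newId()
      addTo(which(famIdx == f), id)
      roles[[length(roles) + 1L]] <- data.frame(
        compound = id, role = "family_core",
        target = sprintf("Plantaceae%02d", f), stringsAsFactors = FALSE)
    }
  set.seed(seed)
  cladeCompounds <- list()
  for (cl in seq_len(config$nInsectFamilies)) {
    carrier <- if (config$cladeCompoundPlacement == "family")
      which(famIdx %in% .targetFamilies(cl, config))
    else
      sort(sample(length(plants),
                  max(1L, round(config$cladeCompoundCoverage *
                                  length(plants)))))
    ids <- character(config$nCladeSpecificCompounds)
    for (k in seq_len(config$nCladeSpecificCompounds)) {
      id <- newId()
      ids[k] <- id
      addTo(carrier, id)
      roles[[length(roles) + 1L]] <- data.frame(
        compound = id, role = "clade_specific",
        target = sprintf("Insectidae%02d", cl), stringsAsFactors = FALSE)
    }
    cladeCompounds[[sprintf("Insectidae%02d", cl)]] <- ids
  }
  for (k in seq_len(config$nBackgroundCompounds)) {
    id <- newId()
    hit <- which(stats::runif(length(plants)) < config$compoundNoise)
    addTo(hit, id)
    roles[[length(roles) + 1L]] <- data.frame(
      compound = id, role = "background", target = "noise",
      stringsAsFactors = FALSE)
  }
  truth <- list(
    cladePreferredFamily = stats::setNames(
      sprintf("Plantaceae%02d",
              .preferredFamily(seq_len(config$nInsectFamilies),
                               config$nPlantFamilies)),
      sprintf("Insectidae%02d", seq_len(config$nInsectFamilies))),
    cladeCompounds = cladeCompounds,
    compoundRoles = do.call(rbind, roles))
  list(catalog = compoundCatalog(sets), truth = truth)
}

#' Generate a synthetic plant-herbivore network
#'
#' Each insect species draws `hostsPerSpecies` host plants without
#' replacement with probability proportional to
#' `exp(lambda * preferred-family + beta * carries-planted-compound)`,
#' where the indicators refer to the species' clade (insect family).
#'
#' @param config a [generatorConfig()].
#' @param taxonomies the list from [generateTaxonomy()].
#' @param catalogTruth the list from [generateCompounds()].
#' @param seed seed for host sampling (defaults to `config$seed`).
#' @return list with `network` (a [PlantHerbivoreNetwork-class]) and
#'   `truth` (ground truth including per-edge generative log-weights and a
#'   config echo).
#' @export
generateNetwork <- function(config, taxonomies, catalogTruth,
                            seed = config$seed) {
  insRec <- taxonomyRecords(taxonomies$insect)
  plaRec <- taxonomyRecords(taxonomies$plant)
  plants <- plaRec$species
  famIdx <- match(plaRec$family, sort(unique(plaRec$family)))
  lambda <- .perClade(config$lambdaFamily, config$nInsectFamilies)
  beta <- .perClade(config$betaCompound, config$nInsectFamilies)
  cladeOf <- match(insRec$family, sort(unique(insRec$family)))
  carries <- vapply(seq_len(config$nInsectFamilies), function(cl) {
    ids <- catalogTruth$truth$cladeCompounds[[sprintf("Insectidae%02d", cl)]]
    vapply(plants, function(p)
      length(intersect(compoundsOf(catalogTruth$catalog, p), ids)) > 0,
      logical(1))
  }, logical(length(plants)))
  set.seed(seed)
  edges <- vector("list", nrow(insRec))
  for (i in seq_len(nrow(insRec))) {
    cl <- cladeOf[i]
    lw <- lambda[cl] * (famIdx == .preferredFamily(cl, config$nPlantFamilies)) +
      beta[cl] * carries[, cl]
    hosts <- sample(plants, config$hostsPerSpecies, prob = exp(lw - max(lw)))
    edges[[i]] <- data.frame(insect = insRec$species[i], plant = hosts,
                             logWeight = lw[match(hosts, plants)],
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  net <- new("PlantHerbivoreNetwork",
             insects = insRec$species, plants = plants,
             edges = edges[, c("insect", "plant")])
  truth <- c(catalogTruth$truth,
             list(edgeLogWeights = edges, config = unclass(config)))
  list(network = net, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Runs [generateTaxonomy()], [generateCompounds()] and
#' [generateNetwork()] with sub-seeds split deterministically from the
#' master seed, and returns everything the pipeline needs plus the planted
#' ground truth.
#'
#' @param config a [generatorConfig()].
#' @return list: `network`, `insectTaxonomy`, `plantTaxonomy`, `catalog`,
#'   `truth`.
#' @export
simulateStudy <- function(config = generatorConfig()) {
  set.seed(config$seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, 2L)
  tax <- generateTaxonomy(config)
  cmp <- generateCompounds(config, tax$plant, seed = subSeeds[1])
  gen <- generateNetwork(config, tax, cmp, seed = subSeeds[2])
  list(network = gen$network, insectTaxonomy = tax$insect,
       plantTaxonomy = tax$plant, catalog = cmp$catalog, truth = gen$truth)
}

.writeTsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")

#' Write a synthetic study to disk as a self-describing fixture
#'
#' Emits `interactions.tsv`, `insect_taxonomy.tsv`, `plant_taxonomy.tsv`,
#' `compounds.tsv` and `truth.json` (ground truth plus a config echo).
#' Re-reading the TSVs with the package readers reproduces the in-memory
#' objects; two writes from the same config are byte-identical.
#'
#' @param dir output directory (created if absent).
#' @param study the list from [simulateStudy()].
#' @return character vector of the files written, invisibly.
#' @export
writeFixture <- function(dir, study) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("interactions.tsv", "insect_taxonomy.tsv",
                        "plant_taxonomy.tsv", "compounds.tsv", "truth.json"))
  .writeTsv(interactionEdges(study$network), f[1])
  .writeTsv(taxonomyRecords(study$insectTaxonomy), f[2])
  .writeTsv(taxonomyRecords(study$plantTaxonomy), f[3])
  sets <- study$catalog@sets
  comp <- data.frame(
    plant = rep(names(sets), lengths(sets)),
    compound = unlist(sets, use.names = FALSE), stringsAsFactors = FALSE)
  .writeTsv(comp, f[4])
  jsonlite::write_json(study$truth, f[5], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(f)
}
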