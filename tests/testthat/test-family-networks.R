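itax <- function(...) taxonomyMap(data.frame(...), side = "insect")
ptax <- function(...) taxonomyMap(data.frame(...), side = "plant")

test_that("interaction counts aggregate edges at the requested levels", {
  net <- toyNetwork(rbind(c("B1", "P1"), c("B2", "P1")))
  it <- itax(species = c("B1", "B2"), family = "F")
  pt <- ptax(species = "P1", family = "G")
  W <- interactionCounts(net, it, pt)
  expect_equal(W["F", "G"], 2L)
  # empty (edgeless) network -> all-zero matrix
  e <- plantHerbivoreNetwork(data.frame(insect = character(0),
                                        plant = character(0)),
                             insects = c("B1", "B2"), plants = "P1")
  expect_true(all(interactionCounts(e, it, pt) == 0L))
  expect_error(interactionCounts(net, it, pt, insectLevel = "tribe"),
               "unknown")
})

test_that("interaction counts match a brute-force recount per edge", {
  set.seed(31)
  pairs <- unique(cbind(sprintf("B%d", sample(8, 20, TRUE)),
                        sprintf("P%dx%d", sample(3, 20, TRUE),
                                sample(4, 20, TRUE))))
  net <- toyNetwork(pairs)
  it <- itax(species = sprintf("B%d", 1:8),
             family = sprintf("IF%d", rep(1:2, each = 4)))
  pt <- gridPlantTaxonomy(3, 4)
  W <- interactionCounts(net, it, pt)
  ed <- interactionEdges(net)
  for (i in rownames(W)) for (j in colnames(W)) {
    brute <- sum(taxonOf(it, ed$insect) == i & taxonOf(pt, ed$plant) == j)
    expect_equal(unname(W[i, j]), brute)
  }
  expect_equal(sum(W), nEdges(net))
})

test_that("total interaction count is conserved by fixed-fixed nulls", {
  set.seed(32)
  pairs <- unique(cbind(sprintf("B%d", sample(8, 30, TRUE)),
                        sprintf("P%dx%d", sample(3, 30, TRUE),
                                sample(4, 30, TRUE))))
  net <- toyNetwork(pairs)
  it <- itax(species = sprintf("B%d", 1:8),
             family = sprintf("IF%d", rep(1:2, each = 4)))
  pt <- gridPlantTaxonomy(3, 4)
  W0 <- sum(interactionCounts(net, it, pt))
  for (s in 1:5) {
    r <- randomizeFixedFixed(net, seed = s)
    expect_equal(sum(interactionCounts(r, it, pt)), W0)
  }
})

test_that("evenness hits the closed-form anchors", {
  pt <- gridPlantTaxonomy(4, 3)
  # hosts all in one family -> E = 0 (others present via a helper insect)
  net <- toyNetwork(rbind(c("B1", "P1x1"), c("B1", "P1x2"),
                          c("Bz", "P2x1"), c("Bz", "P3x1"), c("Bz", "P4x1")))
  expect_equal(evenness(net, pt, "B1")$E, 0)
  # hosts spread equally over all families -> E = 1
  net2 <- toyNetwork(rbind(c("B1", "P1x1"), c("B1", "P2x1"),
                           c("B1", "P3x1"), c("B1", "P4x1")))
  expect_equal(evenness(net2, pt, "B1")$E, 1)
  # counts (3,1) over two of four families
  net3 <- toyNetwork(rbind(c("B1", "P1x1"), c("B1", "P1x2"), c("B1", "P1x3"),
                           c("B1", "P2x1"),
                           c("Bz", "P3x1"), c("Bz", "P4x1")))
  expect_equal(evenness(net3, pt, "B1")$E,
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(4))
  expect_error(evenness(net3, pt, "Bmissing"), "Bmissing")
})

test_that("evenness is label-invariant and grows with a new family", {
  pt <- gridPlantTaxonomy(4, 3)
  base <- rbind(c("B1", "P1x1"), c("B1", "P1x2"),
                c("Bz", "P2x1"), c("Bz", "P3x1"), c("Bz", "P4x1"))
  e0 <- evenness(toyNetwork(base), pt, "B1")$E
  # permuting plant-family labels: rename families via a permuted taxonomy
  perm <- taxonomyRecords(pt)
  perm$family <- sprintf("Fam%d", c(3, 1, 4, 2)[as.integer(sub("Fam", "",
                                                               perm$family))])
  expect_equal(evenness(toyNetwork(base), taxonomyMap(perm, "plant"),
                        "B1")$E, e0)
  # adding a host in a new family strictly increases E for mono-family diet
  e1 <- evenness(toyNetwork(rbind(base, c("B1", "P2x2"))), pt, "B1")$E
  expect_gt(e1, e0)
})

test_that("average evenness is the unweighted species mean", {
  pt <- gridPlantTaxonomy(4, 3)
  # one mono-family species (E = 0), one perfectly even species (E = 1)
  net <- toyNetwork(rbind(c("B1", "P1x1"), c("B1", "P1x2"),
                          c("B2", "P1x3"), c("B2", "P2x1"),
                          c("B2", "P3x1"), c("B2", "P4x1")))
  expect_equal(averageEvenness(net, pt), 0.5)
  # synthetic network vs per-species oracle
  st <- simulateStudy(generatorConfig(seed = 3, nPlantFamilies = 3,
                                      plantsPerFamily = 6,
                                      nInsectFamilies = 3,
                                      speciesPerSubfamily = 5))
  M <- asIncidenceMatrix(st$network)
  fam <- taxonOf(st$plantTaxonomy, colnames(M))
  K <- length(unique(fam))
  perSpecies <- apply(M, 1, function(row)
    oracleEvenness(tapply(row, fam, sum), K))
  expect_equal(averageEvenness(st$network, st$plantTaxonomy),
               mean(perSpecies), tolerance = 1e-12)
})

test_that("family-assortative feeding drives the evenness Z negative", {
  st <- simulateStudy(generatorConfig(lambdaFamily = 4, seed = 17))
  res <- evennessTest(st$network, st$plantTaxonomy, st$insectTaxonomy,
                      nullModelConfig(replicates = 300, seed = 18))
  expect_lt(res$global@z, -3)
  expect_true(all(c("level", "category", "z") %in%
                  colnames(res$perCategory)))
  expect_equal(sum(res$perCategory$level == "family"), 5L)
})

test_that("interaction z-scores separate planted attraction from avoidance", {
  st <- simulateStudy(generatorConfig(lambdaFamily = 4, seed = 23))
  fz <- familyZScores(st$network, st$insectTaxonomy, st$plantTaxonomy,
                      config = nullModelConfig(replicates = 300, seed = 5))
  pref <- st$truth$cladePreferredFamily
  planted <- fz[paste(fz$insectTaxon, fz$plantTaxon) %in%
                paste(names(pref), pref), ]
  expect_true(all(planted$z > 0, na.rm = TRUE))
  # single insect family x single plant family: every null W identical
  net <- toyNetwork(rbind(c("B1", "P1"), c("B2", "P2")))
  one <- familyZScores(net, itax(species = c("B1", "B2"), family = "F"),
                       ptax(species = c("P1", "P2"), family = "G"),
                       config = nullModelConfig(replicates = 50, seed = 1))
  expect_true(all(one$degenerate))
  expect_true(all(is.na(one$z)))
})

test_that("average neighbour degree averages family breadth of herbivores", {
  pt <- gridPlantTaxonomy(4, 3)
  # plant eaten only by mono-family-phagous species
  net <- toyNetwork(rbind(c("B1", "P1x1"), c("B1", "P1x2")))
  expect_equal(averageNeighbourDegree(net, pt, "P1x1"), 1)
  # two herbivores using 1 and 3 families
  net2 <- toyNetwork(rbind(c("B1", "P1x1"),
                           c("B2", "P1x1"), c("B2", "P2x1"), c("B2", "P3x1")))
  expect_equal(averageNeighbourDegree(net2, pt, "P1x1"), 2)
  expect_error(averageNeighbourDegree(net2, pt, "P4x1"), "P4x1")
  # brute-force check on a synthetic network
  st <- simulateStudy(generatorConfig(seed = 29))
  M <- asIncidenceMatrix(st$network)
  fam <- taxonOf(st$plantTaxonomy, colnames(M))
  for (pl in sample(colnames(M)[colSums(M) > 0], 5)) {
    herbs <- rownames(M)[M[, pl] > 0]
    brute <- mean(vapply(herbs, function(k)
      length(unique(fam[M[k, ] > 0])), numeric(1)))
    expect_equal(averageNeighbourDegree(st$network, st$plantTaxonomy, pl),
                 brute, tolerance = 1e-12)
  }
})

test_that("ecozone similarity works on proportions", {
  comp <- cbind(zoneA = c(10, 20, 30), zoneB = c(1, 2, 3),
                zoneC = c(30, 20, 10))
  r <- ecozoneSimilarity(comp)
  expect_equal(unname(r["zoneA", "zoneB"]), 1)  # identical proportions
  expect_equal(unname(diag(r)), rep(1, 3))
  # scale invariance
  comp2 <- comp; comp2[, "zoneA"] <- comp2[, "zoneA"] * 2
  expect_equal(ecozoneSimilarity(comp2), r)
  # anti-ordered two-family compositions
  r2 <- ecozoneSimilarity(cbind(z1 = c(3, 1), z2 = c(1, 3)))
  expect_equal(unname(r2["z1", "z2"]), -1)
  expect_error(ecozoneSimilarity(cbind(z1 = c(1, 2), z2 = c(0, 0))), "zero")
})
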