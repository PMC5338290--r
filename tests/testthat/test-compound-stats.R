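test_that("shared compound counts are symmetric set intersections", {
  cat <- compoundCatalog(list(P1 = c("c1", "c2"), P2 = c("c2", "c3"),
                              P3 = c("c4", "c5")))
  expect_equal(sharedCompoundCount(cat, "P1", "P2"), 1L)
  expect_equal(sharedCompoundCount(cat, "P2", "P1"), 1L)
  expect_equal(sharedCompoundCount(cat, "P1", "P1"), 2L)
  expect_equal(sharedCompoundCount(cat, "P1", "P3"), 0L)
  expect_equal(sharedCompoundCount(cat, "P1", "Pmissing"), 0L)
})

test_that("food-pairing N_s equals the pairwise mean", {
  cat <- compoundCatalog(list(Pa = c("a", "b"), Pb = c("b", "c"),
                              Pc = "d"))
  net <- toyNetwork(rbind(c("B1", "Pa"), c("B1", "Pb")))
  expect_equal(foodPairingNs(net, cat, "B1")$Ns, 1)
  net3 <- toyNetwork(rbind(c("B1", "Pa"), c("B1", "Pb"), c("B1", "Pc")))
  expect_equal(foodPairingNs(net3, cat, "B1")$Ns, 1 / 3)
  # hosts with identical sets of size m -> N_s = m
  cat2 <- compoundCatalog(list(Pa = c("x", "y", "z"), Pb = c("x", "y", "z")))
  expect_equal(foodPairingNs(net, cat2, "B1")$Ns, 3)
  # single-host butterflies are excluded, not zero-filled
  mix <- toyNetwork(rbind(c("B1", "Pa"), c("B1", "Pb"), c("B2", "Pc")))
  batch <- foodPairingNs(mix, cat)
  expect_equal(batch$butterfly, "B1")
  expect_equal(attr(batch, "excluded"), 1L)
  expect_error(foodPairingNs(mix, cat, "B2"), "fewer than 2")
})

test_that("N_s is invariant to compound relabeling and unused compounds", {
  set.seed(43)
  for (rep in 1:10) {
    hosts <- sprintf("P%d", 1:4)
    sets <- lapply(hosts, function(p)
      sample(sprintf("c%d", 1:8), sample(0:6, 1)))
    names(sets) <- hosts
    net <- toyNetwork(cbind("B1", hosts))
    ns0 <- foodPairingNs(net, compoundCatalog(sets), "B1")$Ns
    relab <- lapply(sets, function(v) chartr("c", "k", v))
    expect_equal(foodPairingNs(net, compoundCatalog(relab), "B1")$Ns, ns0)
    extra <- sets; extra[["Pzzz"]] <- c("c1", "c99")
    expect_equal(foodPairingNs(net, compoundCatalog(extra), "B1")$Ns, ns0)
  }
})

test_that("chi vanishes under complete-bipartite feeding and empty chemistry", {
  set.seed(47)
  pairs <- as.matrix(expand.grid(sprintf("B%d", 1:6), sprintf("P%d", 1:8)))
  net <- toyNetwork(pairs)
  sets <- lapply(sprintf("P%d", 1:8), function(p)
    sample(sprintf("c%d", 1:10), sample(1:6, 1)))
  names(sets) <- sprintf("P%d", 1:8)
  chi <- compoundContributionChi(net, compoundCatalog(sets))
  expect_true(all(abs(chi$chi) < 1e-12))
  # plant with no compounds: all its overlaps vanish
  sets$P1 <- character(0)
  sets$P2 <- "c1"  # keep some chemistry elsewhere
  chi2 <- compoundContributionChi(net, compoundCatalog(sets))
  expect_equal(chi2$chi[chi2$plant == "P1"], 0)
})

test_that("chi matches the direct-loop oracle on random networks", {
  set.seed(53)
  for (rep in 1:5) {
    plants <- sprintf("P%d", 1:7)
    pairs <- unique(cbind(sprintf("B%d", sample(5, 18, TRUE)),
                          sample(plants, 18, TRUE)))
    net <- toyNetwork(pairs)
    sets <- lapply(plants, function(p)
      sample(sprintf("c%d", 1:9), sample(0:5, 1)))
    names(sets) <- plants
    cat <- compoundCatalog(sets)
    chi <- compoundContributionChi(net, cat)
    ed <- interactionEdges(net)
    for (pl in intersect(plants, chi$plant)) {
      got <- chi$chi[chi$plant == pl]
      want <- oracleChi(ed, sets, pl, plantSpecies(net))
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("chi-degree profile reports Spearman correlation or suppresses it", {
  st <- simulateStudy(generatorConfig(betaCompound = 3, seed = 61))
  prof <- chiDegreeProfile(st$network, st$catalog, st$plantTaxonomy)
  expect_true(all(c("plant", "chi", "degree", "avgNeighbourDegree") %in%
                  colnames(prof$table)))
  expect_gt(prof$spearman$rho, 0)
  # permuting plant labels leaves the correlation invariant
  perm <- sample(plantSpecies(st$network))
  map <- stats::setNames(perm, plantSpecies(st$network))
  ed <- interactionEdges(st$network)
  netP <- plantHerbivoreNetwork(data.frame(insect = ed$insect,
                                           plant = unname(map[ed$plant])),
                                plants = unname(map[plantSpecies(st$network)]))
  sets <- st$catalog@sets
  catP <- compoundCatalog(stats::setNames(sets, unname(map[names(sets)])))
  recP <- taxonomyRecords(st$plantTaxonomy)
  recP$species <- unname(map[recP$species])
  profP <- chiDegreeProfile(netP, catP, taxonomyMap(recP, "plant"))
  expect_equal(profP$spearman$rho, prof$spearman$rho, tolerance = 1e-12)
  # zero-variance chi: correlation suppressed
  cb <- toyNetwork(as.matrix(expand.grid(sprintf("B%d", 1:3),
                                         sprintf("P%d", 1:4))))
  cat0 <- compoundCatalog(stats::setNames(
    replicate(4, "c1", simplify = FALSE), sprintf("P%d", 1:4)))
  pt <- taxonomyMap(data.frame(species = sprintf("P%d", 1:4), family = "F"),
                    "plant")
  expect_message(p0 <- chiDegreeProfile(cb, cat0, pt), "suppressed")
  expect_null(p0$spearman)
})

test_that("enrichment builds the right tables and effect sizes", {
  # perfect association: 10 clade edges on compound plants, 10 without
  ed <- rbind(cbind(sprintf("A%d", 1:5), sprintf("Pc%d", rep(1:2, 5))),
              cbind(sprintf("X%d", 1:5), sprintf("Pn%d", rep(1:2, 5))))
  net <- toyNetwork(ed)
  it <- taxonomyMap(data.frame(
    species = c(sprintf("A%d", 1:5), sprintf("X%d", 1:5)),
    family = rep(c("CladeA", "Other"), each = 5)), "insect")
  cat <- compoundCatalog(list(Pc1 = "cX", Pc2 = "cX",
                              Pn1 = "cY", Pn2 = "cY"))
  res <- suppressMessages(enrichment(net, cat, it, "CladeA"))
  row <- res[res$compound == "cX", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(10L, 0L, 0L, 10L))
  expect_equal(row$cramersV, 1)
  expect_equal(row$direction, "enriched")
  expect_lt(row$p, 1e-4)
  # identical row proportions -> V = 0, p = 1 (cY is its mirror image)
  both <- compoundCatalog(list(Pc1 = "cZ", Pc2 = "cZ", Pn1 = "cZ",
                               Pn2 = "cZ"))
  res2 <- suppressMessages(enrichment(net, both, it, "CladeA"))
  expect_equal(res2$cramersV, 0)
  expect_equal(res2$p, 1)
  # plant unit counts species, not relationships
  res3 <- enrichment(net, cat, it, "CladeA", unit = "plant")
  expect_equal(res3[res3$compound == "cX", "a"], 2L)
  expect_error(suppressMessages(enrichment(net, cat, it, "Nope")),
               "not present")
})

test_that("Fisher p and V are invariant under row and column swaps", {
  set.seed(67)
  for (rep in 1:20) {
    t <- sample(0:12, 4, TRUE)
    p0 <- phytophagnet:::.fisher2x2(t[1], t[2], t[3], t[4])
    v0 <- phytophagnet:::.cramersV(t[1], t[2], t[3], t[4])
    expect_equal(phytophagnet:::.fisher2x2(t[3], t[4], t[1], t[2]), p0,
                 tolerance = 1e-12)
    expect_equal(phytophagnet:::.fisher2x2(t[2], t[1], t[4], t[3]), p0,
                 tolerance = 1e-12)
    expect_equal(phytophagnet:::.cramersV(t[3], t[4], t[1], t[2]), v0)
    expect_equal(phytophagnet:::.cramersV(t[2], t[1], t[4], t[3]), v0)
  }
})

test_that("compound partition separates common from common specific", {
  cat <- compoundCatalog(list(P1 = c("C1"), P2 = c("C1"),
                              P3 = c("C1", "C2"), P4 = c("C1", "C2", "C9")))
  part <- commonVsCommonSpecific(cat, c("P3", "P4"), c("P1", "P2"))
  expect_equal(part$common, "C1")
  expect_equal(part$commonSpecific, "C2")
  expect_equal(part$other, "C9")
  # hosts share nothing -> empty common-specific set
  cat2 <- compoundCatalog(list(P1 = "a", P2 = "b", P3 = "c"))
  expect_length(commonVsCommonSpecific(cat2, c("P1", "P2"), "P3")$commonSpecific,
                0)
  # single host vs single background: set difference
  part3 <- commonVsCommonSpecific(cat, "P4", "P3")
  expect_setequal(part3$commonSpecific, "C9")
  expect_error(commonVsCommonSpecific(cat, c("P1", "P2"), c("P2", "P3")),
               "disjoint")
})

test_that("compound-driven networks give positive reproducible N_s scores", {
  st <- simulateStudy(generatorConfig(betaCompound = 4, seed = 71))
  cfg <- nullModelConfig(replicates = 300, seed = 72)
  r1 <- feedOnCompoundTest(st$network, st$catalog, st$insectTaxonomy,
                           config = cfg)
  r2 <- feedOnCompoundTest(st$network, st$catalog, st$insectTaxonomy,
                           config = cfg)
  expect_gt(r1$global@z, 3)
  expect_identical(r1$global@z, r2$global@z)
})
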