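test_that("generators are pure functions of the seed", {
  cfg <- SimConfig(nGenes = 100, nPlantedUp = 10, nPlantedDown = 10,
                   ppiCoreSize = 4, dispersion = 1e6, seed = 1)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(countsMatrix(a$counts), countsMatrix(b$counts))
  expect_identical(a$truth, b$truth)
  expect_identical(termGenes(a$catalog), termGenes(b$catalog))
  expect_identical(ppiEdges(a$ppi), ppiEdges(b$ppi))
  ## a different seed changes the matrix
  c <- simulateCounts(SimConfig(nGenes = 100, nPlantedUp = 10,
                                nPlantedDown = 10, ppiCoreSize = 4,
                                dispersion = 1e6, seed = 2))
  expect_false(identical(countsMatrix(a$counts), countsMatrix(c$counts)))
})

test_that("planted categories partition the universe and the core nests", {
  sim <- simulateCounts(SimConfig(nGenes = 300, nPlantedUp = 30,
                                  nPlantedDown = 20, seed = 3))
  tr <- sim$truth
  all3 <- c(plantedUp(tr), plantedDown(tr), nullGenes(tr))
  expect_setequal(all3, rownames(countsMatrix(sim$counts)))
  expect_equal(length(all3), 300)
  expect_equal(anyDuplicated(all3), 0L)
  expect_true(all(plantedCore(tr) %in% plantedUp(tr)))
})

test_that("zero planted effect leaves roles exchangeable up to library scaling", {
  cfg <- SimConfig(nGenes = 800, upLog2fc = 0, downLog2fc = 0,
                   dispersion = 1e6, seed = 4)
  sim <- simulateCounts(cfg)
  m <- countsMatrix(sim$counts)
  libs <- librarySizes(sim$counts)
  lfc <- log2FoldChange(rowMeans(m[, lineSamples(sim$counts)]),
                        m[, "BCFF"],
                        mean(libs[lineSamples(sim$counts)]), libs["BCFF"])
  ## genes with decent expression show no systematic shift
  hi <- m[, "BCFF"] >= 50
  expect_lt(abs(mean(lfc[hi])), 0.1)
})

test_that("planted log2 fold change is recovered empirically", {
  cfg <- SimConfig(nGenes = 2000, nPlantedUp = 100, upLog2fc = 3, seed = 42)
  sim <- simulateCounts(cfg)
  m <- countsMatrix(sim$counts)
  libs <- librarySizes(sim$counts)
  up <- plantedUp(sim$truth)
  obs <- sapply(lineSamples(sim$counts), function(l)
    log2FoldChange(m[up, l], m[up, "BCFF"], libs[l], libs["BCFF"]))
  expect_lt(abs(mean(obs) - 3), 0.5)
})

test_that("planted-up genes sit low in the baseline, high in the lines", {
  sim <- simulateCounts(SimConfig(seed = 7))
  m <- countsMatrix(sim$counts)
  up <- plantedUp(sim$truth)
  expect_gt(mean(m[up, "BCFF"] <= 50), 0.95)
  expect_gt(mean(rowMeans(m[up, lineSamples(sim$counts)]) >= 20), 0.95)
})

test_that("designated enriched terms are hypergeometrically extreme", {
  cfg <- SimConfig(nGenes = 2000, nPlantedUp = 100, seed = 8,
                   nTermsPerLevel = 5L, nEnrichedPerLevel = 1L,
                   termSizeRange = c(40L, 40L), enrichmentFraction = 0.8)
  sim <- simulateCounts(cfg)
  catalog <- simulateAnnotations(sim$truth, cfg)
  up <- plantedUp(sim$truth)
  for (tid in enrichedTerms(sim$truth)) {
    members <- termGenes(catalog)[[tid]]
    k <- length(intersect(members, up))
    p <- oracleHyperP(k, length(members), length(up), 2000)
    expect_lt(p, 1e-10)
  }
})

test_that("a catalog drawn at background prevalence shows no enrichment", {
  cfg <- SimConfig(nGenes = 2000, nPlantedUp = 100, seed = 9,
                   nTermsPerLevel = 5L, nEnrichedPerLevel = 1L,
                   enrichmentFraction = 100 / 2000)
  sim <- simulateCounts(cfg)
  catalog <- simulateAnnotations(sim$truth, cfg)
  up <- plantedUp(sim$truth)
  ## coverage guarantees still add planted genes; judge only the sampled
  ## fraction via the background terms, which draw uniformly
  bg <- setdiff(catalogTerms(catalog)$term_id, enrichedTerms(sim$truth))
  ps <- vapply(bg, function(tid) {
    members <- termGenes(catalog)[[tid]]
    oracleHyperP(length(intersect(members, up)), length(members),
                 length(up), 2000)
  }, numeric(1))
  expect_gt(min(ps), 1e-6)
})

test_that("every inducible gene is annotated at every level", {
  cfg <- SimConfig(nGenes = 300, nPlantedUp = 30, nPlantedDown = 20,
                   seed = 10, nTermsPerLevel = 8L)
  sim <- simulateCounts(cfg)
  catalog <- simulateAnnotations(sim$truth, cfg)
  for (lv in annotationLevelNames()) {
    members <- unique(unlist(termGenes(catalog, lv)))
    expect_true(all(inducibleGenes(sim$truth) %in% members),
                label = paste("inducible coverage at", lv))
  }
})

test_that("the planted PPI core is wired densely", {
  ## complete core, no background: exactly C(6,2) edges
  cfg <- SimConfig(nGenes = 100, nPlantedUp = 10, nPlantedDown = 5,
                   ppiCoreSize = 6, ppiCoreEdgeProb = 1,
                   ppiBackgroundEdgeProb = 0, seed = 11)
  sim <- simulateCounts(cfg)
  ppi <- simulatePPI(sim$truth, cfg)
  expect_equal(numEdges(ppi), choose(6, 2))
  deg <- oracleDegrees(ppiNodes(ppi), ppiEdges(ppi))
  expect_true(all(deg[plantedCore(sim$truth)] >= 4))
  ## default config: full-graph degree of every core node still >= 4
  cfgD <- SimConfig(seed = 12)
  simD <- simulateCounts(cfgD)
  ppiD <- simulatePPI(simD$truth, cfgD)
  degD <- oracleDegrees(ppiNodes(ppiD), ppiEdges(ppiD))
  expect_true(all(degD[plantedCore(simD$truth)] >= 4))
  expect_true(all(ppiEdges(ppiD)$combined_score >= 400 &
                    ppiEdges(ppiD)$combined_score <= 1000))
})

test_that("degenerate configurations are rejected", {
  expect_error(SimConfig(nGenes = 100, nPlantedUp = 80, nPlantedDown = 40),
               "exceed")
  expect_error(SimConfig(dispersion = 0), "dispersion")
  expect_error(SimConfig(ppiCoreSize = 1), "ppiCoreSize")
  cfg <- SimConfig(nGenes = 50, nPlantedUp = 10, nPlantedDown = 5,
                   ppiCoreSize = 4, termSizeRange = c(10L, 40L), seed = 1)
  sim <- simulateCounts(cfg)
  cfg@termSizeRange <- c(10L, 60L)  # exceeds the 50-gene universe
  expect_error(simulateAnnotations(sim$truth, cfg), "universe")
})
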