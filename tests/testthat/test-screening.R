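test_that("count filter boundaries are inclusive and errors name the gene", {
  pcs <- toyCountSet()
  spec <- CountFilterSpec()  # 50 / 20, mean aggregation
  kept <- countFilter(rownames(countsMatrix(pcs)), pcs, spec)
  expect_true("A" %in% kept)       # baseline 10, mean line 103
  expect_false("B" %in% kept)      # baseline 60 > 50
  expect_true("C" %in% kept)       # mean(19,21,20) = 20, inclusive
  expect_false("D" %in% kept)      # lines silent
  ## a gene at exactly the baseline boundary is retained
  m <- matrix(c(50, 100, 51, 100), 2, byrow = TRUE,
              dimnames = list(c("EDGE", "OVER"), c("B", "L")))
  pcs2 <- PluriCountSet(m, c(B = "baseline", L = "line"))
  expect_equal(countFilter(c("EDGE", "OVER"), pcs2, spec), "EDGE")
  expect_error(countFilter("GHOST", pcs, spec), "GHOST")
})

test_that("aggregation rules differ exactly as hand enumeration says", {
  pcs <- toyCountSet()
  ## gene C: lines (19, 21, 20): mean passes, all_lines fails, any passes,
  ## at_least_k passes for k <= 2
  expect_true("C" %in% countFilter("C", pcs, CountFilterSpec(aggregation = "mean")))
  expect_length(countFilter("C", pcs, CountFilterSpec(aggregation = "all_lines")), 0)
  expect_true("C" %in% countFilter("C", pcs, CountFilterSpec(aggregation = "any_line")))
  expect_true("C" %in% countFilter("C", pcs,
    CountFilterSpec(aggregation = "at_least_k", k = 2)))
  expect_length(countFilter("C", pcs,
    CountFilterSpec(aggregation = "at_least_k", k = 3)), 0)
  expect_error(countFilter("C", pcs,
    CountFilterSpec(aggregation = "at_least_k", k = 9)), "exceeds")
})

test_that("count filter is idempotent and monotone in its thresholds", {
  sim <- simulateCounts(SimConfig(nGenes = 400, nPlantedUp = 40,
                                  nPlantedDown = 20, seed = 41))
  pcs <- sim$counts
  genes <- rownames(countsMatrix(pcs))
  for (agg in c("mean", "all_lines", "any_line", "at_least_k")) {
    spec <- CountFilterSpec(aggregation = agg, k = 3)
    once <- countFilter(genes, pcs, spec)
    expect_identical(countFilter(once, pcs, spec), once)
    ## raising minLine never grows the set
    stricter <- countFilter(genes, pcs,
      CountFilterSpec(minLine = 40, aggregation = agg, k = 3))
    expect_true(all(stricter %in% once))
    ## raising maxBaseline never shrinks it
    looser <- countFilter(genes, pcs,
      CountFilterSpec(maxBaseline = 500, aggregation = agg, k = 3))
    expect_true(all(once %in% looser))
  }
})

## Shared fixture: toy DE + screens whose membership is hand-checkable.
toyScreenFixture <- function() {
  pcs <- toyCountSet()
  de <- callDE(pcs, significanceOn = "p")
  list(pcs = pcs, de = de, catalog = toyCatalog())
}

test_that("group 1 keeps up-regulated term members passing counts", {
  fx <- toyScreenFixture()
  sel <- S4Vectors::DataFrame(term_id = c("GOP1", "KP1"))
  g1 <- group1Screen(fx$de, sel, fx$catalog, fx$pcs, CountFilterSpec(),
                     minUpLines = 1)
  ## A: in GOP1+KP1, up everywhere, counts pass -> in, with both terms listed
  ## C: in GOP1 but its fold changes sit below threshold -> depends on DE;
  ## E: in GOP1 but down-regulated; B: not in selected terms (GOP2 excluded)
  expect_true("A" %in% screenGenes(g1))
  expect_false("B" %in% screenGenes(g1))
  expect_false("E" %in% screenGenes(g1))
  prov <- screenProvenance(g1)
  expect_equal(prov$terms[prov$gene_id == "A"], "GOP1,KP1")
  expect_gt(prov$n_up_lines[prov$gene_id == "A"], 0)
  expect_warning(
    empty <- group1Screen(fx$de, S4Vectors::DataFrame(term_id = character()),
                          fx$catalog, fx$pcs),
    "no selected terms")
  expect_length(screenGenes(empty), 0)
})

test_that("group-1 recall on planted truth is an exact set identity", {
  cfg <- SimConfig(nGenes = 600, nPlantedUp = 60, nPlantedDown = 30,
                   seed = 42, nTermsPerLevel = 10L)
  study <- simulateStudy(cfg)
  de <- callDE(study$counts)
  universe <- rownames(countsMatrix(study$counts))
  enr <- enrich(upregulatedGenes(de), study$catalog, universe)
  sel <- selectTopTerms(enr)
  g1 <- group1Screen(de, sel, study$catalog, study$counts)
  ## oracle: direct set algebra over the same ingredients
  members <- unique(unlist(termGenes(study$catalog)[sel$term_id]))
  expected <- intersect(intersect(members, upregulatedGenes(de)),
                        countFilter(universe, study$counts,
                                    CountFilterSpec()))
  expect_setequal(screenGenes(g1), expected)
  ## planted-up genes in selected terms that qualify are fully recalled
  planted <- intersect(plantedUp(study$truth), expected)
  expect_true(all(planted %in% screenGenes(g1)))
  expect_gt(length(planted), 0)
})

test_that("main-subdataset selection counts detected inducible genes", {
  catalog <- toyCatalog()
  universe <- c("A", "B", "C", "D", "E", "F")
  ## inducible list: A and C detected, Z not detected
  sel <- selectMainSubdatasets(c("A", "C", "Z"), catalog, universe,
                               minInduciblePerTerm = 1)
  expect_true(all(c("GOP1", "KP1") %in% sel$term_id))  # GOP1 has A+C, KP1 has A
  expect_false("GOP2" %in% sel$term_id)                # holds no inducible gene
  expect_equal(sel$n_inducible[sel$term_id == "GOP1"], 2L)
  ## ranked by coverage within level
  expect_equal(sel$term_id[sel$level == "GO-process"][1], "GOP1")
  sel2 <- selectMainSubdatasets(c("A", "C", "Z"), catalog, universe,
                                minInduciblePerTerm = 2)
  expect_equal(sel2$term_id, "GOP1")
  expect_warning(none <- selectMainSubdatasets("Z", catalog, universe),
                 "no inducible gene")
  expect_equal(nrow(none), 0L)
})

test_that("group 2 equals hand enumeration on the toy instance", {
  fx <- toyScreenFixture()
  subs <- selectMainSubdatasets(c("A", "C"), fx$catalog,
                                rownames(countsMatrix(fx$pcs)),
                                minInduciblePerTerm = 1)
  g2 <- group2Screen(fx$de, subs, fx$catalog, fx$pcs)
  ## subdataset members: GOP1 {A,C,E}, KP1 {A,F,D}; up + count-passing: A, F
  up <- upregulatedGenes(fx$de)
  members <- unique(unlist(termGenes(fx$catalog)[subs$term_id]))
  expected <- intersect(intersect(members, up),
                        countFilter(rownames(countsMatrix(fx$pcs)), fx$pcs,
                                    CountFilterSpec()))
  expect_setequal(screenGenes(g2), expected)
  expect_true("A" %in% screenGenes(g2))
  expect_false("E" %in% screenGenes(g2))  # down-regulated member excluded
})

test_that("group 3 equals a per-line sort oracle and breaks ties by id", {
  set.seed(43)
  n <- 50
  genes <- sprintf("G%02d", 1:n)
  m <- cbind(B = rep(5L, n),
             L1 = sample(0:300, n, TRUE),
             L2 = sample(0:300, n, TRUE),
             L3 = sample(0:300, n, TRUE))
  rownames(m) <- genes
  m <- rbind(m, PAD = as.integer(2e5 - colSums(m)))
  pcs <- PluriCountSet(m, c(B = "baseline", L1 = "line", L2 = "line",
                            L3 = "line"))
  de <- callDE(pcs, significanceOn = "p")
  spec <- CountFilterSpec()
  topK <- 5L
  g3 <- group3Supplementary(de, pcs, spec, topK = topK)
  ## oracle: per line, sort qualifying up genes by count desc then id
  qualifying <- countFilter(upregulatedGenes(de, 1), pcs, spec)
  expected <- character()
  for (s in c("L1", "L2", "L3")) {
    upHere <- intersect(qualifying,
                        de$gene_id[de$line_id == s & de$direction == "up"])
    o <- upHere[order(-m[upHere, s], upHere)]
    expected <- union(expected, utils::head(o, topK))
  }
  expect_setequal(screenGenes(g3), expected)
  ## fewer qualifying genes than topK keeps them all
  gAll <- group3Supplementary(de, pcs, spec, topK = 1000L)
  expect_setequal(screenGenes(gAll), qualifying)
  ## deterministic tie handling: equal counts order lexicographically
  mt <- matrix(c(0, 100, 0, 100, 0, 100, 0, 50), 4, byrow = TRUE,
               dimnames = list(c("TB", "TA", "TC", "TD"), c("B", "L1")))
  mt <- rbind(mt, PAD = 1e5 - colSums(mt))
  pcs2 <- PluriCountSet(mt, c(B = "baseline", L1 = "line"))
  de2 <- callDE(pcs2, significanceOn = "p")
  g3t <- group3Supplementary(de2, pcs2, CountFilterSpec(), topK = 2L)
  expect_setequal(screenGenes(g3t), c("TA", "TB"))  # TC loses the tie
})

test_that("screen sets shrink/grow monotonically with the count thresholds", {
  cfg <- SimConfig(nGenes = 500, nPlantedUp = 50, nPlantedDown = 20,
                   seed = 44, nTermsPerLevel = 8L)
  study <- simulateStudy(cfg)
  de <- callDE(study$counts)
  universe <- rownames(countsMatrix(study$counts))
  sel <- selectTopTerms(enrich(upregulatedGenes(de), study$catalog,
                               universe))
  base <- CountFilterSpec()
  tighterLine <- CountFilterSpec(minLine = 60)
  looserBase <- CountFilterSpec(maxBaseline = 200)
  for (screen in list(
    function(spec) screenGenes(group1Screen(de, sel, study$catalog,
                                            study$counts, spec)),
    function(spec) screenGenes(group3Supplementary(de, study$counts, spec,
                                                   topK = 1000L)))) {
    mid <- screen(base)
    expect_true(all(screen(tighterLine) %in% mid))
    expect_true(all(mid %in% screen(looserBase)))
  }
})

test_that("group comparison reports overlap and Jaccard", {
  fx <- toyScreenFixture()
  sel <- S4Vectors::DataFrame(term_id = c("GOP1", "KP1"))
  g1 <- group1Screen(fx$de, sel, fx$catalog, fx$pcs)
  cmp <- compareGroups(g1, g1)
  expect_equal(cmp$jaccard, 1)
  subs <- selectMainSubdatasets("B", fx$catalog,
                                rownames(countsMatrix(fx$pcs)),
                                minInduciblePerTerm = 1)
  g2 <- group2Screen(fx$de, subs, fx$catalog, fx$pcs)
  cmp2 <- compareGroups(g1, g2)
  expect_equal(cmp2$intersection_size, length(intersect(screenGenes(g1),
                                                        screenGenes(g2))))
  expect_equal(cmp2$jaccard,
               cmp2$intersection_size / length(union(screenGenes(g1),
                                                     screenGenes(g2))))
})
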