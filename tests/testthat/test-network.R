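test_that("induced subnetworks keep exactly the query-internal edges", {
  tri <- PPINetwork(data.frame(protein1 = c("A", "B", "A"),
                               protein2 = c("B", "C", "C"),
                               combined_score = 900))
  sub <- inducedNetwork(c("A", "B"), tri)
  expect_equal(numEdges(sub), 1L)
  expect_setequal(ppiNodes(sub), c("A", "B"))
  ## identity on the full node set
  all <- inducedNetwork(c("A", "B", "C"), tri)
  expect_identical(ppiEdges(all), ppiEdges(tri))
  ## disjoint query
  expect_warning(none <- inducedNetwork(character(), tri), "empty query")
  expect_equal(numNodes(none), 0L)
  expect_equal(numNodes(inducedNetwork(c("X", "Y"), tri)), 0L)
  ## queried-but-isolated genes stay as degree-0 nodes
  iso <- inducedNetwork(c("A", "C"), PPINetwork(ppiEdges(tri)[1, ],
                                                nodes = c("A", "B", "C")))
  expect_setequal(ppiNodes(iso), c("A", "C"))
  expect_equal(numEdges(iso), 0L)
})

test_that("component filtering is inclusive at the size boundary", {
  ## one component of 6 (path), one of 5 (path), one singleton
  p6 <- sprintf("A%d", 1:6); p5 <- sprintf("B%d", 1:5)
  edges <- data.frame(
    protein1 = c(p6[-6], p5[-5]),
    protein2 = c(p6[-1], p5[-1]),
    combined_score = 900)
  net <- PPINetwork(edges, nodes = c(p6, p5, "LONE"))
  comp <- filterComponents(net, minSize = 6)
  expect_setequal(comp$gene_id, p6)
  expect_equal(unique(comp$component_id), "C1")
  expect_equal(nrow(filterComponents(net, minSize = 7)), 0L)
  expect_equal(nrow(filterComponents(
    PPINetwork(edges[0, ]), 6)), 0L)
})

test_that("components and degrees match the traversal oracle on random graphs", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    edges <- randomEdgeTable(n, runif(1, 0.02, 0.1))
    nodes <- sprintf("N%03d", seq_len(n))
    net <- PPINetwork(edges, nodes = nodes)
    comp <- filterComponents(net, minSize = 1)
    oracle <- oracleComponents(nodes, ppiEdges(net))
    got <- unname(split(comp$gene_id, comp$component_id))
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
    deg <- oracleDegrees(nodes, ppiEdges(net))
    expect_equal(stats::setNames(comp$degree, comp$gene_id)[names(deg)],
                 deg)
  }
})

test_that("component ids are stable: size-descending, then smallest member", {
  edges <- data.frame(
    protein1 = c("X1", "X1", "A1", "A1", "A2"),
    protein2 = c("X2", "X3", "A2", "A3", "A3"),
    combined_score = 900)
  comp <- filterComponents(PPINetwork(edges), minSize = 3)
  ## both components have size 3; A-block has the smaller member id
  expect_equal(comp$component_id[comp$gene_id == "A1"], "C1")
  expect_equal(comp$component_id[comp$gene_id == "X1"], "C2")
})

test_that("core extraction keeps high-degree nodes only", {
  ## star K1,5: only the hub reaches degree 4
  star <- PPINetwork(data.frame(protein1 = "HUB",
                                protein2 = sprintf("S%d", 1:5),
                                combined_score = 900))
  compS <- filterComponents(star, 6)
  expect_equal(coreGenes(compS, 4), "HUB")
  ## path of 6: max degree 2, no core
  path <- PPINetwork(data.frame(protein1 = sprintf("P%d", 1:5),
                                protein2 = sprintf("P%d", 2:6),
                                combined_score = 900))
  expect_length(coreGenes(filterComponents(path, 6), 4), 0)
  ## complete K6: every node has degree 5
  k6 <- t(utils::combn(sprintf("K%d", 1:6), 2))
  comp6 <- filterComponents(PPINetwork(
    data.frame(protein1 = k6[, 1], protein2 = k6[, 2],
               combined_score = 900)), 6)
  expect_setequal(coreGenes(comp6, 4), sprintf("K%d", 1:6))
  ## monotone in minDegree
  expect_true(all(coreGenes(comp6, 6) %in% coreGenes(comp6, 4)))
  expect_length(coreGenes(comp6, 6), 0)
})

test_that("candidate combination obeys inclusion-exclusion and labeling", {
  ct <- combineCandidates(c("A", "B"), c("B", "C"))
  expect_equal(nrow(ct), 3L)
  expect_equal(ct$source[ct$gene_id == "B"], "both")
  expect_equal(sort(ct$gene_id), c("A", "B", "C"))
  ct2 <- combineCandidates(c("A", "B"), c("X", "Y", "Z"))
  expect_equal(nrow(ct2), 5L)
  set.seed(52)
  for (i in 1:20) {
    universe <- sprintf("G%03d", 1:80)
    core <- sample(universe, sample(0:40, 1))
    supp <- sample(universe, sample(0:40, 1))
    ct3 <- combineCandidates(core, supp)
    expect_equal(nrow(ct3),
                 length(core) + length(supp) - length(intersect(core, supp)))
    expect_equal(sum(ct3$source == "both"), length(intersect(core, supp)))
  }
})

test_that("candidate rows carry network and expression evidence", {
  k6 <- t(utils::combn(sprintf("K%d", 1:6), 2))
  net <- PPINetwork(data.frame(protein1 = k6[, 1], protein2 = k6[, 2],
                               combined_score = 900))
  comp <- filterComponents(net, 6)
  core <- coreGenes(comp, 4)
  ct <- combineCandidates(core, c("K1", "EXTRA"), components = comp)
  expect_equal(ct$degree[ct$gene_id == "K2"], 5L)
  expect_true(is.na(ct$degree[ct$gene_id == "EXTRA"]))
  expect_equal(ct$source[ct$gene_id == "K1"], "both")
  ## ordering: both first, then degree descending, then id
  expect_equal(ct$gene_id[1], "K1")
  expect_equal(ct$gene_id[nrow(ct)], "EXTRA")
})
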