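#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
NULL

## ---------------------------------------------------------------------------
## Annotation levels
## ---------------------------------------------------------------------------

.kAnnotationLevels <- c("KEGG-A", "KEGG-B", "KEGG-pathway",
                        "GO-component", "GO-function", "GO-process")
.kGoLevels   <- c("GO-component", "GO-function", "GO-process")
.kKeggLevels <- c("KEGG-A", "KEGG-B", "KEGG-pathway")

#' The six annotation levels used throughout the pipeline
#'
#' Gene-set screening operates over six catalog levels: three KEGG strata
#' (A-class, B-class, pathway) and the three GO namespaces (cellular
#' component, molecular function, biological process).
#'
#' @return Character vector of the six level names.
#' @export
#' @examples
#' annotationLevelNames()
annotationLevelNames <- function() .kAnnotationLevels

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' @rdname SimConfig
#' @export
setClass("SimConfig",
  slots = c(
    nGenes = "integer", nLines = "integer", nBaseline = "integer",
    seed = "integer",
    libSizeBaseline = "numeric", libSizeLine = "numeric",
    dispersion = "numeric", meanLog = "numeric", sdLog = "numeric",
    nPlantedUp = "integer", nPlantedDown = "integer",
    upLog2fc = "numeric", downLog2fc = "numeric",
    plantedUpMeanLog = "numeric", plantedUpSdLog = "numeric",
    nTermsPerLevel = "integer", nEnrichedPerLevel = "integer",
    enrichmentFraction = "numeric", termSizeRange = "integer",
    ppiCoreSize = "integer", ppiCoreEdgeProb = "numeric",
    ppiBackgroundEdgeProb = "numeric",
    nInducible = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 10L) msg <- c(msg, "nGenes must be >= 10")
  if (object@nLines < 1L) msg <- c(msg, "nLines must be >= 1")
  if (object@nBaseline < 1L) msg <- c(msg, "nBaseline must be >= 1")
  if (object@nPlantedUp < 0L || object@nPlantedDown < 0L)
    msg <- c(msg, "planted block sizes must be >= 0")
  if (object@nPlantedUp + object@nPlantedDown > object@nGenes)
    msg <- c(msg, "nPlantedUp + nPlantedDown must not exceed nGenes")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion (NB shape) must be > 0")
  if (object@libSizeBaseline <= 0 || object@libSizeLine <= 0)
    msg <- c(msg, "library sizes must be positive")
  if (length(object@termSizeRange) != 2L || any(object@termSizeRange < 1L) ||
      object@termSizeRange[1L] > object@termSizeRange[2L])
    msg <- c(msg, "termSizeRange must be an increasing pair of integers >= 1")
  if (object@termSizeRange[2L] > object@nGenes)
    msg <- c(msg, "termSizeRange must not exceed the gene universe")
  if (object@ppiCoreSize < 2L) msg <- c(msg, "ppiCoreSize must be >= 2")
  if (object@ppiCoreSize > max(object@nPlantedUp, 0L))
    msg <- c(msg, "ppiCoreSize must not exceed nPlantedUp")
  if (object@enrichmentFraction < 0 || object@enrichmentFraction > 1)
    msg <- c(msg, "enrichmentFraction must be in [0,1]")
  if (object@ppiBackgroundEdgeProb < 0 || object@ppiBackgroundEdgeProb > 1 ||
      object@ppiCoreEdgeProb < 0 || object@ppiCoreEdgeProb > 1)
    msg <- c(msg, "edge probabilities must be in [0,1]")
  if (object@nInducible < 1L || object@nInducible > object@nGenes)
    msg <- c(msg, "nInducible must be in [1, nGenes]")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic reprogramming study
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' study design the pipeline targets: one unreplicated fibroblast baseline
#' against seven clonal iPSC lines, negative-binomial counts with log-normal
#' gene base means, a planted block of up-regulated pluripotency genes that
#' are near-silent in the baseline, annotation terms enriched for the planted
#' block, and a densely wired planted core in the interaction graph.
#'
#' @param nGenes Number of genes in the universe.
#' @param nLines Number of reprogrammed (iPSC) lines.
#' @param nBaseline Number of baseline (fibroblast) replicate columns.
#' @param seed Master seed; fully determines all generated outputs.
#' @param libSizeBaseline,libSizeLine Expected total counts per sample.
#' @param dispersion Negative-binomial shape (`size`); variance is
#'   `mu + mu^2/dispersion`, so large values approach Poisson.
#' @param meanLog,sdLog Log-normal parameters of background gene base means.
#' @param nPlantedUp,nPlantedDown Sizes of the planted up-/down-regulated
#'   blocks (pluripotency block and fibroblast block).
#' @param upLog2fc,downLog2fc Planted effect sizes in log2 units.
#' @param plantedUpMeanLog,plantedUpSdLog Log-normal parameters of the
#'   baseline means of planted-up genes. Kept low by default: pluripotency
#'   genes are silenced in fibroblasts, which is also what lets them pass the
#'   downstream baseline-count screen.
#' @param nTermsPerLevel Terms generated per annotation level.
#' @param nEnrichedPerLevel Designated planted-enriched terms per level.
#' @param enrichmentFraction Fraction of an enriched term's members drawn
#'   from the planted-up block.
#' @param termSizeRange Integer pair; term sizes are uniform in this range.
#' @param ppiCoreSize Size of the planted densely connected core
#'   (a subset of the planted-up block).
#' @param ppiCoreEdgeProb Edge probability within the planted core
#'   (1 = complete graph).
#' @param ppiBackgroundEdgeProb Background (Erdos-Renyi) edge probability.
#' @param nInducible Length of the simulated known-inducible gene list.
#'
#' @return A validated `SimConfig` object.
#' @seealso [simulateCounts()], [simulateAnnotations()], [simulatePPI()]
#' @export
#' @examples
#' cfg <- SimConfig(nGenes = 200, seed = 7)
#' cfg
SimConfig <- function(nGenes = 2000L, nLines = 7L, nBaseline = 1L, seed = 1L,
                      libSizeBaseline = 1e6, libSizeLine = 1e6,
                      dispersion = 100, meanLog = log(150), sdLog = 1.5,
                      nPlantedUp = 100L, nPlantedDown = 100L,
                      upLog2fc = 3, downLog2fc = -3,
                      plantedUpMeanLog = log(12), plantedUpSdLog = 0.6,
                      nTermsPerLevel = 30L, nEnrichedPerLevel = 3L,
                      enrichmentFraction = 0.8,
                      termSizeRange = c(15L, 60L),
                      ppiCoreSize = 6L, ppiCoreEdgeProb = 1,
                      ppiBackgroundEdgeProb = 0.002,
                      nInducible = 25L) {
  new("SimConfig",
      nGenes = as.integer(nGenes), nLines = as.integer(nLines),
      nBaseline = as.integer(nBaseline), seed = as.integer(seed),
      libSizeBaseline = as.numeric(libSizeBaseline),
      libSizeLine = as.numeric(libSizeLine),
      dispersion = as.numeric(dispersion),
      meanLog = as.numeric(meanLog), sdLog = as.numeric(sdLog),
      nPlantedUp = as.integer(nPlantedUp),
      nPlantedDown = as.integer(nPlantedDown),
      upLog2fc = as.numeric(upLog2fc), downLog2fc = as.numeric(downLog2fc),
      plantedUpMeanLog = as.numeric(plantedUpMeanLog),
      plantedUpSdLog = as.numeric(plantedUpSdLog),
      nTermsPerLevel = as.integer(nTermsPerLevel),
      nEnrichedPerLevel = as.integer(nEnrichedPerLevel),
      enrichmentFraction = as.numeric(enrichmentFraction),
      termSizeRange = as.integer(termSizeRange),
      ppiCoreSize = as.integer(ppiCoreSize),
      ppiCoreEdgeProb = as.numeric(ppiCoreEdgeProb),
      ppiBackgroundEdgeProb = as.numeric(ppiBackgroundEdgeProb),
      nInducible = as.integer(nInducible))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nBaseline,
      "baseline +", object@nLines, "line sample(s), seed", object@seed, "\n")
  cat("  planted:", object@nPlantedUp, "up @", object@upLog2fc, "log2FC,",
      object@nPlantedDown, "down @", object@downLog2fc, "log2FC; core of",
      object@ppiCoreSize, "\n")
  cat("  NB shape", object@dispersion, "| lib sizes",
      format(object@libSizeBaseline, big.mark = ","), "/",
      format(object@libSizeLine, big.mark = ","), "\n")
})

## ---------------------------------------------------------------------------
## SimTruth
## ---------------------------------------------------------------------------

#' @rdname SimTruth
#' @export
setClass("SimTruth",
  slots = c(plantedUp = "character", plantedDown = "character",
            nullGenes = "character", plantedCore = "character",
            enrichedTerms = "character", inducible = "character")
)

setValidity("SimTruth", function(object) {
  msg <- character()
  universe <- c(object@plantedUp, object@plantedDown, object@nullGenes)
  if (anyDuplicated(universe))
    msg <- c(msg, "plantedUp, plantedDown and nullGenes must partition the universe")
  if (!all(object@plantedCore %in% object@plantedUp))
    msg <- c(msg, "plantedCore must be a subset of plantedUp")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated study
#'
#' Records which genes were planted up/down-regulated, which belong to the
#' densely wired interaction core, which annotation terms were constructed to
#' be enriched, and the simulated known-inducible gene list. The three gene
#' categories partition the gene universe.
#'
#' @name SimTruth
#' @seealso [simulateCounts()]
NULL

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@plantedUp), "up /",
      length(object@plantedDown), "down /", length(object@nullGenes),
      "null genes;", length(object@plantedCore), "core;",
      length(object@enrichedTerms), "enriched terms;",
      length(object@inducible), "inducible\n")
})

#' @describeIn SimTruth Planted up-regulated genes.
#' @param truth A `SimTruth` object.
#' @export
plantedUp <- function(truth) truth@plantedUp
#' @describeIn SimTruth Planted down-regulated genes.
#' @export
plantedDown <- function(truth) truth@plantedDown
#' @describeIn SimTruth Unperturbed genes.
#' @export
nullGenes <- function(truth) truth@nullGenes
#' @describeIn SimTruth Planted interaction-core genes (subset of planted up).
#' @export
plantedCore <- function(truth) truth@plantedCore
#' @describeIn SimTruth Term ids constructed to be enriched for planted genes.
#' @export
enrichedTerms <- function(truth) truth@enrichedTerms
#' @describeIn SimTruth Simulated known-inducible gene list.
#' @export
inducibleGenes <- function(truth) truth@inducible

## ---------------------------------------------------------------------------
## PluriCountSet
## ---------------------------------------------------------------------------

#' @rdname PluriCountSet
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("PluriCountSet", contains = "SummarizedExperiment")

setValidity("PluriCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"role" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'role' column")
  else {
    if (!all(cd$role %in% c("baseline", "line")))
      msg <- c(msg, "roles must be 'baseline' or 'line'")
    if (sum(cd$role == "baseline") < 1L || sum(cd$role == "line") < 1L)
      msg <- c(msg, "need at least one baseline and one line sample")
  }
  if (length(msg)) msg else TRUE
})

#' Gene-by-sample count container with sample roles
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one integer assay
#' `"counts"` over genes (rows, uppercased symbols) and samples (columns),
#' with a `role` column in `colData` marking each sample as the fibroblast
#' `"baseline"` or a reprogrammed `"line"`.
#'
#' @param counts Integer matrix, genes x samples, with row and column names.
#' @param roles Character vector (one per sample, or named by sample id) of
#'   `"baseline"` / `"line"`.
#'
#' @return A validated `PluriCountSet`.
#' @seealso [readCountMatrix()], [simulateCounts()], [callDE()]
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 40L, 80L), 2, dimnames = list(c("A", "B"), c("F", "L1")))
#' pcs <- PluriCountSet(m, roles = c(F = "baseline", L1 = "line"))
#' librarySizes(pcs)
PluriCountSet <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("count matrix must have gene rownames and sample colnames")
  rownames(counts) <- canonicalSymbols(rownames(counts))
  if (!is.null(names(roles))) {
    missing <- setdiff(colnames(counts), names(roles))
    if (length(missing))
      .stopf("no role given for sample(s): %s", paste(missing, collapse = ", "))
    roles <- roles[colnames(counts)]
  } else if (length(roles) != ncol(counts)) {
    .stopf("roles must cover all %d samples", ncol(counts))
  }
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(role = unname(as.character(roles)),
                                   row.names = colnames(counts)))
  new("PluriCountSet", se)
}

setMethod("show", "PluriCountSet", function(object) {
  r <- sampleRoles(object)
  cat("PluriCountSet:", nrow(object), "genes x", ncol(object), "samples (",
      sum(r == "baseline"), "baseline,", sum(r == "line"), "line )\n")
  cat("  library sizes:", paste(format(librarySizes(object), big.mark = ","),
                                collapse = ", "), "\n")
})

#' @describeIn PluriCountSet Named vector of sample roles.
#' @param object A `PluriCountSet`.
#' @export
sampleRoles <- function(object) {
  r <- SummarizedExperiment::colData(object)$role
  names(r) <- colnames(object)
  r
}

#' @describeIn PluriCountSet Per-sample library sizes (column sums).
#' @export
librarySizes <- function(object)
  colSums(SummarizedExperiment::assay(object, "counts"))

#' @describeIn PluriCountSet Ids of baseline samples.
#' @export
baselineSamples <- function(object)
  names(which(sampleRoles(object) == "baseline"))

#' @describeIn PluriCountSet Ids of reprogrammed line samples.
#' @export
lineSamples <- function(object)
  names(which(sampleRoles(object) == "line"))

#' @describeIn PluriCountSet The integer count matrix.
#' @export
countsMatrix <- function(object) SummarizedExperiment::assay(object, "counts")

## ---------------------------------------------------------------------------
## AnnotationCatalog
## ---------------------------------------------------------------------------

#' @rdname AnnotationCatalog
#' @export
setClass("AnnotationCatalog",
  slots = c(level = "character", termId = "character",
            termName = "character", genes = "CharacterList")
)

setValidity("AnnotationCatalog", function(object) {
  msg <- character()
  n <- length(object@termId)
  if (length(object@level) != n || length(object@termName) != n ||
      length(object@genes) != n)
    return("level, termId, termName and genes must be parallel")
  if (!all(object@level %in% .kAnnotationLevels))
    msg <- c(msg, sprintf("levels must be among: %s",
                          paste(.kAnnotationLevels, collapse = ", ")))
  if (any(lengths(object@genes) == 0L))
    msg <- c(msg, "gene sets must be non-empty")
  dup <- tapply(object@termId, object@level, anyDuplicated)
  if (any(unlist(dup) > 0))
    msg <- c(msg, "term ids must be unique within a level")
  if (length(msg)) msg else TRUE
})

#' Six-level gene-set annotation catalog
#'
#' Holds term-to-gene-set mappings over the six annotation levels returned by
#' [annotationLevelNames()]. Gene symbols are stored uppercased.
#'
#' @param level,termId,termName Parallel character vectors.
#' @param genes A list (or [IRanges::CharacterList]) of member gene symbols,
#'   parallel to `termId`.
#'
#' @return A validated `AnnotationCatalog`.
#' @seealso [readGMT()], [enrich()], [selectMainSubdatasets()]
#' @export
AnnotationCatalog <- function(level, termId, termName, genes) {
  genes <- IRanges::CharacterList(lapply(genes, function(g)
    unique(canonicalSymbols(g))))
  new("AnnotationCatalog", level = as.character(level),
      termId = as.character(termId), termName = as.character(termName),
      genes = genes)
}

setMethod("show", "AnnotationCatalog", function(object) {
  cat("AnnotationCatalog:", length(object@termId), "terms over",
      length(unique(object@level)), "level(s)\n")
  tab <- table(object@level)
  for (lv in names(tab)) cat("  ", lv, ": ", tab[[lv]], " terms\n", sep = "")
})

setMethod("length", "AnnotationCatalog", function(x) length(x@termId))

#' @describeIn AnnotationCatalog Levels present in the catalog.
#' @param catalog An `AnnotationCatalog`.
#' @export
catalogLevels <- function(catalog) unique(catalog@level)

#' @describeIn AnnotationCatalog Term table (level, termId, termName, size),
#'   optionally restricted to one level.
#' @param level Optional level name to restrict to.
#' @export
catalogTerms <- function(catalog, level = NULL) {
  keep <- if (is.null(level)) rep(TRUE, length(catalog)) else catalog@level == level
  S4Vectors::DataFrame(level = catalog@level[keep], term_id = catalog@termId[keep],
                       term_name = catalog@termName[keep],
                       size = lengths(catalog@genes)[keep])
}

#' @describeIn AnnotationCatalog Named list of member-gene sets,
#'   optionally restricted to one level.
#' @export
termGenes <- function(catalog, level = NULL) {
  keep <- if (is.null(level)) rep(TRUE, length(catalog)) else catalog@level == level
  out <- catalog@genes[keep]
  names(out) <- catalog@termId[keep]
  out
}

#' @describeIn AnnotationCatalog Restrict the catalog to a subset of levels.
#' @param levels Character vector of level names to keep.
#' @export
subsetCatalog <- function(catalog, levels) {
  keep <- catalog@level %in% levels
  new("AnnotationCatalog", level = catalog@level[keep],
      termId = catalog@termId[keep], termName = catalog@termName[keep],
      genes = catalog@genes[keep])
}

## ---------------------------------------------------------------------------
## PPINetwork
## ---------------------------------------------------------------------------

#' @rdname PPINetwork
#' @export
setClass("PPINetwork",
  slots = c(nodes = "character", edges = "data.frame")
)

setValidity("PPINetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!identical(colnames(e), c("protein1", "protein2", "combined_score")))
    return("edges must have columns protein1, protein2, combined_score")
  if (nrow(e)) {
    if (any(e$protein1 == e$protein2)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$protein1 > e$protein2))
      msg <- c(msg, "edges must be canonically ordered (protein1 < protein2)")
    if (anyDuplicated(paste(e$protein1, e$protein2)))
      msg <- c(msg, "duplicate edges are not allowed")
    if (any(e$combined_score < 0 | e$combined_score > 1000))
      msg <- c(msg, "combined_score must lie in [0, 1000]")
    if (!all(c(e$protein1, e$protein2) %in% object@nodes))
      msg <- c(msg, "all edge endpoints must be nodes")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be unique")
  if (length(msg)) msg else TRUE
})

#' Confidence-scored protein-protein interaction network
#'
#' An undirected graph over uppercased gene symbols with STRING-convention
#' confidence scores in \[0, 1000\]. Edge pairs are canonicalized
#' (`protein1 < protein2`); self-loops are dropped with a warning and
#' duplicate pairs collapse to their maximum score.
#'
#' @param edges A data frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param nodes Optional node universe; defaults to the symbols occurring in
#'   `edges`. Extra nodes are kept as isolated (degree-0) vertices.
#'
#' @return A validated `PPINetwork`.
#' @seealso [readPPIEdges()], [inducedNetwork()], [filterComponents()]
#' @export
#' @examples
#' net <- PPINetwork(data.frame(protein1 = c("B", "A"), protein2 = c("A", "C"),
#'                              combined_score = c(900, 800)))
#' numEdges(net)
PPINetwork <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("protein1", "protein2", "combined_score") %in% colnames(edges)))
  p1 <- canonicalSymbols(edges$protein1)
  p2 <- canonicalSymbols(edges$protein2)
  score <- as.numeric(edges$combined_score)
  loop <- p1 == p2
  if (any(loop)) {
    .warnf("dropping %d self-loop edge(s) (e.g. %s)", sum(loop), p1[loop][1L])
    p1 <- p1[!loop]; p2 <- p2[!loop]; score <- score[!loop]
  }
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    score <- as.numeric(tapply(score, key, max)[unique(key)])
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  o <- order(a, b)
  e <- data.frame(protein1 = a[o], protein2 = b[o], combined_score = score[o],
                  stringsAsFactors = FALSE)
  nodes <- sort(unique(c(canonicalSymbols(nodes %||% character()), a, b)))
  new("PPINetwork", nodes = nodes, edges = e)
}

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork:", length(object@nodes), "nodes,", nrow(object@edges),
      "edges\n")
  if (nrow(object@edges))
    cat("  combined_score range:", min(object@edges$combined_score), "-",
        max(object@edges$combined_score), "\n")
})

#' @describeIn PPINetwork Number of nodes.
#' @param network A `PPINetwork`.
#' @export
numNodes <- function(network) length(network@nodes)

#' @describeIn PPINetwork Number of (canonical, undirected) edges.
#' @export
numEdges <- function(network) nrow(network@edges)

#' @describeIn PPINetwork The canonical edge table.
#' @export
ppiEdges <- function(network) network@edges

#' @describeIn PPINetwork The node set (including isolated nodes).
#' @export
ppiNodes <- function(network) network@nodes

## igraph view of a PPINetwork (internal)
#' @importFrom igraph graph_from_data_frame
.asIgraph <- function(network) {
  igraph::graph_from_data_frame(network@edges, directed = FALSE,
                                vertices = network@nodes)
}

## ---------------------------------------------------------------------------
## Result tables: DETable, EnrichmentResult, CandidateTable
## ---------------------------------------------------------------------------

#' @rdname callDE
#' @export
setClass("DETable", contains = "DFrame")

setValidity("DETable", function(object) {
  need <- c("gene_id", "line_id", "baseline_count", "line_count",
            "cpm_baseline", "cpm_line", "log2fc", "p", "q", "direction")
  if (!all(need %in% colnames(object)))
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) && any(object$q < object$p - 1e-12))
    return("q must be >= p (BH never decreases a p-value)")
  if (nrow(object) && !all(object$direction %in% c("up", "down", "ns")))
    return("direction must be up/down/ns")
  TRUE
})

#' @rdname enrich
#' @export
setClass("EnrichmentResult", contains = "DFrame")

setValidity("EnrichmentResult", function(object) {
  need <- c("level", "term_id", "k", "K", "n", "N", "p", "q")
  if (!all(need %in% colnames(object)))
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) && any(object$k > pmin(object$K, object$n)))
    return("overlap k must not exceed min(K, n)")
  if (nrow(object) && any(object$q < object$p - 1e-12))
    return("q must be >= p")
  TRUE
})

#' @rdname combineCandidates
#' @export
setClass("CandidateTable", contains = "DFrame")

setValidity("CandidateTable", function(object) {
  need <- c("gene_id", "source", "component_id", "degree")
  if (!all(need %in% colnames(object)))
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) && !all(object$source %in% c("core", "supplementary", "both")))
    return("source must be core/supplementary/both")
  if (anyDuplicated(object$gene_id)) return("gene_id must be unique")
  TRUE
})

## ---------------------------------------------------------------------------
## ScreenSet
## ---------------------------------------------------------------------------

#' @rdname ScreenSet
#' @export
setClass("ScreenSet",
  slots = c(label = "character", genes = "character",
            provenance = "DFrame", parameters = "list")
)

setValidity("ScreenSet", function(object) {
  msg <- character()
  if (!object@label %in% c("group1", "group2", "group3_supplementary"))
    msg <- c(msg, "label must be group1, group2 or group3_supplementary")
  if (anyDuplicated(object@genes)) msg <- c(msg, "genes must be unique")
  if (nrow(object@provenance) != length(object@genes) ||
      (length(object@genes) && !setequal(object@provenance$gene_id, object@genes)))
    msg <- c(msg, "provenance must cover exactly the member genes")
  if (length(msg)) msg else TRUE
})

#' A screening-group result with per-gene provenance
#'
#' Produced by [group1Screen()], [group2Screen()] and [group3Supplementary()].
#' Carries the member genes, a provenance table (which terms/lines/counts
#' qualified each gene), and the filter parameters used.
#'
#' @name ScreenSet
#' @seealso [countFilter()], [compareGroups()]
NULL

setMethod("show", "ScreenSet", function(object) {
  cat("ScreenSet <", object@label, ">: ", length(object@genes), " genes\n",
      sep = "")
  if (length(object@parameters))
    cat("  parameters:", paste(names(object@parameters),
                               vapply(object@parameters, function(x)
                                 paste(x, collapse = "/"), ""), sep = "=",
                               collapse = ", "), "\n")
})

setMethod("length", "ScreenSet", function(x) length(x@genes))

#' @describeIn ScreenSet Member genes of a screen set.
#' @param x A `ScreenSet`.
#' @export
screenGenes <- function(x) x@genes

#' @describeIn ScreenSet Per-gene provenance table.
#' @export
screenProvenance <- function(x) x@provenance

#' @describeIn ScreenSet Filter parameters the screen was run with.
#' @export
screenParameters <- function(x) x@parameters

.ScreenSet <- function(label, genes, provenance, parameters) {
  o <- order(genes)
  genes <- genes[o]
  provenance <- provenance[match(genes, provenance$gene_id), , drop = FALSE]
  rownames(provenance) <- NULL
  new("ScreenSet", label = label, genes = genes,
      provenance = provenance, parameters = parameters)
}

## ---------------------------------------------------------------------------
## CountFilterSpec
## ---------------------------------------------------------------------------

#' @rdname CountFilterSpec
#' @export
setClass("CountFilterSpec",
  slots = c(maxBaseline = "numeric", minLine = "numeric",
            aggregation = "character", k = "integer")
)

setValidity("CountFilterSpec", function(object) {
  msg <- character()
  if (object@maxBaseline < 0 || object@minLine < 0)
    msg <- c(msg, "thresholds must be >= 0")
  if (!object@aggregation %in% c("all_lines", "any_line", "mean", "at_least_k"))
    msg <- c(msg, "aggregation must be all_lines/any_line/mean/at_least_k")
  if (object@aggregation == "at_least_k" && object@k < 1L)
    msg <- c(msg, "k must be >= 1 for at_least_k")
  if (length(msg)) msg else TRUE
})

#' Count-threshold filter settings
#'
#' The screening groups retain a gene only if its baseline (fibroblast) count
#' is at most `maxBaseline` and its counts across the reprogrammed lines meet
#' `minLine` under the chosen aggregation rule. Both comparisons are
#' inclusive. The defaults (50 / 20) encode the convention of keeping genes
#' near-silent in fibroblasts but expressed in the iPSC lines.
#'
#' @param maxBaseline Maximum allowed baseline count (inclusive).
#' @param minLine Minimum required line count (inclusive).
#' @param aggregation How line counts are aggregated: every line
#'   (`"all_lines"`), any line (`"any_line"`), the mean across lines
#'   (`"mean"`, default), or at least `k` lines (`"at_least_k"`).
#' @param k Number of lines for `"at_least_k"`.
#'
#' @return A validated `CountFilterSpec`.
#' @seealso [countFilter()]
#' @export
#' @examples
#' CountFilterSpec()
CountFilterSpec <- function(maxBaseline = 50, minLine = 20,
                            aggregation = c("mean", "all_lines", "any_line",
                                            "at_least_k"),
                            k = 1L) {
  new("CountFilterSpec", maxBaseline = as.numeric(maxBaseline),
      minLine = as.numeric(minLine),
      aggregation = match.arg(aggregation), k = as.integer(k))
}

setMethod("show", "CountFilterSpec", function(object) {
  cat("CountFilterSpec: baseline <=", object@maxBaseline, "& line counts >=",
      object@minLine, "under", object@aggregation,
      if (object@aggregation == "at_least_k") paste0("(k=", object@k, ")") else "",
      "\n")
})
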