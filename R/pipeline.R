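## End-to-end mining pipeline and reproducibility manifest.

#' Mine candidate pluripotency genes from counts, annotations and PPI
#'
#' Runs the full mining procedure in order: per-line differential
#' expression, enrichment of the up-regulated set, term selection, the
#' group-1 (enrichment-membership) and group-2 (inducible-gene-driven)
#' screens, the group-3 per-line top-k supplementary ranking, induction of
#' the PPI subnetwork on the merged screened genes, component- and
#' degree-based core extraction, and the final core/supplementary
#' combination.
#'
#' @param object A [PluriCountSet()].
#' @param catalog An [AnnotationCatalog()].
#' @param inducible Character vector of known inducible gene symbols
#'   (default: [inducibleGenesDefault()]).
#' @param ppi A [PPINetwork()].
#' @param lfcThreshold,alpha,significanceOn Passed to [callDE()].
#' @param filterSpec A [CountFilterSpec()] shared by all screens.
#' @param goTopN,pathwayQ,alwaysInclude Passed to [selectTopTerms()].
#' @param minInduciblePerTerm Passed to [selectMainSubdatasets()].
#' @param minUpLines Up-call rule shared by the screens.
#' @param topK Per-line supplementary ranking depth.
#' @param minComponent,minDegree Passed to [filterComponents()] /
#'   [coreGenes()].
#' @param verbose Emit per-stage set sizes via [message()].
#' @return A list with every intermediate: `de`, `enrichment`,
#'   `selectedTerms`, `subdatasets`, `group1`, `group2`, `group3`,
#'   `comparison`, `network`, `components`, `core`, `candidates`.
#' @seealso [runPipeline()] for the file-based, manifest-writing driver.
#' @export
mineCandidates <- function(object, catalog, ppi,
                           inducible = inducibleGenesDefault(),
                           lfcThreshold = 1, alpha = 0.05,
                           significanceOn = c("q", "p"),
                           filterSpec = CountFilterSpec(),
                           goTopN = 20, pathwayQ = 0.05,
                           alwaysInclude = character(),
                           minInduciblePerTerm = c(GO = 3, KEGG = 2),
                           minUpLines = 1L, topK = 30L,
                           minComponent = 6L, minDegree = 4L,
                           verbose = TRUE) {
  significanceOn <- match.arg(significanceOn)
  say <- function(...) if (verbose) message("[pluriMine] ", ...)
  universe <- rownames(countsMatrix(object))

  de <- callDE(object, lfcThreshold, alpha, significanceOn)
  up <- upregulatedGenes(de, minUpLines)
  say("de: ", nrow(de), " gene-line tests, ", length(up),
      " genes up in >= ", minUpLines, " line(s)")

  enrichment <- enrich(up, catalog, universe)
  selectedTerms <- selectTopTerms(enrichment, goTopN, pathwayQ, alwaysInclude)
  say("enrich: ", nrow(enrichment), " terms tested, ",
      nrow(selectedTerms), " selected")

  g1 <- group1Screen(de, selectedTerms, catalog, object, filterSpec,
                     minUpLines)
  subdatasets <- selectMainSubdatasets(inducible, catalog, universe,
                                       minInduciblePerTerm)
  g2 <- group2Screen(de, subdatasets, catalog, object, filterSpec,
                     minUpLines)
  g3 <- group3Supplementary(de, object, filterSpec, topK, minUpLines)
  cmp <- compareGroups(g1, g2)
  say("screens: |group1|=", length(g1), " |group2|=", length(g2),
      " jaccard=", signif(cmp$jaccard %||% NA, 3),
      " |supplementary|=", length(g3))

  screened <- union(screenGenes(g1), screenGenes(g2))
  network <- inducedNetwork(screened, ppi)
  components <- filterComponents(network, minComponent)
  core <- coreGenes(components, minDegree)
  say("network: ", numNodes(network), " nodes, ", numEdges(network),
      " edges; ", length(unique(components$component_id)),
      " component(s) >= ", minComponent, "; |core|=", length(core))

  candidates <- combineCandidates(core, screenGenes(g3), components, de,
                                  groups = list(group1 = g1, group2 = g2,
                                                group3 = g3))
  say("final: ", nrow(candidates), " candidate genes (",
      sum(candidates$source == "both"), " shared core/supplementary)")

  list(de = de, enrichment = enrichment, selectedTerms = selectedTerms,
       subdatasets = subdatasets, group1 = g1, group2 = g2, group3 = g3,
       comparison = cmp, network = network, components = components,
       core = core, candidates = candidates)
}

.writeTable <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the pipeline against files (or a seeded simulation) with a manifest
#'
#' File-based driver around [mineCandidates()]. Either simulates a study
#' (`simulate = TRUE`, controlled entirely by `seed` and `simConfig`) or
#' reads a count matrix, roles sidecar, GMT directory, inducible list and
#' PPI edge table from disk. Writes every stage result as TSV into `outDir`
#' together with `manifest.json` (package version, timestamp, parameters,
#' master seed, input digests, outputs with row counts) sufficient to re-run
#' the analysis bit-identically. On failure, files created by the failing
#' run are removed.
#'
#' @param outDir Output directory (created if needed).
#' @param simulate Simulate inputs instead of reading files.
#' @param seed Master seed used for simulation.
#' @param simConfig Optional [SimConfig()]; its seed is overridden by
#'   `seed`.
#' @param countsPath,rolesPath,gmtDir,induciblePath,ppiPath Input files used
#'   when `simulate = FALSE` (`induciblePath = NULL` falls back to the
#'   packaged literature list).
#' @param minScore Score threshold applied when reading PPI edges.
#' @param ... Further arguments passed to [mineCandidates()].
#' @return Invisibly, the [mineCandidates()] result list plus `manifest`.
#' @export
runPipeline <- function(outDir, simulate = TRUE, seed = 1L,
                        simConfig = NULL,
                        countsPath = NULL, rolesPath = NULL, gmtDir = NULL,
                        induciblePath = NULL, ppiPath = NULL,
                        minScore = 400, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on.exit({
    ## remove partial outputs if we die before the manifest is written
    if (!file.exists(file.path(outDir, "manifest.json")))
      unlink(written)
  }, add = TRUE)

  inputs <- list()
  if (simulate) {
    config <- simConfig %||% SimConfig()
    config@seed <- as.integer(seed)
    validObject(config)
    study <- simulateStudy(config)
    object <- study$counts; catalog <- study$catalog; ppi <- study$ppi
    inducible <- inducibleGenes(study$truth)
    written <- c(written,
      writeCountMatrix(object, file.path(outDir, "counts.tsv"),
                       file.path(outDir, "roles.tsv")),
      writeGMT(catalog, file.path(outDir, "gmt")),
      writePPIEdges(ppi, file.path(outDir, "ppi_edges.tsv")),
      writeSimTruth(study$truth, file.path(outDir, "sim_truth.json")))
    inputs$simulation <- list(seed = seed,
                              seed_offsets = as.list(.seedOffsets))
  } else {
    for (p in c(countsPath, rolesPath, ppiPath))
      if (!file.exists(p)) .stopf("input not found: %s", p)
    if (!dir.exists(gmtDir)) .stopf("GMT directory not found: %s", gmtDir)
    object <- readCountMatrix(countsPath, rolesPath)
    catalog <- readAnnotationDir(gmtDir)
    ppi <- readPPIEdges(ppiPath, minScore)
    inducible <- if (is.null(induciblePath)) inducibleGenesDefault()
                 else readGeneList(induciblePath)
    paths <- c(counts = countsPath, roles = rolesPath, ppi = ppiPath,
               inducible = induciblePath %||% system.file(
                 "extdata", "inducible_default.txt", package = "pluriMine"))
    inputs$files <- as.list(paths)
    inputs$digests <- as.list(tools::md5sum(unname(paths)))
  }

  res <- mineCandidates(object, catalog, ppi, inducible = inducible, ...)

  outFiles <- c(
    de = .writeTable(res$de, file.path(outDir, "de.tsv")),
    enrichment = .writeTable(res$enrichment,
                             file.path(outDir, "enrichment.tsv")),
    selected_terms = .writeTable(res$selectedTerms,
                                 file.path(outDir, "selected_terms.tsv")),
    subdatasets = .writeTable(res$subdatasets,
                              file.path(outDir, "subdatasets.tsv")),
    group1 = .writeTable(screenProvenance(res$group1),
                         file.path(outDir, "group1.tsv")),
    group2 = .writeTable(screenProvenance(res$group2),
                         file.path(outDir, "group2.tsv")),
    group3 = .writeTable(screenProvenance(res$group3),
                         file.path(outDir, "group3_supplementary.tsv")),
    components = .writeTable(res$components,
                             file.path(outDir, "components.tsv")),
    candidates = .writeTable(res$candidates,
                             file.path(outDir, "candidates.tsv")))
  written <- c(written, outFiles)

  dots <- list(...)
  manifest <- list(
    tool = "pluriMine",
    version = as.character(utils::packageVersion("pluriMine")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    simulate = simulate,
    master_seed = if (simulate) seed else NULL,
    parameters = dots[vapply(dots, function(x)
      is.atomic(x) && length(x) < 50L, logical(1))],
    inputs = inputs,
    outputs = lapply(as.list(outFiles), function(p)
      list(path = basename(p),
           rows = length(readLines(p)) - 1L)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  res$manifest <- manifest
  invisible(res)
}
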