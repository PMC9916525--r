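## Readers and writers for every external format the pipeline touches.
## All files are UTF-8, tab-delimited, with header rows.

#' Read a gene-by-sample count matrix with its sample-role sidecar
#'
#' The count TSV has a `gene_id` first column and one column per sample; the
#' sidecar TSV has columns `sample_id` and `role` (`baseline` or `line`).
#' Counts must be non-negative integers and gene ids unique (after
#' uppercasing); violations are format errors naming the offender.
#'
#' @param path Path to the count TSV.
#' @param rolesPath Path to the roles sidecar TSV.
#' @return A [PluriCountSet()].
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, rolesPath) {
  if (!file.exists(path)) .stopf("count matrix file not found: %s", path)
  if (!file.exists(rolesPath)) .stopf("roles file not found: %s", rolesPath)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1L] != "gene_id")
    .stopf("first column of %s must be 'gene_id'", path)
  ids <- canonicalSymbols(tab$gene_id)
  if (anyDuplicated(ids))
    .stopf("duplicated gene id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)))
    .stopf("counts must be numeric and complete in %s", path)
  if (any(m < 0)) {
    bad <- ids[which(rowSums(m < 0) > 0)[1L]]
    .stopf("negative count found (gene %s)", bad)
  }
  if (any(m != floor(m))) {
    bad <- ids[which(rowSums(m != floor(m)) > 0)[1L]]
    .stopf("non-integer count found (gene %s)", bad)
  }
  rownames(m) <- ids
  roles <- utils::read.delim(rolesPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "role") %in% colnames(roles)))
    .stopf("roles sidecar must have columns sample_id and role")
  missing <- setdiff(colnames(m), roles$sample_id)
  if (length(missing))
    .stopf("missing role for sample(s): %s", paste(missing, collapse = ", "))
  PluriCountSet(m, stats::setNames(roles$role, roles$sample_id))
}

#' Write a count matrix and its sample-role sidecar
#'
#' @param object A [PluriCountSet()].
#' @param path Output count TSV path.
#' @param rolesPath Output roles sidecar TSV path.
#' @return Invisibly, `c(path, rolesPath)`.
#' @export
writeCountMatrix <- function(object, path, rolesPath) {
  m <- countsMatrix(object)
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  roles <- data.frame(sample_id = colnames(m), role = unname(sampleRoles(object)))
  utils::write.table(roles, rolesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, rolesPath))
}

#' Read one annotation level from a GMT file
#'
#' Standard GMT: one term per line, `term_id TAB description TAB gene...`.
#' Lines with fewer than three fields are format errors (reported with their
#' line number); empty gene fields are dropped; genes repeated within a line
#' are stored once; duplicate term ids within one file are format errors.
#'
#' @param path Path to the GMT file.
#' @param level The annotation level this file encodes (one of
#'   [annotationLevelNames()]).
#' @return An [AnnotationCatalog()] fragment holding this level.
#' @seealso [writeGMT()], [readAnnotationDir()]
#' @export
readGMT <- function(path, level) {
  level <- match.arg(level, .kAnnotationLevels)
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    .stopf("GMT line %d of %s has fewer than 3 tab-separated fields",
           short[1L], path)
  termId <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(termId))
    .stopf("duplicate term id(s) in %s: %s", path,
           paste(unique(termId[duplicated(termId)]), collapse = ", "))
  termName <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) {
    g <- canonicalSymbols(f[-(1:2)])
    unique(g[nzchar(g)])
  })
  empty <- lengths(genes) == 0L
  if (any(empty))
    .stopf("term %s in %s has no genes", termId[empty][1L], path)
  AnnotationCatalog(rep(level, length(termId)), termId, termName, genes)
}

#' Write an annotation catalog as one GMT file per level
#'
#' @param catalog An [AnnotationCatalog()].
#' @param dir Output directory; files are named `<level>.gmt`.
#' @return Invisibly, the written file paths.
#' @export
writeGMT <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (lv in catalogLevels(catalog)) {
    keep <- catalog@level == lv
    lines <- mapply(function(id, nm, g) paste(c(id, nm, g), collapse = "\t"),
                    catalog@termId[keep], catalog@termName[keep],
                    as.list(catalog@genes[keep]))
    p <- file.path(dir, paste0(lv, ".gmt"))
    writeLines(unname(lines), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a directory of per-level GMT files into one catalog
#'
#' Expects files named `<level>.gmt` for the levels present.
#'
#' @param dir Directory containing the GMT files.
#' @return An [AnnotationCatalog()] over all levels found.
#' @export
readAnnotationDir <- function(dir) {
  if (!dir.exists(dir)) .stopf("annotation directory not found: %s", dir)
  found <- .kAnnotationLevels[file.exists(file.path(dir,
    paste0(.kAnnotationLevels, ".gmt")))]
  if (!length(found)) .stopf("no <level>.gmt files found in %s", dir)
  frags <- lapply(found, function(lv) readGMT(file.path(dir,
    paste0(lv, ".gmt")), lv))
  AnnotationCatalog(
    level = unlist(lapply(frags, function(f) f@level)),
    termId = unlist(lapply(frags, function(f) f@termId)),
    termName = unlist(lapply(frags, function(f) f@termName)),
    genes = do.call(c, lapply(frags, function(f) as.list(f@genes))))
}

#' Read a STRING-style PPI edge table
#'
#' Expects the detailed-format dialect: a header `protein1 protein2
#' combined_score` (tab- or space-delimited), scores in \[0, 1000\]. Edges
#' below `minScore` are dropped (the comparison is inclusive, `>=`); pairs
#' are canonicalized; self-loops are dropped with a warning.
#'
#' @param path Path to the edge table.
#' @param minScore Minimum combined score kept (default 400, the STRING
#'   medium-confidence convention).
#' @return A [PPINetwork()].
#' @seealso [writePPIEdges()]
#' @export
readPPIEdges <- function(path, minScore = 400) {
  if (!file.exists(path)) .stopf("PPI edge file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% colnames(tab)))
    .stopf("PPI table must have header: %s", paste(need, collapse = " "))
  score <- suppressWarnings(as.numeric(tab$combined_score))
  if (any(is.na(score)))
    .stopf("non-numeric combined_score at line %d",
           which(is.na(score))[1L] + 1L)
  tab$combined_score <- score
  tab <- tab[score >= minScore, , drop = FALSE]
  PPINetwork(tab)
}

#' Write a PPI network as a STRING-style edge table
#'
#' @param network A [PPINetwork()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writePPIEdges <- function(network, path) {
  utils::write.table(ppiEdges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' Symbols are uppercased and de-duplicated preserving first occurrence;
#' blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique uppercased symbols.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) .stopf("gene list file not found: %s", path)
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(canonicalSymbols(x))
}

#' The default literature list of known inducible (reprogramming) genes
#'
#' The four Yamanaka factors plus published substitutes for each: L-Myc,
#' N-Myc and Glis1 for c-Myc; Klf1/2/5, Esrrb and Bmp4 for Klf4; Rcor2,
#' GMNN, TH2A, TH2B, Obox1, Sox1 and Sox3 for Sox2; Nr5a1, Nr5a2,
#' E-cadherin, TCL1A, Brn4 and Tet1 for Oct4 — 25 symbols in all, shipped as
#' `inst/extdata/inducible_default.txt`.
#'
#' @return Character vector of 25 uppercased gene symbols.
#' @export
#' @examples
#' length(inducibleGenesDefault())
inducibleGenesDefault <- function() {
  readGeneList(system.file("extdata", "inducible_default.txt",
                           package = "pluriMine", mustWork = TRUE))
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth A [SimTruth-class].
#' @param path JSON path.
#' @return `writeSimTruth` invisibly returns `path`; `readSimTruth` returns
#'   the reconstructed [SimTruth-class].
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(list(
    planted_up = truth@plantedUp, planted_down = truth@plantedDown,
    null_genes = truth@nullGenes, planted_core = truth@plantedCore,
    enriched_terms = truth@enrichedTerms, inducible = truth@inducible),
    path, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(v) if (length(v)) as.character(v) else character()
  new("SimTruth", plantedUp = asChr(x$planted_up),
      plantedDown = asChr(x$planted_down), nullGenes = asChr(x$null_genes),
      plantedCore = asChr(x$planted_core),
      enrichedTerms = asChr(x$enriched_terms),
      inducible = asChr(x$inducible))
}
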