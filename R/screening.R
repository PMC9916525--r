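## The three screening groups: enrichment-membership (group 1),
## inducible-gene-driven annotation subdatasets (group 2), and the
## per-line top-k supplementary ranking (group 3), all sharing the
## baseline/line count filter.

.lineCountAggregate <- function(lineCounts, spec) {
  switch(spec@aggregation,
    all_lines = apply(lineCounts >= spec@minLine, 1L, all),
    any_line = apply(lineCounts >= spec@minLine, 1L, any),
    mean = rowMeans(lineCounts) >= spec@minLine,
    at_least_k = rowSums(lineCounts >= spec@minLine) >= spec@k)
}

#' Apply the baseline/line count filter to a gene set
#'
#' A gene is retained iff its baseline count is at most `maxBaseline`
#' (inclusive) and its line counts meet `minLine` (inclusive) under the
#' aggregation rule of `spec`. With several baseline columns their mean
#' count is compared. Deterministic and idempotent.
#'
#' @param genes Character vector of gene ids; must be present in `object`.
#' @param object A [PluriCountSet()].
#' @param spec A [CountFilterSpec()].
#' @return Sorted character vector of retained genes.
#' @export
#' @examples
#' m <- matrix(c(10L, 60L, 100L, 100L), 2,
#'             dimnames = list(c("A", "B"), c("F", "L1")))
#' pcs <- PluriCountSet(m, c(F = "baseline", L1 = "line"))
#' countFilter(c("A", "B"), pcs, CountFilterSpec())
countFilter <- function(genes, object, spec = CountFilterSpec()) {
  stopifnot(is(object, "PluriCountSet"), is(spec, "CountFilterSpec"))
  validObject(spec)
  genes <- unique(canonicalSymbols(genes))
  m <- countsMatrix(object)
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown))
    .stopf("unknown gene(s): %s", paste(utils::head(unknown, 5L),
                                        collapse = ", "))
  if (!length(genes)) return(character())
  if (spec@aggregation == "at_least_k" && spec@k > length(lineSamples(object)))
    .stopf("k = %d exceeds the number of lines (%d)", spec@k,
           length(lineSamples(object)))
  bl <- baselineSamples(object)
  base <- rowMeans(m[genes, bl, drop = FALSE])
  lineOk <- .lineCountAggregate(m[genes, lineSamples(object), drop = FALSE],
                                spec)
  sort(genes[base <= spec@maxBaseline & lineOk])
}

.specAsList <- function(spec) {
  list(maxBaseline = spec@maxBaseline, minLine = spec@minLine,
       aggregation = spec@aggregation, k = spec@k)
}

## Shared provenance builder: per-gene qualifying lines, counts, lfc.
.screenProvenance <- function(genes, de, object, termsByGene = NULL) {
  m <- countsMatrix(object)
  upLines <- .upLinesByGene(de)
  sub <- de[de$gene_id %in% genes & de$direction == "up", , drop = FALSE]
  maxFc <- vapply(genes, function(g) {
    v <- sub$log2fc[sub$gene_id == g]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  S4Vectors::DataFrame(
    gene_id = genes,
    up_lines = vapply(genes, function(g)
      paste(sort(upLines[[g]] %||% character()), collapse = ","),
      "", USE.NAMES = FALSE),
    n_up_lines = vapply(genes, function(g)
      length(upLines[[g]] %||% character()), integer(1), USE.NAMES = FALSE),
    baseline_count = unname(rowMeans(m[genes, baselineSamples(object),
                                       drop = FALSE])),
    mean_line_count = unname(rowMeans(m[genes, lineSamples(object),
                                        drop = FALSE])),
    max_log2fc = unname(maxFc),
    terms = if (is.null(termsByGene)) rep(NA_character_, length(genes)) else
      vapply(genes, function(g)
        paste(sort(termsByGene[[g]] %||% character()), collapse = ","),
        "", USE.NAMES = FALSE))
}

## selected terms (DataFrame with term_id) -> member map restricted to terms
.termsByGene <- function(termIds, catalog) {
  sets <- termGenes(catalog)
  sets <- sets[intersect(termIds, names(sets))]
  inv <- list()
  for (tid in names(sets))
    for (g in sets[[tid]]) inv[[g]] <- c(inv[[g]], tid)
  inv
}

#' Group 1: enrichment-membership screen
#'
#' Genes that (a) belong to at least one selected enriched term, (b) are
#' called up-regulated in at least `minUpLines` lines, and (c) pass the
#' count filter. Provenance records the qualifying terms and lines.
#'
#' @param de A `DETable` from [callDE()].
#' @param selectedTerms A term table from [selectTopTerms()] (needs a
#'   `term_id` column).
#' @param catalog The [AnnotationCatalog()].
#' @param object The [PluriCountSet()].
#' @param spec A [CountFilterSpec()].
#' @param minUpLines Minimum number of lines with an `up` call.
#' @return A [ScreenSet] labeled `"group1"`.
#' @export
group1Screen <- function(de, selectedTerms, catalog, object,
                         spec = CountFilterSpec(), minUpLines = 1L) {
  stopifnot(is(de, "DETable"), is(catalog, "AnnotationCatalog"))
  params <- c(.specAsList(spec), list(minUpLines = minUpLines))
  if (!nrow(selectedTerms)) {
    .warnf("no selected terms; group 1 is empty")
    return(.ScreenSet("group1", character(),
                      .screenProvenance(character(), de, object), params))
  }
  byGene <- .termsByGene(selectedTerms$term_id, catalog)
  members <- intersect(names(byGene), rownames(countsMatrix(object)))
  up <- upregulatedGenes(de, minUpLines)
  keep <- countFilter(intersect(members, up), object, spec)
  .ScreenSet("group1", keep,
             .screenProvenance(keep, de, object, byGene), params)
}

#' Select the main annotation subdatasets containing the inducible genes
#'
#' For each annotation level, keeps the terms containing at least
#' `minInduciblePerTerm` detected inducible genes (detected = present in the
#' supplied universe), ranked by inducible-gene coverage (descending, ties
#' by term id). The default threshold is 3 at GO levels and 2 at KEGG levels
#' (KEGG strata are coarser and fewer).
#'
#' @param inducible Character vector of known-inducible gene symbols.
#' @param catalog An [AnnotationCatalog()].
#' @param universe Detected genes (typically `rownames` of the count set).
#' @param minInduciblePerTerm Either a single number or a named vector with
#'   entries `GO` and `KEGG`.
#' @return A [S4Vectors::DataFrame] of selected terms with columns `level`,
#'   `term_id`, `n_inducible`, `inducible_hits`.
#' @export
selectMainSubdatasets <- function(inducible, catalog, universe,
                                  minInduciblePerTerm = c(GO = 3, KEGG = 2)) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  detected <- intersect(unique(canonicalSymbols(inducible)),
                        unique(canonicalSymbols(universe)))
  empty <- S4Vectors::DataFrame(level = character(), term_id = character(),
                                n_inducible = integer(),
                                inducible_hits = character())
  if (!length(detected)) {
    .warnf("no inducible gene detected in the universe")
    return(empty)
  }
  thr <- function(lv) {
    if (length(minInduciblePerTerm) == 1L && is.null(names(minInduciblePerTerm)))
      return(minInduciblePerTerm)
    if (startsWith(lv, "GO")) minInduciblePerTerm[["GO"]]
    else minInduciblePerTerm[["KEGG"]]
  }
  out <- empty
  for (lv in catalogLevels(catalog)) {
    sets <- termGenes(catalog, lv)
    hits <- lapply(sets, function(g) intersect(detected, g))
    nHit <- lengths(hits)
    keep <- which(nHit >= thr(lv))
    if (!length(keep)) next
    keep <- keep[order(-nHit[keep], names(sets)[keep])]
    out <- rbind(out, S4Vectors::DataFrame(
      level = lv, term_id = names(sets)[keep],
      n_inducible = unname(nHit[keep]),
      inducible_hits = vapply(hits[keep], function(h)
        paste(sort(h), collapse = ","), "")))
  }
  rownames(out) <- NULL
  out
}

#' Group 2: inducible-gene-driven subdataset screen
#'
#' Genes belonging to at least one selected subdataset term, called up in at
#' least `minUpLines` lines, and passing the count filter.
#'
#' @param subdatasets Output of [selectMainSubdatasets()].
#' @inheritParams group1Screen
#' @return A [ScreenSet] labeled `"group2"`.
#' @export
group2Screen <- function(de, subdatasets, catalog, object,
                         spec = CountFilterSpec(), minUpLines = 1L) {
  stopifnot(is(de, "DETable"), is(catalog, "AnnotationCatalog"))
  params <- c(.specAsList(spec), list(minUpLines = minUpLines))
  if (!nrow(subdatasets)) {
    .warnf("no selected subdatasets; group 2 is empty")
    return(.ScreenSet("group2", character(),
                      .screenProvenance(character(), de, object), params))
  }
  byGene <- .termsByGene(subdatasets$term_id, catalog)
  members <- intersect(names(byGene), rownames(countsMatrix(object)))
  up <- upregulatedGenes(de, minUpLines)
  keep <- countFilter(intersect(members, up), object, spec)
  .ScreenSet("group2", keep,
             .screenProvenance(keep, de, object, byGene), params)
}

#' Group 3: per-line top-k supplementary ranking
#'
#' Starting from all up-regulated genes passing the count filter (no
#' annotation screening), each line ranks the genes it called up by its own
#' raw count, descending (ties broken by lexicographic gene id), and the top
#' `topK` per line are unioned into the supplementary set.
#'
#' @inheritParams group1Screen
#' @param topK Genes kept per line (default 30).
#' @return A [ScreenSet] labeled `"group3_supplementary"`; its provenance
#'   lists, per gene, the lines whose top-`topK` it entered.
#' @export
group3Supplementary <- function(de, object, spec = CountFilterSpec(),
                                topK = 30L, minUpLines = 1L) {
  stopifnot(is(de, "DETable"))
  params <- c(.specAsList(spec), list(topK = topK, minUpLines = minUpLines))
  qualifying <- countFilter(upregulatedGenes(de, minUpLines), object, spec)
  m <- countsMatrix(object)
  chosen <- list()
  for (s in lineSamples(object)) {
    upHere <- unique(de$gene_id[de$line_id == s & de$direction == "up"])
    cand <- intersect(qualifying, upHere)
    if (!length(cand)) next
    counts <- m[cand, s]
    o <- order(-counts, cand)
    top <- cand[o][seq_len(min(topK, length(cand)))]
    for (g in top) chosen[[g]] <- c(chosen[[g]], s)
  }
  genes <- sort(names(chosen))
  prov <- .screenProvenance(genes, de, object)
  prov$top_lines <- vapply(genes, function(g)
    paste(sort(chosen[[g]]), collapse = ","), "", USE.NAMES = FALSE)
  .ScreenSet("group3_supplementary", genes, prov, params)
}

#' Overlap report for two screening groups
#'
#' Reports set sizes, the intersection, and the Jaccard index. The decision
#' to merge the groups stays with the caller.
#'
#' @param g1,g2 Two [ScreenSet] objects.
#' @return A list with `size1`, `size2`, `intersection`, `union`,
#'   `intersection_size`, `jaccard`.
#' @export
compareGroups <- function(g1, g2) {
  stopifnot(is(g1, "ScreenSet"), is(g2, "ScreenSet"))
  a <- screenGenes(g1); b <- screenGenes(g2)
  i <- intersect(a, b); u <- union(a, b)
  list(size1 = length(a), size2 = length(b),
       intersection = sort(i), union = sort(u),
       intersection_size = length(i),
       jaccard = if (length(u)) length(i) / length(u) else NA_real_)
}
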