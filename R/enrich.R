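## Hypergeometric gene-set enrichment and term selection.

#' Hypergeometric gene-set enrichment over a catalog
#'
#' For every catalog term, computes the upper-tail hypergeometric p-value of
#' the overlap between the query and the term within the universe:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the universe size,
#' `K` the term size within the universe, `n` the query size and `k` the
#' observed overlap. BH adjustment is applied within each annotation level
#' (levels are separate hypothesis families). Terms disjoint from the
#' universe are skipped with a warning.
#'
#' @param query Character vector of query genes; must lie in `universe`.
#' @param catalog An [AnnotationCatalog()].
#' @param universe Character vector defining the gene universe (typically
#'   the genes detected in the count matrix).
#' @return An `EnrichmentResult` (a [S4Vectors::DataFrame]) with columns
#'   `level`, `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`.
#' @seealso [selectTopTerms()]
#' @export
enrich <- function(query, catalog, universe) {
  stopifnot(is(catalog, "AnnotationCatalog"))
  universe <- unique(canonicalSymbols(universe))
  if (!length(universe)) .stopf("universe must not be empty")
  query <- unique(canonicalSymbols(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    .stopf("query gene(s) outside the universe: %s",
           paste(utils::head(outside, 3L), collapse = ", "))
  N <- length(universe)
  n <- length(query)

  K <- vapply(as.list(catalog@genes), function(g)
    sum(g %in% universe), integer(1))
  k <- vapply(as.list(catalog@genes), function(g)
    sum(query %in% g), integer(1))
  skip <- K == 0L
  if (any(skip))
    .warnf("skipping %d term(s) disjoint from the universe", sum(skip))

  lv <- catalog@level[!skip]
  p <- stats::phyper(k[!skip] - 1L, K[!skip], N - K[!skip], n,
                     lower.tail = FALSE)
  q <- unsplit(lapply(split(p, lv), bhAdjust), lv)
  out <- S4Vectors::DataFrame(
    level = lv, term_id = catalog@termId[!skip],
    term_name = catalog@termName[!skip],
    k = k[!skip], K = K[!skip], n = n, N = N, p = p, q = q)
  out <- out[order(out$level, out$p, -out$k, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  new("EnrichmentResult", out)
}

#' Select enriched terms for the group-1 screen
#'
#' GO levels contribute their top `goTopN` terms each, ranked by ascending
#' p (ties broken by larger overlap, then lexicographic term id). KEGG
#' levels contribute every term with `q < pathwayQ`, unioned with an
#' `alwaysInclude` list of forced terms (e.g. stemness pathways selected on
#' biological grounds regardless of their q-value). Forced terms absent from
#' the enrichment result are skipped with a warning.
#'
#' @param enrichment An `EnrichmentResult` from [enrich()].
#' @param goTopN Number of top terms kept per GO level (default 20).
#' @param pathwayQ q-value threshold for KEGG levels (default 0.05).
#' @param alwaysInclude Character vector of term ids to force-include.
#' @return A [S4Vectors::DataFrame] of selected terms with a `selection`
#'   provenance flag (`top_go`, `q_threshold` or `forced`).
#' @export
selectTopTerms <- function(enrichment, goTopN = 20, pathwayQ = 0.05,
                           alwaysInclude = character()) {
  stopifnot(is(enrichment, "EnrichmentResult"))
  e <- as(enrichment, "DFrame")
  pick <- list()
  for (lv in intersect(.kGoLevels, unique(e$level))) {
    sub <- e[e$level == lv, , drop = FALSE]
    sub <- sub[order(sub$p, -sub$k, sub$term_id), , drop = FALSE]
    sub <- utils::head(sub, goTopN)
    if (nrow(sub)) { sub$selection <- "top_go"; pick[[lv]] <- sub }
  }
  for (lv in intersect(.kKeggLevels, unique(e$level))) {
    sub <- e[e$level == lv & e$q < pathwayQ, , drop = FALSE]
    if (nrow(sub)) { sub$selection <- "q_threshold"; pick[[lv]] <- sub }
  }
  out <- if (length(pick)) do.call(rbind, unname(pick)) else {
    e0 <- e[integer(0), , drop = FALSE]; e0$selection <- character(0); e0
  }
  forced <- setdiff(unique(alwaysInclude), out$term_id)
  if (length(forced)) {
    hit <- e[e$term_id %in% forced, , drop = FALSE]
    missing <- setdiff(forced, hit$term_id)
    if (length(missing))
      .warnf("alwaysInclude term(s) not in the enrichment result, skipped: %s",
             paste(missing, collapse = ", "))
    if (nrow(hit)) { hit$selection <- "forced"; out <- rbind(out, hit) }
  }
  out <- out[order(out$level, out$p, -out$k, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
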