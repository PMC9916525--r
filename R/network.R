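## Core-gene extraction from PPI evidence: induced subnetworks, component
## size filtering, within-component degree filtering, and the final
## candidate table.

#' Induce a subnetwork on a query gene set
#'
#' Returns the subgraph on `genes` intersected with the network's nodes,
#' keeping only edges with both endpoints in the query. Queried genes
#' present in the network but left without edges are retained as degree-0
#' nodes; queried genes absent from the network are dropped.
#'
#' @param genes Character vector of query gene symbols.
#' @param ppi A [PPINetwork()].
#' @return A [PPINetwork()] on the surviving nodes.
#' @export
inducedNetwork <- function(genes, ppi) {
  stopifnot(is(ppi, "PPINetwork"))
  genes <- unique(canonicalSymbols(genes))
  if (!length(genes)) {
    .warnf("empty query; returning an empty network")
    return(PPINetwork(data.frame(protein1 = character(),
                                 protein2 = character(),
                                 combined_score = numeric())))
  }
  nodes <- intersect(ppi@nodes, genes)
  e <- ppi@edges
  keep <- e$protein1 %in% nodes & e$protein2 %in% nodes
  PPINetwork(e[keep, , drop = FALSE], nodes = nodes)
}

#' Connected components passing a minimum-size filter
#'
#' Finds the connected components of the network and keeps those with at
#' least `minSize` nodes (inclusive). Components get stable ids `C1, C2,
#' ...` ordered by size (descending), ties broken by smallest member id.
#' Each node's degree within the induced network is reported.
#'
#' @param network A [PPINetwork()] (typically from [inducedNetwork()]).
#' @param minSize Minimum component size kept (default 6).
#' @return A [S4Vectors::DataFrame] with columns `component_id`, `gene_id`,
#'   `degree`, ordered by component then gene id.
#' @seealso [coreGenes()]
#' @importFrom igraph components degree
#' @export
filterComponents <- function(network, minSize = 6L) {
  stopifnot(is(network, "PPINetwork"))
  empty <- S4Vectors::DataFrame(component_id = character(),
                                gene_id = character(), degree = integer())
  if (!numNodes(network)) return(empty)
  g <- .asIgraph(network)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  keep <- which(comp$csize >= minSize)
  if (!length(keep)) return(empty)
  memberGenes <- lapply(keep, function(ci) sort(names(comp$membership)
                                                [comp$membership == ci]))
  o <- order(-comp$csize[keep], vapply(memberGenes, `[`, "", 1L))
  memberGenes <- memberGenes[o]
  out <- do.call(rbind, lapply(seq_along(memberGenes), function(i)
    S4Vectors::DataFrame(component_id = sprintf("C%d", i),
                         gene_id = memberGenes[[i]],
                         degree = unname(deg[memberGenes[[i]]]))))
  rownames(out) <- NULL
  out
}

#' Core genes: high-degree nodes of the retained components
#'
#' Nodes whose degree within their retained component is at least
#' `minDegree`. The default 4 encodes "more than three connections". Degrees
#' are computed within the induced network (components are disjoint, so the
#' component-internal and induced-network degrees coincide).
#'
#' @param components Component table from [filterComponents()].
#' @param minDegree Minimum within-component degree (default 4).
#' @return Sorted character vector of core gene ids.
#' @export
coreGenes <- function(components, minDegree = 4L) {
  sort(unique(components$gene_id[components$degree >= minDegree]))
}

#' Combine core and supplementary genes into the final candidate table
#'
#' Takes the union of the two sets, labels each gene `core`,
#' `supplementary` or `both`, and attaches network evidence (component id
#' and degree, where the gene was in the analyzed network) and expression
#' evidence (per-line up calls and mean log2 fold change, where a `DETable`
#' is supplied). The union size always satisfies
#' `|core| + |supplementary| - |intersection|`. Rows are ordered with
#' `both` first, then by degree (descending, missing last), then gene id.
#'
#' @param core Character vector of core genes (see [coreGenes()]).
#' @param supplementary Character vector of supplementary genes (e.g.
#'   [screenGenes()] of the group-3 [ScreenSet]).
#' @param components Optional component table from [filterComponents()].
#' @param de Optional `DETable` for expression evidence.
#' @param groups Optional named list of [ScreenSet]s; adds a
#'   `qualifying_groups` provenance column.
#' @return A `CandidateTable` (a [S4Vectors::DataFrame]) with columns
#'   `gene_id`, `source`, `component_id`, `degree`, and the optional
#'   evidence columns.
#' @export
#' @examples
#' ct <- combineCandidates(c("A", "B"), c("B", "C"))
#' nrow(ct)  # 3
combineCandidates <- function(core, supplementary, components = NULL,
                              de = NULL, groups = NULL) {
  core <- unique(canonicalSymbols(core))
  supplementary <- unique(canonicalSymbols(supplementary))
  genes <- union(core, supplementary)
  source <- ifelse(genes %in% core & genes %in% supplementary, "both",
                   ifelse(genes %in% core, "core", "supplementary"))
  compId <- rep(NA_character_, length(genes))
  degree <- rep(NA_integer_, length(genes))
  if (!is.null(components) && nrow(components)) {
    i <- match(genes, components$gene_id)
    compId <- as.character(components$component_id[i])
    degree <- as.integer(components$degree[i])
  }
  out <- S4Vectors::DataFrame(gene_id = genes, source = source,
                              component_id = compId, degree = degree)
  if (!is.null(de)) {
    upLines <- .upLinesByGene(de)
    out$n_up_lines <- vapply(genes, function(g)
      length(upLines[[g]] %||% character()), integer(1))
    out$mean_log2fc <- vapply(genes, function(g) {
      v <- de$log2fc[de$gene_id == g]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  }
  if (!is.null(groups)) {
    out$qualifying_groups <- vapply(genes, function(g)
      paste(names(groups)[vapply(groups, function(s)
        g %in% screenGenes(s), logical(1))], collapse = ","), "")
  }
  srcRank <- ifelse(out$source == "both", 0L, 1L)
  degKey <- ifelse(is.na(out$degree), -1L, out$degree)
  out <- out[order(srcRank, -degKey, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  new("CandidateTable", out)
}
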