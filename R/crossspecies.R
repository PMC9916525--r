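## Ortholog-mapped cross-species set comparison (the multi-species Venn).

#' Read an ortholog-symbol mapping table
#'
#' TSV with columns `source_symbol`, `target_species`, `target_symbol`.
#' Duplicate (source, species) pairs after case normalization are format
#' errors.
#'
#' @param path Path to the TSV.
#' @return A data frame with canonicalized symbols.
#' @export
readOrthologMap <- function(path) {
  if (!file.exists(path)) .stopf("ortholog map not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_symbol", "target_species", "target_symbol")
  if (!all(need %in% colnames(tab)))
    .stopf("ortholog map must have columns: %s", paste(need, collapse = ", "))
  tab$source_symbol <- canonicalSymbols(tab$source_symbol)
  tab$target_symbol <- canonicalSymbols(tab$target_symbol)
  key <- paste(tab$source_symbol, tab$target_species)
  if (anyDuplicated(key))
    .stopf("duplicate (source, species) pair(s): %s",
           key[duplicated(key)][1L])
  tab
}

#' Map gene symbols to another species through an ortholog table
#'
#' Translates each input symbol to its ortholog in `species`. Unmapped
#' symbols are reported, not silently dropped; several sources collapsing to
#' one target are flagged. With `map = NULL`, uppercase symbol identity is
#' used as an approximate fallback (logged as such).
#'
#' @param genes Character vector of source symbols.
#' @param map Ortholog table as from [readOrthologMap()], or `NULL`.
#' @param species Target species to map into.
#' @return A list: `mapped` (unique target symbols), `unmapped` (source
#'   symbols without a translation), `collisions` (target symbols hit by
#'   more than one source).
#' @export
mapSymbols <- function(genes, map, species) {
  genes <- unique(canonicalSymbols(genes))
  if (is.null(map)) {
    message("no ortholog map supplied; using uppercase symbol identity ",
            "(approximate)")
    return(list(mapped = sort(genes), unmapped = character(),
                collisions = character()))
  }
  if (!species %in% map$target_species)
    .stopf("unknown species '%s'; map covers: %s", species,
           paste(unique(map$target_species), collapse = ", "))
  sub <- map[map$target_species == species, , drop = FALSE]
  i <- match(genes, sub$source_symbol)
  unmapped <- genes[is.na(i)]
  target <- sub$target_symbol[i[!is.na(i)]]
  collisions <- sort(unique(target[duplicated(target)]))
  list(mapped = sort(unique(target)), unmapped = sort(unmapped),
       collisions = collisions)
}

#' Venn region counts for up to four named gene sets
#'
#' Computes the exclusive count of every Venn region (membership pattern)
#' plus all pairwise intersection sizes. Region counts always sum to the
#' size of the union.
#'
#' @param sets Named list of 2 to 4 character vectors.
#' @return A list: `regions` (data frame of membership pattern and exclusive
#'   `count`), `pairwise` (matrix of pairwise intersection sizes),
#'   `union_size`.
#' @export
#' @examples
#' vennCounts(list(a = c("X", "Y"), b = c("Y", "Z")))$regions
vennCounts <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("sets must be named")
  if (length(sets) < 2L || length(sets) > 4L)
    .stopf("between 2 and 4 sets are supported (got %d)", length(sets))
  sets <- lapply(sets, function(s) unique(canonicalSymbols(s)))
  u <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
  memb <- matrix(memb, nrow = length(u),
                 dimnames = list(u, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  colnames(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  key <- apply(memb, 1L, function(r) paste(as.integer(r), collapse = ""))
  pkey <- apply(patterns, 1L, function(r) paste(as.integer(r), collapse = ""))
  counts <- as.integer(table(factor(key, levels = pkey)))
  regions <- data.frame(
    region = apply(patterns, 1L, function(r)
      paste(names(sets)[as.logical(r)], collapse = "&")),
    patterns, count = counts, row.names = NULL, check.names = FALSE)
  pairwise <- outer(seq_along(sets), seq_along(sets),
                    Vectorize(function(i, j)
                      length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pairwise) <- list(names(sets), names(sets))
  list(regions = regions, pairwise = pairwise, union_size = length(u))
}
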