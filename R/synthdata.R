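## Synthetic reprogramming-study generator.
##
## All three generators are pure functions of (config, master seed): child
## seeds are derived by fixed offsets (counts +1, annotations +2, PPI +3,
## inducible list +4) and the global RNG state is restored afterwards.

.seedOffsets <- c(counts = 1L, annotations = 2L, ppi = 3L, inducible = 4L)

.geneIds <- function(n) sprintf("GENE%05d", seq_len(n))

.sampleNames <- function(config) {
  base <- if (config@nBaseline == 1L) "BCFF" else
    sprintf("BCFF_%d", seq_len(config@nBaseline))
  lines <- if (config@nLines == 7L)
    paste0("BCIPSC_", c("A1", "A2", "A3", "A6", "A7", "A23", "B13"))
  else sprintf("BCIPSC_%02d", seq_len(config@nLines))
  list(baseline = base, lines = lines)
}

#' Simulate a reprogramming-study count matrix with planted truth
#'
#' Draws a negative-binomial gene-by-sample count matrix emulating an
#' unreplicated reprogramming study: one (or more) fibroblast baseline
#' column(s) and `nLines` clonal iPSC line columns. Gene base means are
#' log-normal; a planted block of pluripotency genes (low baseline
#' expression) is up-regulated in every line by `upLog2fc`, a planted
#' fibroblast block is down-regulated by `downLog2fc`, and all remaining
#' genes are unchanged. Expected column totals follow the configured library
#' sizes. The same seed always reproduces the same matrix.
#'
#' @param config A [SimConfig()].
#'
#' @return A list with elements `counts` (a [PluriCountSet()]) and `truth`
#'   (a [SimTruth-class] recording planted gene categories, the planted
#'   interaction core, the deterministically named enriched terms, and the
#'   simulated inducible-gene list).
#' @seealso [simulateAnnotations()], [simulatePPI()]
#' @export
#' @examples
#' sim <- simulateCounts(SimConfig(nGenes = 300, nPlantedUp = 20,
#'                                 nPlantedDown = 20, seed = 11))
#' sim$counts
#' sim$truth
simulateCounts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  genes <- .geneIds(config@nGenes)

  out <- withr::with_seed(.childSeed(config@seed, .seedOffsets["counts"]), {
    ## planted category assignment
    perm <- sample(genes)
    up <- sort(perm[seq_len(config@nPlantedUp)])
    down <- sort(perm[config@nPlantedUp + seq_len(config@nPlantedDown)])
    nullg <- sort(setdiff(genes, c(up, down)))

    baseMean <- stats::rlnorm(config@nGenes, config@meanLog, config@sdLog)
    names(baseMean) <- genes
    ## pluripotency genes are near-silent in fibroblasts
    baseMean[up] <- stats::rlnorm(length(up), config@plantedUpMeanLog,
                                  config@plantedUpSdLog)

    lfc <- stats::setNames(numeric(config@nGenes), genes)
    lfc[up] <- config@upLog2fc
    lfc[down] <- config@downLog2fc

    nm <- .sampleNames(config)
    nSamp <- config@nBaseline + config@nLines
    mu <- matrix(0, config@nGenes, nSamp,
                 dimnames = list(genes, c(nm$baseline, nm$lines)))
    ## scale relative to the baseline expression profile so the baseline
    ## column hits its nominal library size in expectation
    scaleBase <- config@libSizeBaseline / sum(baseMean)
    scaleLine <- config@libSizeLine / sum(baseMean)
    for (s in nm$baseline) mu[, s] <- baseMean * scaleBase
    for (s in nm$lines) mu[, s] <- baseMean * 2^lfc * scaleLine

    counts <- matrix(stats::rnbinom(length(mu), size = config@dispersion,
                                    mu = mu),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    core <- up[seq_len(config@ppiCoreSize)]

    ## inducible list: a mix of reactivated (planted-up) factors and factors
    ## that stay silent, as for literature reprogramming genes
    nFromUp <- min(length(up), ceiling(config@nInducible / 2))
    indUp <- sample(up, nFromUp)
    indOther <- sample(setdiff(genes, indUp), config@nInducible - nFromUp)
    inducible <- sort(c(indUp, indOther))

    roles <- c(rep("baseline", config@nBaseline), rep("line", config@nLines))
    names(roles) <- colnames(counts)
    list(counts = PluriCountSet(counts, roles),
         up = up, down = down, nullg = nullg, core = core,
         inducible = inducible)
  })

  truth <- new("SimTruth", plantedUp = out$up, plantedDown = out$down,
               nullGenes = out$nullg, plantedCore = out$core,
               enrichedTerms = .enrichedTermIds(config),
               inducible = out$inducible)
  list(counts = out$counts, truth = truth)
}

## Enriched terms are the first nEnrichedPerLevel terms of each level, by
## construction, so their ids are known before the catalog is drawn.
.enrichedTermIds <- function(config) {
  unlist(lapply(.kAnnotationLevels, function(lv)
    sprintf("%s_T%02d", lv, seq_len(config@nEnrichedPerLevel))),
    use.names = FALSE)
}

#' Simulate a six-level annotation catalog with planted enrichment
#'
#' Builds `nTermsPerLevel` terms at each of the six annotation levels. The
#' first `nEnrichedPerLevel` terms of each level are designated enriched:
#' they draw a configured fraction of their members from the planted
#' up-regulated block (background terms draw uniformly from the universe).
#' Guarantees that every planted-up gene occurs in at least one enriched
#' term, that the first enriched pathway-level term (the simulated stemness
#' pathway) contains the whole planted interaction core, and that every
#' inducible-list gene is annotated to at least one term per level.
#'
#' @param truth The [SimTruth-class] from [simulateCounts()].
#' @param config The same [SimConfig()] the counts were drawn with.
#'
#' @return An [AnnotationCatalog()].
#' @export
simulateAnnotations <- function(truth, config) {
  stopifnot(is(truth, "SimTruth"), is(config, "SimConfig"))
  universe <- sort(c(truth@plantedUp, truth@plantedDown, truth@nullGenes))
  up <- truth@plantedUp
  if (config@termSizeRange[2L] > length(universe))
    .stopf("termSizeRange exceeds the gene universe (%d genes)",
           length(universe))

  withr::with_seed(.childSeed(config@seed, .seedOffsets["annotations"]), {
    level <- character(); termId <- character(); termName <- character()
    genes <- list()
    for (lv in .kAnnotationLevels) {
      nEnr <- min(config@nEnrichedPerLevel, config@nTermsPerLevel)
      ## round-robin coverage of the planted-up block over this level's
      ## enriched terms
      covSplit <- if (nEnr > 0 && length(up))
        split(sample(up), rep(seq_len(nEnr), length.out = length(up)))
      else list()
      for (i in seq_len(config@nTermsPerLevel)) {
        sz <- sample(config@termSizeRange[1L]:config@termSizeRange[2L], 1L)
        id <- sprintf("%s_T%02d", lv, i)
        if (i <= nEnr) {
          nUp <- min(length(up), round(config@enrichmentFraction * sz))
          member <- sample(up, nUp)
          member <- unique(c(member, covSplit[[i]]))
          filler <- sample(setdiff(universe, member),
                           max(0L, sz - length(member)))
          member <- c(member, filler)
          if (lv == "KEGG-pathway" && i == 1L)
            member <- unique(c(member, truth@plantedCore))
          nm <- sprintf("simulated enriched %s term %d", lv, i)
        } else {
          member <- sample(universe, sz)
          nm <- sprintf("simulated background %s term %d", lv, i)
        }
        level <- c(level, lv); termId <- c(termId, id); termName <- c(termName, nm)
        genes[[id]] <- sort(unique(member))
      }
      ## every inducible gene annotated to >= 1 term at this level
      lvIdx <- which(level == lv)
      for (j in seq_along(truth@inducible)) {
        g <- truth@inducible[j]
        members <- unlist(genes[termId[lvIdx]], use.names = FALSE)
        if (!g %in% members) {
          tgt <- termId[lvIdx][1L + (j %% length(lvIdx))]
          genes[[tgt]] <- sort(c(genes[[tgt]], g))
        }
      }
    }
    AnnotationCatalog(level, termId, termName, genes[termId])
  })
}

#' Simulate a confidence-scored PPI network with a planted dense core
#'
#' Wires the planted core genes with probability `ppiCoreEdgeProb`
#' (1 = complete subgraph) and adds Erdos-Renyi background edges over the
#' whole gene universe at `ppiBackgroundEdgeProb`. Confidence scores are
#' drawn uniformly on \[400, 1000\] so that default score thresholds retain
#' every generated edge.
#'
#' @inheritParams simulateAnnotations
#'
#' @return A [PPINetwork()] whose node set is the full gene universe.
#' @export
simulatePPI <- function(truth, config) {
  stopifnot(is(truth, "SimTruth"), is(config, "SimConfig"))
  if (length(truth@plantedCore) < 2L)
    .stopf("planted core must contain at least 2 genes")
  universe <- sort(c(truth@plantedUp, truth@plantedDown, truth@nullGenes))
  n <- length(universe)

  withr::with_seed(.childSeed(config@seed, .seedOffsets["ppi"]), {
    core <- sort(truth@plantedCore)
    corePairs <- t(utils::combn(core, 2L))
    keep <- stats::runif(nrow(corePairs)) <= config@ppiCoreEdgeProb
    corePairs <- corePairs[keep, , drop = FALSE]

    ## background: sample pair indices from the C(n,2) lattice
    nPairs <- n * (n - 1) / 2
    nBg <- stats::rbinom(1L, nPairs, config@ppiBackgroundEdgeProb)
    idx <- sort(sample.int(nPairs, nBg))
    ## map linear index (1-based, row-major over i<j) to (i, j); the
    ## closed form can land one row off at exact boundaries, so correct
    i <- ceiling((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
    rowStart <- function(i) (i - 1) * (2 * n - i) / 2
    i <- ifelse(idx <= rowStart(i), i - 1L, i)
    i <- ifelse(idx > rowStart(i + 1), i + 1L, i)
    offs <- idx - rowStart(i)
    j <- i + offs
    bgPairs <- cbind(universe[i], universe[j])

    pairs <- rbind(corePairs, bgPairs)
    edges <- data.frame(protein1 = pairs[, 1L], protein2 = pairs[, 2L],
                        combined_score = round(stats::runif(nrow(pairs),
                                                            400, 1000)),
                        stringsAsFactors = FALSE)
    PPINetwork(edges, nodes = universe)
  })
}

#' Run all three generators from one configuration
#'
#' @inheritParams simulateCounts
#' @return A list with `counts`, `truth`, `catalog`, `ppi`.
#' @export
simulateStudy <- function(config) {
  sim <- simulateCounts(config)
  catalog <- simulateAnnotations(sim$truth, config)
  ppi <- simulatePPI(sim$truth, config)
  list(counts = sim$counts, truth = sim$truth, catalog = catalog, ppi = ppi)
}
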