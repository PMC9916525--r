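## Per-line differential expression against the fibroblast baseline.
##
## With one unreplicated baseline and unreplicated clonal lines no
## dispersion can be estimated, so the implemented statistic is the exact
## conditional binomial test: conditional on the two-sample total t = a + b,
## the line count a is Binomial(t, pi) under the null of equal relative
## abundance, with pi the line's share of the summed library sizes. The
## two-sided p-value is the sum of all outcome probabilities not exceeding
## the observed one (the "small p-values" convention). This is a principled
## stand-in for replicate-aware NB machinery, not a reproduction of it.

#' Counts per million
#'
#' @param count Raw count (vectorized).
#' @param librarySize Total counts of the sample; must be positive.
#' @return `count * 1e6 / librarySize`.
#' @export
#' @examples
#' cpm(7, 3.5e6)
cpm <- function(count, librarySize) {
  if (any(librarySize <= 0)) .stopf("library size must be positive")
  count * 1e6 / librarySize
}

#' Library-size-normalized log2 fold change with pseudocount
#'
#' `log2(((a + c) / lineLib) / ((b + c) / baselineLib))` with pseudocount
#' `c` applied to the raw counts before scaling; the pseudocount stabilizes
#' zeros and makes the statistic antisymmetric under sample swap.
#'
#' @param lineCount,baselineCount Raw counts (vectorized).
#' @param lineLib,baselineLib Library sizes (positive).
#' @param pseudocount Positive pseudocount added to both raw counts.
#' @return Log2 fold change of the line over the baseline.
#' @export
#' @examples
#' log2FoldChange(31, 7, 1e6, 1e6)  # log2(32/8) = 2
log2FoldChange <- function(lineCount, baselineCount, lineLib, baselineLib,
                           pseudocount = 1) {
  if (any(c(lineLib, baselineLib) <= 0)) .stopf("library sizes must be positive")
  if (pseudocount <= 0) .stopf("pseudocount must be positive")
  log2(((lineCount + pseudocount) / lineLib) /
         ((baselineCount + pseudocount) / baselineLib))
}

## Two-sided conditional binomial p for a successes out of t at prob pi.
## Outcomes whose probability is within 1e-12 relative of the observed one
## count as ties and are included. Enumeration up to .enumMax totals;
## binary-search tail boundaries beyond (dbinom is unimodal in x).
.enumMax <- 1e5
.tieRelErr <- 1 + 1e-12

.exactCountP <- function(a, t, prob) {
  if (t == 0) return(1)
  d <- stats::dbinom(a, t, prob) * .tieRelErr
  if (t <= .enumMax) {
    px <- stats::dbinom(0:t, t, prob)
    return(min(1, sum(px[px <= d])))
  }
  mode <- floor((t + 1) * prob)
  if (stats::dbinom(mode, t, prob) <= d) return(1)
  if (a < mode) {
    lower <- stats::pbinom(a, t, prob)
    if (stats::dbinom(t, t, prob) > d) return(min(1, lower))
    lo <- mode; hi <- t
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (stats::dbinom(mid, t, prob) <= d) hi <- mid else lo <- mid
    }
    min(1, lower + stats::pbinom(hi - 1, t, prob, lower.tail = FALSE))
  } else {
    upper <- stats::pbinom(a - 1, t, prob, lower.tail = FALSE)
    if (stats::dbinom(0, t, prob) > d) return(min(1, upper))
    lo <- 0; hi <- mode
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (stats::dbinom(mid, t, prob) <= d) lo <- mid else hi <- mid
    }
    min(1, upper + stats::pbinom(lo, t, prob))
  }
}

#' Exact conditional count test for one gene, line vs baseline
#'
#' Conditional on the total `t = lineCount + baselineCount`, the line count
#' is Binomial(`t`, `pi`) under the null, with
#' `pi = lineLib / (lineLib + baselineLib)`. The two-sided p-value sums the
#' probabilities of all outcomes at most as probable as the observed one
#' (ties within 1e-12 relative are included); `p = 1` when `t = 0`.
#'
#' @inheritParams log2FoldChange
#' @return p-value(s) in (0, 1]; vectorized over the counts.
#' @export
#' @examples
#' exactCountTest(10, 0, 1e6, 1e6)  # 2 * 2^-10
exactCountTest <- function(lineCount, baselineCount, lineLib, baselineLib) {
  if (any(lineCount != floor(lineCount)) ||
      any(baselineCount != floor(baselineCount)) ||
      any(lineCount < 0) || any(baselineCount < 0))
    .stopf("counts must be non-negative integers")
  if (any(c(lineLib, baselineLib) <= 0)) .stopf("library sizes must be positive")
  prob <- lineLib / (lineLib + baselineLib)
  n <- max(length(lineCount), length(baselineCount))
  a <- rep_len(lineCount, n); b <- rep_len(baselineCount, n)
  pr <- rep_len(prob, n)
  vapply(seq_len(n), function(i) .exactCountP(a[i], a[i] + b[i], pr[i]),
         numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]) behind input
#' validation: all p-values must lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values; elementwise `q >= p`, `q <= 1`.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call per-line differential expression against the baseline
#'
#' For every (gene, line) pair, computes CPM values, the pseudocount log2
#' fold change, the exact conditional binomial p-value, and a per-line BH
#' q-value. Multiple baseline columns are pooled by summation. A gene is
#' called `up` in a line if `log2fc >= lfcThreshold` and the chosen
#' significance measure (`q` by default, `p` optionally) is below `alpha`;
#' `down` symmetrically; otherwise `ns`.
#'
#' @param object A [PluriCountSet()].
#' @param lfcThreshold Absolute log2-fold-change threshold (default 1).
#' @param alpha Significance level (default 0.05).
#' @param significanceOn Whether the significance rule reads the FDR-adjusted
#'   `"q"` (default) or the raw `"p"`.
#' @param pseudocount Pseudocount for the fold change.
#' @return A `DETable` (a [S4Vectors::DataFrame]) with one row per
#'   (gene, line): `gene_id`, `line_id`, counts, CPMs, `log2fc`, `p`, `q`,
#'   `direction`.
#' @seealso [exactCountTest()], [upregulatedGenes()]
#' @export
callDE <- function(object, lfcThreshold = 1, alpha = 0.05,
                   significanceOn = c("q", "p"), pseudocount = 1) {
  stopifnot(is(object, "PluriCountSet"))
  significanceOn <- match.arg(significanceOn)
  m <- countsMatrix(object)
  libs <- librarySizes(object)
  bl <- baselineSamples(object)
  ln <- lineSamples(object)
  if (!length(ln)) .stopf("no line samples in the count matrix")
  baseCount <- if (length(bl) == 1L) m[, bl] else rowSums(m[, bl, drop = FALSE])
  baseLib <- sum(libs[bl])

  res <- lapply(ln, function(s) {
    a <- m[, s]; lib <- libs[s]
    p <- exactCountTest(a, baseCount, lib, baseLib)
    S4Vectors::DataFrame(
      gene_id = rownames(m), line_id = s,
      baseline_count = unname(baseCount), line_count = unname(a),
      cpm_baseline = unname(cpm(baseCount, baseLib)),
      cpm_line = unname(cpm(a, lib)),
      log2fc = unname(log2FoldChange(a, baseCount, lib, baseLib, pseudocount)),
      p = unname(p), q = unname(bhAdjust(p)))
  })
  tab <- do.call(rbind, res)
  sig <- if (significanceOn == "q") tab$q else tab$p
  tab$direction <- ifelse(sig < alpha & tab$log2fc >= lfcThreshold, "up",
                   ifelse(sig < alpha & tab$log2fc <= -lfcThreshold, "down",
                          "ns"))
  out <- new("DETable", tab)
  S4Vectors::metadata(out) <- list(lfcThreshold = lfcThreshold, alpha = alpha,
                                   significanceOn = significanceOn,
                                   pseudocount = pseudocount)
  out
}

#' Genes called up-regulated in at least a given number of lines
#'
#' @param de A `DETable` from [callDE()].
#' @param minLines Minimum number of lines a gene must be called `up` in.
#' @return Sorted character vector of gene ids.
#' @export
upregulatedGenes <- function(de, minLines = 1L) {
  up <- de[de$direction == "up", , drop = FALSE]
  tab <- table(up$gene_id)
  sort(names(tab)[tab >= minLines])
}

#' Per-gene up-call line counts and lines
#' @noRd
.upLinesByGene <- function(de) {
  up <- de[de$direction == "up", , drop = FALSE]
  split(as.character(up$line_id), as.character(up$gene_id))
}
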