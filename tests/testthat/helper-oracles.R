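## Independent brute-force oracles, deliberately written with elementary
## arithmetic (choose(), explicit loops, BFS) so they share no code path
## with the implementation they check.

## Two-sided conditional binomial p by full enumeration of all t+1 outcomes.
oracleExactP <- function(a, b, lineLib, baseLib) {
  t <- a + b
  if (t == 0) return(1)
  prob <- lineLib / (lineLib + baseLib)
  x <- 0:t
  ## log-space binomial coefficients so the oracle also covers large totals
  px <- exp(lchoose(t, x) + x * log(prob) + (t - x) * log1p(-prob))
  sum(px[px <= px[a + 1] * (1 + 1e-12)])
}

## Upper-tail hypergeometric P(X >= k) by direct coefficient sums.
oracleHyperP <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  x <- k:hi
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

## Benjamini-Hochberg step-up with an explicit cumulative minimum.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

## Connected components by breadth-first traversal over an edge list.
oracleComponents <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- edges$protein1[r]; b <- edges$protein2[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(); comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start; comp <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

## Degree of every node counted straight off the edge list.
oracleDegrees <- function(nodes, edges) {
  d <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    d[edges$protein1[r]] <- d[edges$protein1[r]] + 1L
    d[edges$protein2[r]] <- d[edges$protein2[r]] + 1L
  }
  d
}

## Random undirected graph as a canonical edge table.
randomEdgeTable <- function(n, p) {
  nodes <- sprintf("N%03d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(protein1 = pairs[keep, 1], protein2 = pairs[keep, 2],
             combined_score = 900, stringsAsFactors = FALSE)
}

## Tiny deterministic count set used across screening tests.
toyCountSet <- function() {
  m <- matrix(c(
    ## F    L1   L2   L3
       10,  100, 120,  90,   # A  clean up-regulated, passes filter
       60,  200, 220, 210,   # B  baseline too high (60 > 50)
        5,   19,  21,  20,   # C  line counts straddle minLine
        0,    0,    0,   0,  # D  silent
       40,    2,    1,   3,  # E  down-regulated
       30,   90,  10, 100    # F  up in some lines only
  ), nrow = 6, byrow = TRUE,
  dimnames = list(c("A", "B", "C", "D", "E", "F"),
                  c("F0", "L1", "L2", "L3")))
  ## pad one high-count gene so library sizes are realistic
  PluriCountSet(rbind(m, PAD = c(5000L, 5000L, 5000L, 5000L)),
                c(F0 = "baseline", L1 = "line", L2 = "line", L3 = "line"))
}

## Minimal catalog over the toy genes.
toyCatalog <- function() {
  AnnotationCatalog(
    level = c("GO-process", "GO-process", "KEGG-pathway"),
    termId = c("GOP1", "GOP2", "KP1"),
    termName = c("proliferation", "adhesion", "stemness"),
    genes = list(c("A", "C", "E"), c("B", "F"), c("A", "F", "D")))
}
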