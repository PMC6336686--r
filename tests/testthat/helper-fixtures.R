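# shared fixtures and independent oracles, built in code at test time

# a small DE table with known content
makeDeTable <- function(genes, lfc, se = 0.1, padj = NULL, seed = 1) {
  set.seed(seed)
  p <- 2 * pnorm(abs(lfc) / se, lower.tail = FALSE)
  data.frame(gene = genes, log2FC = lfc, SE = se, p = p,
             padj = if (is.null(padj)) p.adjust(p, "BH") else padj)
}

# exhaustive all-pairs peak-TSS scan; the oracle for annotatePeaksToTSS.
# gap convention: number of bases strictly between the TSS point and the
# nearest end of the (1-based, closed) peak interval; 0 if contained.
bruteAnnotate <- function(peaks, tss, window) {
  ps <- GenomicRanges::start(peaks); pe <- GenomicRanges::end(peaks)
  pc <- as.character(GenomicRanges::seqnames(peaks))
  nm <- if (!is.null(peaks$name)) peaks$name else as.character(seq_along(peaks))
  out <- lapply(seq_along(peaks), function(i) {
    pos <- tss$tss
    d <- ifelse(pos >= ps[i] & pos <= pe[i], 0,
                ifelse(pos < ps[i], ps[i] - pos - 1, pos - pe[i] - 1))
    j <- which(pc[i] == tss$chrom & d <= window)
    if (length(j)) data.frame(peak = nm[i], gene = tss$gene[j], d = d[j])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(peak = character(), gene = character(),
                               d = numeric())
  else out
}

# exact upper-tail hypergeometric by enumerating every placement of the
# nB marked elements in a universe of size N (feasible for N <= 12)
enumHyperP <- function(N, nA, nB, k) {
  sets <- utils::combn(N, nB)
  aSet <- seq_len(nA)
  hits <- apply(sets, 2L, function(s) sum(s %in% aSet) >= k)
  mean(hits)
}

# exact bootstrap probability: enumerate all ordered with-replacement
# k-tuples over the universe values (feasible for |U|^k <= ~1e6)
enumBootP <- function(vals, k, observed) {
  grids <- do.call(expand.grid, rep(list(seq_along(vals)), k))
  means <- rowMeans(matrix(vals[as.matrix(grids)], nrow(grids), k))
  mean(means >= observed)
}

# two-sample KS statistic from first principles (max ecdf difference)
bruteKsD <- function(x, y) {
  g <- sort(c(x, y))
  max(abs(ecdf(x)(g) - ecdf(y)(g)))
}

# adjusted Rand index between two label vectors
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp <- ai * bj / n2
  (nij - exp) / ((ai + bj) / 2 - exp)
}

# cohort with every planted effect, shared across tests (small but rich)
richCohort <- function(seed = 101, nTumors = 160, nNormals = 30) {
  g <- geneIds(120)
  simulateCohort(cohortSpec(
    nTumors = nTumors, nNormals = nNormals, nGenes = 120, nMirnas = 4,
    plantedAxis = list(mirna = "miR-001", targets = g[1:20],
                       rLow = 0.7, rHigh = 0.1),
    plantedOutliers = list(genes = g[21:30], zEffect = 5,
                           tumorFraction = 0.45),
    plantedSurvival = list(genes = g[31:40], hazardRatio = 2,
                           eventFraction = 0.4),
    seed = seed))
}
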