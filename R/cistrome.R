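#' Annotate binding peaks to gene TSS windows
#'
#' Reports every (peak, gene) pair whose minimum distance between the peak
#' interval and the TSS point is at most `window` bp (the classical
#' "±7.5 kb of the TSS" annotation). Peaks may map to several genes and
#' genes to several peaks. Coordinates are BED-convention internally
#' (0-based half-open intervals); the TSS table carries 1-based positions.
#' Distance follows the gap convention: adjacent but non-overlapping
#' features have distance equal to the number of bases strictly between
#' them, so a peak starting 7501 bp beyond the TSS is excluded at
#' `window = 7500`.
#'
#' @param peaks a [GenomicRanges::GRanges] of peaks (e.g. from
#'   [readPeaksBED()] or [simulateCistrome()]).
#' @param tss data.frame with columns gene, chrom, strand, tss (1-based).
#' @param window maximum distance in bp (default 7500, symmetric).
#' @return data.frame with columns `peak`, `gene`, `distance` (bp, 0 if the
#'   TSS falls inside the peak, negative if the peak lies upstream of the
#'   TSS in the gene's orientation) and `strand`.
#' @examples
#' pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200),
#'                              name = "pk1")
#' tss <- data.frame(gene = "g1", chrom = "chr1", strand = "+", tss = 1100)
#' annotatePeaksToTSS(pk, tss, window = 7500)
#' @export
annotatePeaksToTSS <- function(peaks, tss, window = 7500) {
  stopifnot(is(peaks, "GRanges"))
  if (length(window) != 1L || window <= 0)
    stop("'window' must be a single positive number of bp", call. = FALSE)
  empty <- data.frame(peak = character(), gene = character(),
                      distance = numeric(), strand = character())
  if (nrow(tss) == 0L) {
    warning("empty TSS table: returning an empty peak-gene map")
    return(empty)
  }
  tssGR <- GenomicRanges::GRanges(tss$chrom,
                                  IRanges::IRanges(tss$tss, width = 1L))
  hits <- GenomicRanges::findOverlaps(peaks, tssGR,
                                      maxgap = as.integer(window))
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(peaks[q], tssGR[s])
  keep <- d <= window
  q <- q[keep]; s <- s[keep]; d <- d[keep]

  # signed distance: + when the peak lies downstream of the TSS in the
  # gene's orientation, - upstream, 0 when the TSS is inside the peak
  pStart <- GenomicRanges::start(peaks)[q]
  pos <- tss$tss[s]
  genomicSign <- ifelse(d == 0, 0, ifelse(pStart > pos, 1, -1))
  sgn <- ifelse(tss$strand[s] == "-", -genomicSign, genomicSign)

  nm <- if (!is.null(peaks$name)) peaks$name else as.character(seq_along(peaks))
  data.frame(peak = nm[q], gene = tss$gene[s], distance = sgn * d,
             strand = tss$strand[s], row.names = NULL)
}

#' Interval-overlap count and hypergeometric significance
#'
#' Counts intervals in `a` that lie within `maxGap` bp of any interval in
#' `b` (each counted once) and assesses the overlap by an upper-tail
#' hypergeometric test over a binned genome: with `universe` bins, `|a|`
#' draws and `|b|` successes, the p-value is `P(X >= n_overlap)`. If
#' `universe` is omitted the genome spanned by both sets is divided into
#' bins of width equal to the median interval width.
#'
#' @param a,b [GenomicRanges::GRanges] interval sets.
#' @param maxGap maximum gap in bp for two intervals to count as
#'   overlapping (default 500).
#' @param universe number of genomic bins; must be able to hold both sets.
#' @return list with `nOverlap`, `p`, `universe`, and the set sizes.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1000), width = 100))
#' overlapSignificance(a, a, universe = 1000)
#' @export
overlapSignificance <- function(a, b, maxGap = 500, universe = NULL) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  if (maxGap < 0) stop("'maxGap' must be >= 0", call. = FALSE)
  # sets on disjoint chromosome namespaces are a legitimate comparison;
  # silence the seqlevel-merge notice
  nOv <- sum(suppressWarnings(
    GenomicRanges::countOverlaps(a, b, maxgap = as.integer(maxGap))) > 0L)
  if (is.null(universe)) {
    med <- median(c(GenomicRanges::width(a), GenomicRanges::width(b)))
    span <- sum(vapply(split(c(GenomicRanges::granges(a),
                               GenomicRanges::granges(b)),
                             GenomicRanges::seqnames(c(GenomicRanges::granges(a),
                                                       GenomicRanges::granges(b)))),
                       function(g) if (length(g)) max(GenomicRanges::end(g)) else 0,
                       numeric(1)))
    universe <- max(1, floor(span / med))
  }
  occupancy <- length(a) + length(b) - nOv
  if (universe < occupancy)
    stop("'universe' (", universe, " bins) is smaller than the combined ",
         "occupancy of the two interval sets (", occupancy, ")",
         call. = FALSE)
  p <- phyper(nOv - 1L, length(b), universe - length(b), length(a),
              lower.tail = FALSE)
  list(nOverlap = nOv, p = p, universe = universe,
       nA = length(a), nB = length(b))
}

#' Bootstrap test: are bound genes more differentially expressed than chance?
#'
#' The cistrome-transcriptome association test. The observed statistic is
#' the mean |log2FC| (or signed mean) of the bound genes within the DE
#' universe; the null is built by drawing `nResamples` gene sets of the
#' same size from the full universe by sampling with replacement, and the
#' empirical p-value uses the add-one rule `(1 + b) / (1 + B)`, so it is
#' never zero.
#'
#' @param boundGenes character vector of gene ids (e.g. from
#'   [annotatePeaksToTSS()]); intersected with the DE universe first.
#' @param de DE table (gene, log2FC, SE, p, padj).
#' @param nResamples number of bootstrap resamples (>= 1000; default 1e5).
#' @param seed integer RNG seed.
#' @param statistic `"meanAbsLog2FC"` (default) or `"meanLog2FC"`.
#' @return an [EmpiricalTestResult-class].
#' @examples
#' de <- data.frame(gene = geneIds(50), log2FC = rnorm(50), SE = 0.1,
#'                  p = runif(50), padj = runif(50))
#' bootstrapExpressionAssociation(geneIds(50)[1:5], de,
#'                                nResamples = 1000, seed = 1)
#' @export
bootstrapExpressionAssociation <- function(boundGenes, de,
                                           nResamples = 1e5, seed = 1L,
                                           statistic = c("meanAbsLog2FC",
                                                         "meanLog2FC")) {
  statistic <- match.arg(statistic)
  assertDETable(de)
  if (nResamples < 1000)
    stop("'nResamples' must be at least 1000", call. = FALSE)
  inUniverse <- intersect(boundGenes, de$gene)
  if (!length(inUniverse))
    stop("no bound genes fall in the DE universe", call. = FALSE)
  if (length(inUniverse) < length(boundGenes))
    message(length(inUniverse), " of ", length(boundGenes),
            " bound genes intersect the DE universe")
  vals <- if (statistic == "meanAbsLog2FC") abs(de$log2FC) else de$log2FC
  k <- length(inUniverse)
  observed <- mean(vals[match(inUniverse, de$gene)])
  set.seed(as.integer(seed))
  B <- as.integer(nResamples)
  null <- rowMeans(matrix(vals[sample.int(length(vals), B * k,
                                          replace = TRUE)], B, k))
  newEmpiricalTestResult(observed, null, seed, statistic)
}

#' Compare correlation distributions of a target set against background
#'
#' Computes the Pearson correlation of a focal feature (e.g. a miRNA)
#' against every gene in the expression matrix, then tests by two-sample
#' Kolmogorov-Smirnov whether the correlations of a designated target set
#' are distributed differently from the background of all genes.
#'
#' @param focal numeric vector, expression of the focal feature across
#'   samples (in the column order of `expr`).
#' @param targetGenes character vector of target gene ids.
#' @param expr genes x samples log2 expression matrix.
#' @return list with `rTargets`, `rBackground` (named correlation vectors),
#'   `D` (KS statistic) and `p`.
#' @examples
#' m <- matrix(rnorm(300), 10, 30, dimnames = list(geneIds(10), NULL))
#' correlationDistributionTest(rnorm(30), geneIds(10)[1:3], m)
#' @export
correlationDistributionTest <- function(focal, targetGenes, expr) {
  if (length(focal) != ncol(expr))
    stop("'focal' length must equal the number of samples", call. = FALSE)
  if (ncol(expr) < 3L)
    stop("at least 3 samples are required", call. = FALSE)
  if (sd(focal) == 0)
    stop("zero-variance focal vector: correlations undefined", call. = FALSE)
  if (!all(targetGenes %in% rownames(expr)))
    stop("targetGenes must all be rows of 'expr'", call. = FALSE)
  r <- as.numeric(cor(focal, t(expr)))
  names(r) <- rownames(expr)
  rT <- r[targetGenes]
  if (setequal(targetGenes, rownames(expr))) {
    return(list(rTargets = rT, rBackground = r, D = 0, p = 1))
  }
  ks <- suppressWarnings(ks.test(rT, r))
  list(rTargets = rT, rBackground = r,
       D = unname(ks$statistic), p = ks$p.value)
}
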