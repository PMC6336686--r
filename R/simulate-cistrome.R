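#' Specify a synthetic cistrome (peaks + TSS + matched DE table)
#'
#' Parameters for [simulateCistrome()], which emulates the input to the
#' cistrome-transcriptome association test: a set of binding peaks, a gene
#' TSS table, and a differential-expression table in which genes planted as
#' "bound" (receiving at least one peak within `window` bp of their TSS)
#' have their absolute log2 fold change raised by `boundEffect` on average.
#'
#' @param nChroms,chromLength genome shape: number of chromosomes and their
#'   common length in bp. The default gives a TSS spacing of tens of kb
#'   (order of real gene density), so a random peak rarely falls inside an
#'   annotation window.
#' @param nPeaks total peaks (planted peaks included).
#' @param nGenes genes in the TSS table and DE universe.
#' @param plantedBoundGenes gene ids guaranteed a proximal peak.
#' @param boundEffect mean uplift of |log2FC| for bound genes (0 = null).
#' @param window annotation window around the TSS, bp.
#' @param peakWidth typical peak width, bp.
#' @param lfcSd baseline spread of the null log2 fold changes.
#' @param seed integer RNG seed.
#' @return a validated list of class `"cistromeSpec"`.
#' @export
cistromeSpec <- function(nChroms = 2L, chromLength = 5e7, nPeaks = 300L,
                         nGenes = 2000L, plantedBoundGenes = character(),
                         boundEffect = 0.5, window = 7500,
                         peakWidth = 200L, lfcSd = 0.3, seed = 1L) {
  nGenes <- checkCount(nGenes, "nGenes", 1L)
  if (!all(plantedBoundGenes %in% geneIds(nGenes)))
    failField("plantedBoundGenes", "not all in the generated gene universe")
  if (length(window) != 1L || !is.finite(window) || window <= 0)
    failField("window", "must be a single positive number of bp")
  structure(list(
    nChroms = checkCount(nChroms, "nChroms", 1L),
    chromLength = checkPositive(chromLength, "chromLength"),
    nPeaks = checkCount(nPeaks, "nPeaks", 1L),
    nGenes = nGenes, plantedBoundGenes = plantedBoundGenes,
    boundEffect = boundEffect, window = window,
    peakWidth = checkCount(peakWidth, "peakWidth", 10L),
    lfcSd = checkPositive(lfcSd, "lfcSd"),
    seed = checkCount(seed, "seed")), class = "cistromeSpec")
}

#' Simulate peaks, TSS coordinates and a matched DE table
#'
#' Peaks are BED-convention intervals (0-based, half-open) on a small
#' synthetic genome. Every gene in `plantedBoundGenes` receives one peak
#' whose distance to its TSS is strictly below `window`; remaining peaks
#' are placed uniformly. The DE table draws null log2 fold changes from
#' `N(0, lfcSd)` and adds `boundEffect` to the magnitude for bound genes,
#' preserving sign.
#'
#' @param spec a [cistromeSpec()].
#' @return list with `peaks` (a [GenomicRanges::GRanges]), `tss` (data.frame:
#'   gene, chrom, strand, tss with 1-based positions), `de` (DE table) and
#'   `truth` (planted bound gene ids).
#' @examples
#' cs <- simulateCistrome(cistromeSpec(nPeaks = 50, nGenes = 100,
#'         plantedBoundGenes = geneIds(100)[1:10], seed = 2))
#' cs$peaks
#' @export
simulateCistrome <- function(spec) {
  stopifnot(inherits(spec, "cistromeSpec"))
  set.seed(spec$seed)
  genes <- geneIds(spec$nGenes)
  chroms <- sprintf("chr%d", seq_len(spec$nChroms))
  L <- spec$chromLength; w <- spec$peakWidth

  tss <- data.frame(
    gene = genes,
    chrom = sample(chroms, spec$nGenes, replace = TRUE),
    strand = sample(c("+", "-"), spec$nGenes, replace = TRUE),
    tss = sample.int(as.integer(L - 2 * spec$window) , spec$nGenes) +
      as.integer(spec$window))

  bi <- match(spec$plantedBoundGenes, genes)
  nPlanted <- length(bi)
  if (spec$nPeaks < nPlanted)
    failField("nPeaks", "fewer peaks than planted bound genes")

  # planted peak: start (1-based) offset from the TSS keeps the interval
  # within `window` bp of the TSS point under the gap convention
  offs <- sample.int(2L * (spec$window - w), nPlanted, replace = TRUE) -
    (spec$window - w)
  pStart1 <- pmax(1, tss$tss[bi] + offs - w %/% 2L)
  pChrom <- tss$chrom[bi]

  nRand <- spec$nPeaks - nPlanted
  rChrom <- sample(chroms, nRand, replace = TRUE)
  rStart1 <- sample.int(as.integer(L - w), nRand, replace = TRUE)

  peaks <- GenomicRanges::GRanges(
    seqnames = c(pChrom, rChrom),
    ranges = IRanges::IRanges(start = c(pStart1, rStart1), width = w),
    name = sprintf("peak%05d", seq_len(spec$nPeaks)),
    score = round(runif(spec$nPeaks, 10, 1000)))

  lfc <- rnorm(spec$nGenes, 0, spec$lfcSd)
  if (nPlanted)
    lfc[bi] <- sign(lfc[bi]) * (abs(lfc[bi]) + spec$boundEffect)
  sdEff <- spec$lfcSd
  p <- 2 * pnorm(abs(lfc) / sdEff, lower.tail = FALSE)
  de <- data.frame(gene = genes, log2FC = lfc, SE = sdEff, p = p,
                   padj = p.adjust(p, "BH"), contrast = "knockdown_vs_control")

  list(peaks = peaks, tss = tss, de = de,
       truth = list(boundGenes = spec$plantedBoundGenes,
                    boundEffect = spec$boundEffect))
}
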