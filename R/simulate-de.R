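#' Specify a synthetic knockdown-by-hormone expression experiment
#'
#' Parameters for [simulateDEExperiment()], which emulates a 2x2 design:
#' control and regulator-knockdown cells, each profiled with and without
#' hormone, in `nReplicates` replicates. A chosen subset of genes responds
#' to hormone (log2 fold changes drawn from a signed truncated Gaussian);
#' within that subset, `dampenedGenes` have their hormone effect multiplied
#' by `dampeningFactor` in the knockdown conditions only.
#'
#' @param nGenes total genes (responsive genes are a subset).
#' @param nReplicates replicates per condition; must be >= 2 so a standard
#'   error is defined.
#' @param responsiveGenes character vector of hormone-responsive gene ids
#'   (must fall in the generated universe `gene0001 ...`).
#' @param dampenedGenes subset of `responsiveGenes` whose hormone response
#'   is attenuated under knockdown.
#' @param dampeningFactor multiplier in `[0, 1]` applied to the hormone
#'   log2FC of dampened genes in knockdown conditions (1 = no dampening).
#' @param lfcMean,lfcSd,lfcMin distribution of the planted hormone |log2FC|
#'   (Gaussian, truncated below at `lfcMin`); sign is random per gene.
#' @param residualSd replicate-level residual standard deviation (log2).
#' @param seed integer RNG seed.
#' @return a validated list of class `"deExperimentSpec"`.
#' @export
deExperimentSpec <- function(nGenes = 2500L, nReplicates = 3L,
                             responsiveGenes = character(),
                             dampenedGenes = character(),
                             dampeningFactor = 1,
                             lfcMean = 1.5, lfcSd = 0.5, lfcMin = 0.5,
                             residualSd = 0.1, seed = 1L) {
  nGenes <- checkCount(nGenes, "nGenes")
  nReplicates <- checkCount(nReplicates, "nReplicates", 0L)
  if (nReplicates < 2L)
    failField("nReplicates", "must be >= 2 (standard errors are undefined otherwise)")
  genes <- geneIds(nGenes)
  if (!all(responsiveGenes %in% genes))
    failField("responsiveGenes", "not all in the generated gene universe")
  if (!all(dampenedGenes %in% responsiveGenes))
    failField("dampenedGenes", "must be a subset of responsiveGenes")
  structure(list(
    nGenes = nGenes, nReplicates = nReplicates,
    responsiveGenes = responsiveGenes, dampenedGenes = dampenedGenes,
    dampeningFactor = checkFraction(dampeningFactor, "dampeningFactor"),
    lfcMean = lfcMean, lfcSd = lfcSd, lfcMin = lfcMin,
    residualSd = checkPositive(residualSd, "residualSd"),
    seed = checkCount(seed, "seed")), class = "deExperimentSpec")
}

#' Simulate the knockdown-by-hormone experiment and summarise it as DE tables
#'
#' Generates replicate-level log2 expression for the four conditions and
#' reduces each hormone-vs-vehicle contrast to a DE table (per-gene log2FC,
#' Welch SE, p and BH-adjusted p), the schema consumed by [callDEGs()] and
#' [classifyModulation()].
#'
#' @param spec a [deExperimentSpec()].
#' @return list with elements
#'   \describe{
#'     \item{control, knockdown}{DE tables for hormone vs vehicle in each
#'       background.}
#'     \item{truth}{list with `responsive` and `dampened` gene ids and the
#'       planted per-gene hormone log2FC.}
#'     \item{replicates}{the four replicate-level matrices.}
#'   }
#' @examples
#' spec <- deExperimentSpec(nGenes = 50, responsiveGenes = geneIds(50)[1:10],
#'                          dampenedGenes = geneIds(50)[1:5],
#'                          dampeningFactor = 0.4, seed = 3)
#' de <- simulateDEExperiment(spec)
#' head(de$control)
#' @export
simulateDEExperiment <- function(spec) {
  stopifnot(inherits(spec, "deExperimentSpec"))
  set.seed(spec$seed)
  genes <- geneIds(spec$nGenes)
  nr <- spec$nReplicates

  if (spec$nGenes == 0L) {
    empty <- data.frame(gene = character(), log2FC = numeric(),
                        SE = numeric(), p = numeric(), padj = numeric(),
                        contrast = character())
    return(list(control = empty, knockdown = empty,
                truth = list(responsive = character(),
                             dampened = character(),
                             lfc = numeric()),
                replicates = list()))
  }

  beta <- numeric(spec$nGenes)
  names(beta) <- genes
  ri <- match(spec$responsiveGenes, genes)
  if (length(ri)) {
    mag <- pmax(rnorm(length(ri), spec$lfcMean, spec$lfcSd), spec$lfcMin)
    beta[ri] <- sample(c(-1, 1), length(ri), replace = TRUE) * mag
  }
  damp <- rep(1, spec$nGenes)
  damp[match(spec$dampenedGenes, genes)] <- spec$dampeningFactor

  mu <- runif(spec$nGenes, 4, 12)
  draw <- function(effect) {
    m <- mu + effect + matrix(rnorm(spec$nGenes * nr, sd = spec$residualSd),
                              spec$nGenes, nr)
    rownames(m) <- genes
    m
  }
  reps <- list(
    control_vehicle    = draw(0),
    control_hormone    = draw(beta),
    knockdown_vehicle  = draw(0),
    knockdown_hormone  = draw(beta * damp))

  makeDE <- function(h, v, contrast) {
    w <- rowWelch(reps[[h]], reps[[v]])
    data.frame(gene = genes, log2FC = w$log2FC, SE = w$SE, p = w$p,
               padj = p.adjust(w$p, "BH"), contrast = contrast,
               row.names = NULL)
  }
  list(
    control   = makeDE("control_hormone", "control_vehicle",
                       "hormone_vs_vehicle.control"),
    knockdown = makeDE("knockdown_hormone", "knockdown_vehicle",
                       "hormone_vs_vehicle.knockdown"),
    truth = list(responsive = spec$responsiveGenes,
                 dampened = spec$dampenedGenes, lfc = beta),
    replicates = reps)
}
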