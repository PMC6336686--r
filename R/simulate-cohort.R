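#' Specify a synthetic tumor/normal cohort
#'
#' Builds and validates the parameter set for [simulateCohort()]. The
#' generator emulates a prostate-cancer style expression cohort: log2-scale
#' gene and miRNA matrices over tumor and normal samples, clinical
#' covariates (age, Gleason sum, disease-free survival), and three kinds of
#' planted effect used to benchmark the downstream screens:
#'
#' * `plantedAxis` — a miRNA whose correlation with chosen target genes
#'   differs between the low and high quartile of its own expression
#'   (`rLow` vs `rHigh`), the structure probed by [correlationShift()].
#' * `plantedOutliers` — genes shifted by `zEffect` normal-reference
#'   standard deviations in a fraction of tumors, the structure probed by
#'   [tumorNormalZ()] and [filterOutlierGenes()].
#' * `plantedSurvival` — a tumor subgroup with elevated expression of the
#'   given genes and an exponential hazard multiplied by `hazardRatio`,
#'   the structure probed by [survivalScreen()].
#'
#' @param nTumors,nNormals,nGenes,nMirnas cohort dimensions.
#' @param plantedAxis `NULL` or `list(mirna=, targets=, rLow=, rHigh=)`
#'   with correlations in `[-1, 1]`; `rLow`/`rHigh` may be scalars or one
#'   value per target gene, so mixed positive and negative axes can be
#'   planted in one cohort.
#' @param plantedOutliers `NULL` or `list(genes=, zEffect=, tumorFraction=)`.
#' @param plantedSurvival `NULL` or `list(genes=, hazardRatio=,
#'   eventFraction=, subgroupFraction=, exprShift=)`; the last two default
#'   to 0.5 and 3 (subgroup size as a fraction of tumors, and the log2
#'   expression uplift, in units of `noiseSd`, marking subgroup tumors).
#' @param noiseSd per-feature residual standard deviation on the log2 scale.
#' @param gleasonProbs list with elements `base` and `subgroup`: class
#'   probabilities over Gleason sums 6:9 for tumors outside and inside the
#'   planted survival subgroup.
#' @param seed integer RNG seed; every generated byte is a function of it.
#' @return a validated list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(nTumors = 400L, nNormals = 50L, nGenes = 500L,
                       nMirnas = 20L,
                       plantedAxis = NULL, plantedOutliers = NULL,
                       plantedSurvival = NULL, noiseSd = 1,
                       gleasonProbs = list(
                         base     = c(`6` = .45, `7` = .35, `8` = .15, `9` = .05),
                         subgroup = c(`6` = .10, `7` = .30, `8` = .35, `9` = .25)),
                       seed = 1L) {
  spec <- list(
    nTumors  = checkCount(nTumors, "nTumors", 1L),
    nNormals = checkCount(nNormals, "nNormals", 2L),
    nGenes   = checkCount(nGenes, "nGenes", 1L),
    nMirnas  = checkCount(nMirnas, "nMirnas", 1L),
    plantedAxis = plantedAxis, plantedOutliers = plantedOutliers,
    plantedSurvival = plantedSurvival,
    noiseSd  = checkPositive(noiseSd, "noiseSd"),
    gleasonProbs = gleasonProbs,
    seed     = checkCount(seed, "seed"))
  genes  <- geneIds(spec$nGenes)
  mirnas <- mirnaIds(spec$nMirnas)
  if (!is.null(plantedAxis)) {
    if (!plantedAxis$mirna %in% mirnas)
      failField("plantedAxis$mirna", "not in the generated miRNA universe")
    if (!all(plantedAxis$targets %in% genes))
      failField("plantedAxis$targets", "not all in the generated gene universe")
    for (f in c("rLow", "rHigh")) {
      r <- plantedAxis[[f]]
      if (!length(r) %in% c(1L, length(plantedAxis$targets)) ||
          !all(is.finite(r)) || any(abs(r) > 1))
        failField(paste0("plantedAxis$", f),
                  "must lie in [-1, 1] (length 1 or one value per target)")
    }
  }
  if (!is.null(plantedOutliers)) {
    if (!all(plantedOutliers$genes %in% genes))
      failField("plantedOutliers$genes", "not all in the generated gene universe")
    checkPositive(plantedOutliers$zEffect, "plantedOutliers$zEffect")
    checkFraction(plantedOutliers$tumorFraction, "plantedOutliers$tumorFraction")
  }
  if (!is.null(plantedSurvival)) {
    if (!all(plantedSurvival$genes %in% genes))
      failField("plantedSurvival$genes", "not all in the generated gene universe")
    checkPositive(plantedSurvival$hazardRatio, "plantedSurvival$hazardRatio")
    checkFraction(plantedSurvival$eventFraction, "plantedSurvival$eventFraction")
    spec$plantedSurvival$subgroupFraction <-
      checkFraction(plantedSurvival$subgroupFraction %||% 0.5,
                    "plantedSurvival$subgroupFraction")
    spec$plantedSurvival$exprShift <- plantedSurvival$exprShift %||% 3
  }
  structure(spec, class = "cohortSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature identifiers of the generated universes
#'
#' The synthetic generators name genes `gene0001, gene0002, ...` and
#' miRNAs `miR-001, ...`; these helpers produce the same ids so planted
#' subsets can be specified concisely.
#'
#' @param n universe size.
#' @return character vector of ids.
#' @examples
#' geneIds(3)
#' @export
geneIds  <- function(n) sprintf("gene%04d", seq_len(n))

#' @rdname geneIds
#' @export
mirnaIds <- function(n) sprintf("miR-%03d", seq_len(n))

# index sets of the lower/upper floor(n/4) values, stable order for ties
stratifyIdx <- function(values) {
  n <- length(values)
  k <- floor(n / 4)
  ord <- order(values, seq_along(values))
  list(low = sort(ord[seq_len(k)]), high = sort(ord[seq.int(n - k + 1L, n)]))
}

#' Simulate a tumor/normal expression cohort with planted effects
#'
#' Draws log2-scale gene and miRNA expression from a Gaussian latent model.
#' Stratum-specific miRNA-target correlations are planted by mixing each
#' target gene with the miRNA's standardized latent value within each
#' quartile stratum: `g = r * z + sqrt(1 - r^2) * e`, so the within-stratum
#' Pearson correlation converges to the planted `r`. Survival times are
#' exponential with administrative censoring at `horizon`; the baseline
#' rate is solved so the expected event fraction matches the spec.
#'
#' @param spec a [cohortSpec()].
#' @param horizon administrative censoring time, months.
#' @return a [SimulatedCohort-class] object.
#' @examples
#' sc <- simulateCohort(cohortSpec(nTumors = 40, nNormals = 10,
#'                                 nGenes = 30, nMirnas = 4, seed = 7))
#' dim(geneExpr(sc))
#' head(clinicalTable(sc))
#' @export
simulateCohort <- function(spec, horizon = 120) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  nT <- spec$nTumors; nN <- spec$nNormals; n <- nT + nN
  samples <- c(sprintf("tumor%04d", seq_len(nT)),
               sprintf("normal%04d", seq_len(nN)))
  tumorIdx <- seq_len(nT)
  genes <- geneIds(spec$nGenes); mirnas <- mirnaIds(spec$nMirnas)
  sdv <- spec$noiseSd

  muM <- runif(spec$nMirnas, 4, 10)
  zM <- matrix(rnorm(spec$nMirnas * n), spec$nMirnas, n)
  mirnaMat <- muM + sdv * zM
  dimnames(mirnaMat) <- list(mirnas, samples)

  muG <- runif(spec$nGenes, 4, 12)
  eps <- matrix(rnorm(spec$nGenes * n), spec$nGenes, n)
  latent <- eps
  truth <- list()

  if (!is.null(spec$plantedAxis)) {
    ax <- spec$plantedAxis
    mz <- zM[match(ax$mirna, mirnas), tumorIdx]
    strata <- stratifyIdx(mz)
    mid <- setdiff(tumorIdx, c(strata$low, strata$high))
    gi <- match(ax$targets, genes)
    rLow <- rep_len(ax$rLow, length(gi))
    rHigh <- rep_len(ax$rHigh, length(gi))
    rFor <- list(low = rLow, high = rHigh, mid = (rLow + rHigh) / 2)
    for (part in names(rFor)) {
      idx <- switch(part, low = strata$low, high = strata$high, mid = mid)
      if (length(idx) < 3L) next
      z <- as.numeric(scale(mz[idx]))
      r <- rFor[[part]]
      latent[gi, idx] <- r * matrix(z, length(gi), length(idx), byrow = TRUE) +
        sqrt(1 - r^2) * eps[gi, idx, drop = FALSE]
    }
    truth$axis <- list(mirna = ax$mirna, targets = ax$targets,
                       rLow = ax$rLow, rHigh = ax$rHigh,
                       lowSamples = samples[strata$low],
                       highSamples = samples[strata$high])
  }

  geneMat <- muG + sdv * latent
  dimnames(geneMat) <- list(genes, samples)

  if (!is.null(spec$plantedOutliers)) {
    ol <- spec$plantedOutliers
    kT <- round(ol$tumorFraction * nT)
    gi <- match(ol$genes, genes)
    hitSamples <- vector("list", length(gi))
    for (j in seq_along(gi)) {
      hit <- sample(tumorIdx, kT)
      sgn <- sample(c(-1, 1), 1L)
      geneMat[gi[j], hit] <- geneMat[gi[j], hit] + sgn * ol$zEffect * sdv
      hitSamples[[j]] <- samples[sort(hit)]
    }
    names(hitSamples) <- ol$genes
    truth$outliers <- list(genes = ol$genes, zEffect = ol$zEffect,
                           tumorFraction = ol$tumorFraction,
                           hitSamples = hitSamples)
  }

  inSubgroup <- rep(FALSE, nT)
  hr <- 1
  if (!is.null(spec$plantedSurvival)) {
    sv <- spec$plantedSurvival
    hr <- sv$hazardRatio
    kS <- round(sv$subgroupFraction * nT)
    sub <- sort(sample(tumorIdx, kS))
    inSubgroup[sub] <- TRUE
    gi <- match(sv$genes, genes)
    geneMat[gi, sub] <- geneMat[gi, sub] + sv$exprShift * sdv
    truth$survival <- list(genes = sv$genes, hazardRatio = hr,
                           eventFraction = sv$eventFraction,
                           subgroupSamples = samples[sub])
  }

  eventFraction <- if (is.null(spec$plantedSurvival)) 0.4 else
    spec$plantedSurvival$eventFraction
  # solve the baseline exponential rate so E[event fraction] at the horizon
  # matches, averaging over subgroup membership
  lam0 <- uniroot(function(l)
    mean(1 - exp(-l * ifelse(inSubgroup, hr, 1) * horizon)) - eventFraction,
    interval = c(1e-8, 10))$root
  rate <- lam0 * ifelse(inSubgroup, hr, 1)
  tEvent <- rexp(nT, rate)
  dfsTime <- pmin(tEvent, horizon)
  dfsEvent <- as.integer(tEvent <= horizon)

  probsFor <- function(sub) {
    p <- if (sub) spec$gleasonProbs$subgroup else spec$gleasonProbs$base
    sample(as.integer(names(p)), 1L, prob = p)
  }
  gleason <- vapply(inSubgroup, probsFor, integer(1))

  clin <- S4Vectors::DataFrame(
    role = rep(c("tumor", "normal"), c(nT, nN)),
    age = round(runif(n, 45, 75)),
    gleason_sum = c(gleason, rep(NA_integer_, nN)),
    dfs_time = c(dfsTime, rep(NA_real_, nN)),
    dfs_event = c(dfsEvent, rep(NA_integer_, nN)),
    row.names = samples)

  se <- function(m) SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = m), colData = clin)
  new("SimulatedCohort", genes = se(geneMat), mirnas = se(mirnaMat),
      truth = truth)
}
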