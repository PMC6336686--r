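#' @import methods
#' @importFrom stats rnorm runif rbinom rexp quantile sd cor median
#'   pnorm pt phyper p.adjust ks.test t.test chisq.test glm binom.test
#'   anova as.dist dist hclust cutree complete.cases setNames
#'   binomial uniroot ecdf
NULL

#' Result of a resampling (bootstrap) significance test
#'
#' Container for an observed statistic, its resampled null distribution and
#' the add-one empirical p-value
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + B)} for upper-tail tests.
#' The add-one rule guarantees the empirical p is never zero.
#'
#' @slot observed numeric(1), observed value of the test statistic.
#' @slot null numeric vector of resampled null statistics.
#' @slot nResamples integer(1), number of resamples \eqn{B}.
#' @slot pEmpirical numeric(1) in (0, 1], add-one empirical p-value.
#' @slot seed integer(1), RNG seed used to build the null.
#' @slot statistic character(1), label of the statistic resampled.
#'
#' @seealso [bootstrapExpressionAssociation()], [mirnaSetElevationTest()]
#' @export
setClass("EmpiricalTestResult",
  representation(
    observed   = "numeric",
    null       = "numeric",
    nResamples = "integer",
    pEmpirical = "numeric",
    seed       = "integer",
    statistic  = "character"
  )
)

setValidity("EmpiricalTestResult", function(object) {
  msg <- character()
  if (length(object@observed) != 1L || !is.finite(object@observed))
    msg <- c(msg, "'observed' must be a single finite number")
  if (length(object@null) != object@nResamples)
    msg <- c(msg, "'null' length must equal 'nResamples'")
  expected <- (1 + sum(object@null >= object@observed)) /
    (1 + object@nResamples)
  if (length(object@pEmpirical) != 1L ||
      abs(object@pEmpirical - expected) > 1e-12)
    msg <- c(msg, "'pEmpirical' must satisfy the add-one rule (1+b)/(1+B)")
  if (object@pEmpirical <= 0 || object@pEmpirical > 1)
    msg <- c(msg, "'pEmpirical' must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn EmpiricalTestResult compact display
#' @param object an `EmpiricalTestResult`
#' @export
setMethod("show", "EmpiricalTestResult", function(object) {
  cat("EmpiricalTestResult\n")
  cat("  statistic:  ", object@statistic, "\n", sep = "")
  cat("  observed:   ", format(object@observed, digits = 5), "\n", sep = "")
  cat("  resamples:  ", object@nResamples, "\n", sep = "")
  cat("  p.empirical:", format(object@pEmpirical, digits = 5),
      " (add-one rule, seed ", object@seed, ")\n", sep = "")
})

#' @rdname EmpiricalTestResult-accessors
#' @param x an `EmpiricalTestResult`
#' @return `observedStat()` the observed statistic; `nullStats()` the
#'   resampled null vector; `pEmpirical()` the add-one empirical p-value.
#' @export
observedStat <- function(x) {
  stopifnot(is(x, "EmpiricalTestResult"))
  x@observed
}

#' @rdname EmpiricalTestResult-accessors
#' @export
nullStats <- function(x) {
  stopifnot(is(x, "EmpiricalTestResult"))
  x@null
}

#' @rdname EmpiricalTestResult-accessors
#' @export
pEmpirical <- function(x) {
  stopifnot(is(x, "EmpiricalTestResult"))
  x@pEmpirical
}

# internal constructor enforcing the add-one rule
newEmpiricalTestResult <- function(observed, null, seed, statistic) {
  new("EmpiricalTestResult",
      observed   = observed,
      null       = as.numeric(null),
      nResamples = length(null),
      pEmpirical = (1 + sum(null >= observed)) / (1 + length(null)),
      seed       = as.integer(seed),
      statistic  = statistic)
}

#' Simulated tumor/normal cohort with planted ground truth
#'
#' Holds a gene-level and a miRNA-level [SummarizedExperiment] (log2-scale
#' expression, clinical covariates in `colData`) plus the list of planted
#' effects the generator realised, so downstream recovery can be scored
#' against ground truth.
#'
#' @slot genes SummarizedExperiment of gene expression (assay "log2expr").
#' @slot mirnas SummarizedExperiment of miRNA expression (assay "log2expr").
#' @slot truth list describing planted effects (axis correlations, outlier
#'   genes and tumor subsets, survival subgroup and hazard ratio).
#'
#' @seealso [simulateCohort()], [cohortSpec()]
#' @export
setClass("SimulatedCohort",
  representation(
    genes  = "SummarizedExperiment",
    mirnas = "SummarizedExperiment",
    truth  = "list"
  )
)

setValidity("SimulatedCohort", function(object) {
  msg <- character()
  if (!identical(colnames(object@genes), colnames(object@mirnas)))
    msg <- c(msg, "gene and miRNA experiments must share samples")
  cd <- SummarizedExperiment::colData(object@genes)
  need <- c("role", "age", "gleason_sum", "dfs_time", "dfs_event")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulatedCohort compact display
#' @param object a `SimulatedCohort`
#' @export
setMethod("show", "SimulatedCohort", function(object) {
  cd <- SummarizedExperiment::colData(object@genes)
  cat("SimulatedCohort\n")
  cat("  genes:  ", nrow(object@genes), " x ", ncol(object@genes), "\n",
      sep = "")
  cat("  miRNAs: ", nrow(object@mirnas), " x ", ncol(object@mirnas), "\n",
      sep = "")
  cat("  tumors/normals: ", sum(cd$role == "tumor"), "/",
      sum(cd$role == "normal"), "\n", sep = "")
  cat("  planted: ", paste(names(object@truth), collapse = ", "), "\n",
      sep = "")
})

#' @rdname SimulatedCohort-accessors
#' @param x a `SimulatedCohort`
#' @return `geneExpr()`/`mirnaExpr()` the log2 expression matrices;
#'   `clinicalTable()` the clinical data.frame (one row per sample);
#'   `cohortTruth()` the planted ground-truth list.
#' @export
geneExpr <- function(x) {
  stopifnot(is(x, "SimulatedCohort"))
  SummarizedExperiment::assay(x@genes, "log2expr")
}

#' @rdname SimulatedCohort-accessors
#' @export
mirnaExpr <- function(x) {
  stopifnot(is(x, "SimulatedCohort"))
  SummarizedExperiment::assay(x@mirnas, "log2expr")
}

#' @rdname SimulatedCohort-accessors
#' @export
clinicalTable <- function(x) {
  stopifnot(is(x, "SimulatedCohort"))
  cd <- as.data.frame(SummarizedExperiment::colData(x@genes))
  cd$sample <- rownames(cd)
  rownames(cd) <- NULL
  cd[, c("sample", setdiff(colnames(cd), "sample"))]
}

#' @rdname SimulatedCohort-accessors
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "SimulatedCohort"))
  x@truth
}
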