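#' Consensus miRNA targets from a prediction vote matrix
#'
#' Keeps (miRNA, gene) interactions positively predicted by at least
#' `minVotes` of the prediction algorithms (classically 5 of 9).
#'
#' @param votes data.frame with columns mirna, gene, votes (integer count
#'   of algorithms predicting the interaction).
#' @param minVotes inclusive vote threshold (default 5).
#' @param nAlgorithms total algorithms voting (default 9); votes above
#'   this raise an error.
#' @return named list: per miRNA, the character vector of consensus
#'   target genes.
#' @examples
#' v <- data.frame(mirna = "miR-96", gene = c("RARG", "TACC1", "CDH1"),
#'                 votes = c(9, 5, 4))
#' consensusTargets(v)   # CDH1 (4 votes) is dropped
#' @export
consensusTargets <- function(votes, minVotes = 5L, nAlgorithms = 9L) {
  need <- c("mirna", "gene", "votes")
  if (!all(need %in% colnames(votes)))
    stop("'votes' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(votes$votes < 0 | votes$votes > nAlgorithms))
    stop("votes must lie in [0, ", nAlgorithms, "]", call. = FALSE)
  kept <- votes[votes$votes >= minVotes, ]
  lapply(split(kept$gene, kept$mirna), unique)
}

#' Bootstrap test for coordinate elevation of a miRNA candidate set
#'
#' Asks whether a candidate miRNA set is more elevated in tumors than
#' randomly drawn sets of the same size: the observed statistic is the
#' mean per-miRNA elevation (tumor-vs-normal log2FC, or a -log10 p
#' significance score), the null is built by sampling with replacement
#' from the full miRNA universe, and the add-one empirical p is reported.
#'
#' @param mirnaDe data.frame with columns mirna and the statistic column
#'   (`log2FC` and/or `p`).
#' @param candidateSet character vector of candidate miRNA ids.
#' @param nResamples bootstrap resamples (default 1e5).
#' @param seed integer RNG seed.
#' @param statistic `"log2FC"` (default) or `"negLog10P"`.
#' @return an [EmpiricalTestResult-class].
#' @export
mirnaSetElevationTest <- function(mirnaDe, candidateSet, nResamples = 1e5,
                                  seed = 1L,
                                  statistic = c("log2FC", "negLog10P")) {
  statistic <- match.arg(statistic)
  if (!length(candidateSet))
    stop("'candidateSet' is empty", call. = FALSE)
  if (!all(candidateSet %in% mirnaDe$mirna))
    stop("candidate miRNAs missing from the universe", call. = FALSE)
  vals <- if (statistic == "log2FC") mirnaDe$log2FC
          else -log10(mirnaDe$p)
  k <- length(unique(candidateSet))
  observed <- mean(vals[match(unique(candidateSet), mirnaDe$mirna)])
  set.seed(as.integer(seed))
  B <- as.integer(nResamples)
  null <- rowMeans(matrix(vals[sample.int(length(vals), B * k,
                                          replace = TRUE)], B, k))
  newEmpiricalTestResult(observed, null, seed, paste0("mean ", statistic))
}

#' Call a miRNA targetome from biotin-pulldown enrichment
#'
#' A gene is a direct target if it is significantly enriched in the
#' targeting-mimic pulldown over input (`FC > fcMin`, strict, and
#' `padj < padjMax`) and *not* enriched under the same rule in the
#' non-targeting control pulldown.
#'
#' @param pulldown data.frame with columns gene, log2FC_mir, padj_mir
#'   (targeting mimic) and log2FC_ctl, padj_ctl (control mimic).
#' @param fcMin linear fold-change threshold, strict (default 1.2).
#' @param padjMax adjusted-p threshold, strict (default 0.05).
#' @return character vector of targetome gene ids.
#' @examples
#' pd <- data.frame(gene = c("a", "b"), log2FC_mir = c(1, 1),
#'                  padj_mir = c(0.01, 0.01),
#'                  log2FC_ctl = c(0, 1), padj_ctl = c(0.9, 0.01))
#' callPulldownTargets(pd)   # "b" is enriched in the control too
#' @export
callPulldownTargets <- function(pulldown, fcMin = 1.2, padjMax = 0.05) {
  need <- c("gene", "log2FC_mir", "padj_mir", "log2FC_ctl", "padj_ctl")
  missing <- setdiff(need, colnames(pulldown))
  if (length(missing))
    stop("pulldown table missing column(s): ",
         paste(missing, collapse = ", "),
         if ("log2FC_ctl" %in% missing || "padj_ctl" %in% missing)
           " (the non-targeting control contrast is required)",
         call. = FALSE)
  lfcMin <- log2(fcMin)
  hitMir <- pulldown$log2FC_mir > lfcMin & pulldown$padj_mir < padjMax
  hitCtl <- pulldown$log2FC_ctl > lfcMin & pulldown$padj_ctl < padjMax
  pulldown$gene[hitMir & !hitCtl]
}

#' Split a cohort at the lower and upper quartile of a marker
#'
#' Returns the `floor(n/4)` samples with the smallest values and the
#' `floor(n/4)` with the largest, ties broken by stable sample order.
#'
#' @param values named numeric vector (names = sample ids).
#' @return list with `low`, `high` (sample-id vectors), `variable`
#'   (attribute name, optional) and the stratum sizes.
#' @examples
#' quartileStratify(setNames(1:8, letters[1:8]))
#' @export
quartileStratify <- function(values) {
  if (length(values) < 8L)
    stop("need at least 8 samples to form quartile strata", call. = FALSE)
  if (is.null(names(values)))
    names(values) <- as.character(seq_along(values))
  if (length(unique(values)) == 1L)
    stop("all values equal: quartile strata are undefined", call. = FALSE)
  n <- length(values)
  k <- as.integer(n %/% 4)
  ord <- order(values, seq_along(values))
  list(low = names(values)[sort(ord[seq_len(k)])],
       high = names(values)[sort(ord[seq.int(n - k + 1L, n)])],
       sizeLow = k, sizeHigh = k)
}

#' Correlation shift of a network gene between two cohort strata
#'
#' For each dependent gene, computes the Pearson correlation with the
#' network gene separately in the low and high strata (BH q-values within
#' stratum), keeps genes significant in at least one stratum, and
#' classifies the change from high to low stratum:
#' \describe{
#'   \item{switched}{both correlations significant with opposite signs;}
#'   \item{strengthened}{|r_low| > |r_high| with the same sign, or
#'     significance gained in the low stratum;}
#'   \item{weakened}{|r_low| < |r_high| with the same sign, or
#'     significance lost;}
#'   \item{unchanged}{otherwise.}
#' }
#' A Welch two-sample t-test then compares the correlation strengths of
#' the positive-strengthened group against the negative-weakened group.
#' Strength means the *magnitude* |r_low| (optionally Fisher
#' z-transformed): comparing signed r between a positive and a negative
#' group would be significant even when no shift exists, whereas the
#' magnitude comparison is calibrated under a no-shift null.
#'
#' @param networkGene gene id whose correlations are examined.
#' @param dependentGenes character vector of genes to correlate against.
#' @param expr genes x samples log2 expression matrix containing both.
#' @param strata list with `low`/`high` sample ids
#'   (see [quartileStratify()]).
#' @param qMax per-stratum BH q threshold for a significant correlation
#'   (default 0.1).
#' @param fisherZ compare Fisher z-transformed magnitudes in the Welch
#'   test.
#' @return list with `table` (data.frame: gene, r_low, q_low, r_high,
#'   q_high, delta = r_low - r_high, class) and `welch` (estimate
#'   difference, p, group sizes; `inestimable` when either group has
#'   fewer than 2 genes).
#' @export
correlationShift <- function(networkGene, dependentGenes, expr, strata,
                             qMax = 0.1, fisherZ = FALSE) {
  stopifnot(networkGene %in% rownames(expr))
  dependentGenes <- setdiff(unique(dependentGenes), networkGene)
  if (!all(dependentGenes %in% rownames(expr)))
    stop("dependent genes missing from 'expr'", call. = FALSE)
  if (length(strata$low) < 10L || length(strata$high) < 10L)
    stop("each stratum needs at least 10 samples", call. = FALSE)

  corIn <- function(samples) {
    x <- expr[networkGene, samples]
    r <- as.numeric(cor(x, t(expr[dependentGenes, samples, drop = FALSE])))
    q <- p.adjust(corPvalue(r, length(samples)), "BH")
    list(r = r, q = q)
  }
  lo <- corIn(strata$low)
  hi <- corIn(strata$high)

  sigLo <- lo$q < qMax; sigHi <- hi$q < qMax
  keep <- sigLo | sigHi
  rL <- lo$r[keep]; rH <- hi$r[keep]
  qL <- lo$q[keep]; qH <- hi$q[keep]
  sL <- sigLo[keep]; sH <- sigHi[keep]

  cls <- rep("unchanged", sum(keep))
  sameSign <- sign(rL) == sign(rH)
  cls[sL & sH & !sameSign] <- "switched"
  # significance gained/lost dominates the magnitude comparison: a
  # correlation that emerges in (or vanishes from) one stratum changed
  # strength regardless of the noise-level sign in the other stratum
  strengthened <- (sL & !sH) | (abs(rL) > abs(rH) & sameSign)
  weakened <- (!sL & sH) | (abs(rL) < abs(rH) & sameSign)
  cls[cls == "unchanged" & strengthened] <- "strengthened"
  cls[cls == "unchanged" & weakened] <- "weakened"

  tab <- data.frame(gene = dependentGenes[keep], r_low = rL, q_low = qL,
                    r_high = rH, q_high = qH, delta = rL - rH,
                    class = cls, row.names = NULL)

  strength <- if (fisherZ) atanh(pmin(abs(tab$r_low), 0.999999))
              else abs(tab$r_low)
  posStr <- strength[tab$r_low > 0 & tab$class == "strengthened"]
  negWk <- strength[tab$r_low < 0 & tab$class == "weakened"]
  welch <- if (length(posStr) < 2L || length(negWk) < 2L) {
    list(inestimable = TRUE, nPositiveStrengthened = length(posStr),
         nNegativeWeakened = length(negWk), estimate = NA_real_,
         p = NA_real_)
  } else {
    tt <- t.test(posStr, negWk)
    list(inestimable = FALSE, nPositiveStrengthened = length(posStr),
         nNegativeWeakened = length(negWk),
         estimate = unname(diff(rev(tt$estimate))), p = tt$p.value)
  }
  list(table = tab, welch = welch)
}

#' Differential expression between two sample groups by Welch t-test
#'
#' Per-gene Welch t-test on log2 expression between two disjoint sample
#' groups, BH-adjusted; the output uses the standard DE-table schema so it
#' composes directly with [callDEGs()] and downstream set tests.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param groupA,groupB disjoint sample-id vectors, each of size >= 3.
#' @param contrast label recorded in the table.
#' @return DE table (gene, log2FC = meanA - meanB, SE, p, padj, contrast).
#' @export
axisDifferentialExpression <- function(expr, groupA, groupB,
                                       contrast = "groupA_vs_groupB") {
  if (length(intersect(groupA, groupB)))
    stop("'groupA' and 'groupB' overlap", call. = FALSE)
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs at least 3 samples", call. = FALSE)
  if (!all(c(groupA, groupB) %in% colnames(expr)))
    stop("group samples missing from 'expr'", call. = FALSE)
  w <- rowWelch(expr[, groupA, drop = FALSE], expr[, groupB, drop = FALSE])
  data.frame(gene = rownames(expr), log2FC = w$log2FC, SE = w$SE, p = w$p,
             padj = p.adjust(w$p, "BH"), contrast = contrast,
             row.names = NULL)
}

#' Pairwise correlation matrix across genes and miRNAs
#'
#' Pearson correlations among the requested features over the shared
#' samples of one or two expression matrices, with BH q-values on the
#' off-diagonal entries. Zero-variance features are flagged (NA entries).
#'
#' @param features character vector of feature ids to correlate.
#' @param expr genes x samples matrix; `mirnaExpr` optionally supplies
#'   features not found in `expr`.
#' @param mirnaExpr optional second (miRNA) matrix sharing samples.
#' @return list with `r` (symmetric correlation matrix, unit diagonal),
#'   `q` (BH q matrix, NA diagonal) and `flagged` (zero-variance
#'   features).
#' @export
correlationMatrix <- function(features, expr, mirnaExpr = NULL) {
  pull <- function(f) {
    if (f %in% rownames(expr)) expr[f, , drop = TRUE]
    else if (!is.null(mirnaExpr) && f %in% rownames(mirnaExpr))
      mirnaExpr[f, colnames(expr), drop = TRUE]
    else stop("feature not found: ", f, call. = FALSE)
  }
  if (!is.null(mirnaExpr)) {
    shared <- intersect(colnames(expr), colnames(mirnaExpr))
    if (!length(shared))
      stop("no shared samples between the matrices", call. = FALSE)
    expr <- expr[, shared, drop = FALSE]
    mirnaExpr <- mirnaExpr[, shared, drop = FALSE]
  }
  m <- t(vapply(features, pull, numeric(ncol(expr))))
  flagged <- features[apply(m, 1L, sd) == 0]
  r <- suppressWarnings(cor(t(m)))
  diag(r) <- 1
  n <- ncol(expr)
  q <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  off <- upper.tri(r)
  p <- corPvalue(r[off], n)
  q[off] <- p.adjust(p, "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(r = r, q = q, flagged = flagged)
}
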