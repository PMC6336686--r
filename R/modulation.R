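#' Call differentially expressed genes at fold-change and adjusted-p
#' thresholds
#'
#' The conventional DEG rule: adjusted p strictly below `padjMax` and
#' |log2FC| at least `log2(foldChangeLinear)`. The fold-change boundary is
#' inclusive (a gene at exactly 1.2-fold passes), the adjusted-p boundary
#' exclusive.
#'
#' @param de DE table (gene, log2FC, SE, p, padj).
#' @param foldChangeLinear linear fold-change threshold (default 1.2).
#' @param padjMax adjusted-p threshold (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @examples
#' de <- data.frame(gene = c("a", "b"), log2FC = c(log2(1.2), 0.5),
#'                  SE = 0.1, p = c(0.001, 0.05), padj = c(0.049, 0.05))
#' callDEGs(de)   # "a" is up; "b" fails the padj rule
#' @export
callDEGs <- function(de, foldChangeLinear = 1.2, padjMax = 0.05) {
  assertDETable(de)
  if (foldChangeLinear < 1)
    stop("'foldChangeLinear' must be >= 1", call. = FALSE)
  lfcMin <- log2(foldChangeLinear)
  ok <- de$padj < padjMax
  list(up   = de$gene[ok & de$log2FC >=  lfcMin],
       down = de$gene[ok & de$log2FC <= -lfcMin])
}

#' Classify how knockdown reshapes a hormone response
#'
#' Compares the hormone-vs-vehicle response of each control-condition DEG
#' against its response under regulator knockdown, and classifies genes as
#' dampened (same-sign, significantly smaller effect under knockdown),
#' lost (significant interaction with sign disagreement or a sub-threshold
#' knockdown effect), gained (DEG under knockdown only) or unchanged. The
#' interaction test is a z-test on the log2FC difference with pooled
#' standard errors, `z = (lfc_ctl - lfc_kd) / sqrt(SE_ctl^2 + SE_kd^2)`,
#' BH-adjusted across the control DEG universe. Genes whose knockdown
#' effect is significantly *larger* (amplified) are coded `unchanged` with
#' a negative delta.
#'
#' @param ctl DE table for hormone vs vehicle in control cells.
#' @param kd DE table for hormone vs vehicle in knockdown cells.
#' @param foldChangeLinear,padjMax DEG thresholds (see [callDEGs()]).
#' @param alphaInteraction significance level for the adjusted interaction
#'   p (default 0.05).
#' @return list with `calls` (data.frame: gene, category, lfc_control,
#'   lfc_knockdown, delta, p_interaction, padj_interaction) and `summary`
#'   (counts per category, the dampened fraction of control DEGs, and a
#'   directional-consistency sign test on the significant interactions).
#' @examples
#' ctl <- data.frame(gene = "g", log2FC = 2, SE = 0.1, p = 1e-8, padj = 1e-8)
#' kd  <- data.frame(gene = "g", log2FC = 1, SE = 0.1, p = 1e-4, padj = 1e-4)
#' classifyModulation(ctl, kd)$calls
#' @export
classifyModulation <- function(ctl, kd, foldChangeLinear = 1.2,
                               padjMax = 0.05, alphaInteraction = 0.05) {
  assertDETable(ctl, need_se = TRUE, what = "control DE table")
  assertDETable(kd, need_se = TRUE, what = "knockdown DE table")
  shared <- intersect(ctl$gene, kd$gene)
  if (!length(shared))
    stop("control and knockdown tables share no genes", call. = FALSE)
  ctl <- ctl[match(shared, ctl$gene), ]
  kd <- kd[match(shared, kd$gene), ]

  ctlDegs <- callDEGs(ctl, foldChangeLinear, padjMax)
  kdDegs <- callDEGs(kd, foldChangeLinear, padjMax)
  universe <- c(ctlDegs$up, ctlDegs$down)

  i <- match(universe, shared)
  z <- (ctl$log2FC[i] - kd$log2FC[i]) / sqrt(ctl$SE[i]^2 + kd$SE[i]^2)
  pInt <- 2 * pnorm(abs(z), lower.tail = FALSE)
  padjInt <- p.adjust(pInt, "BH")

  lc <- ctl$log2FC[i]; lk <- kd$log2FC[i]
  sameSign <- sign(lc) == sign(lk)
  sig <- padjInt < alphaInteraction
  # decision tree over the control-DEG universe:
  #   not significant                      -> unchanged
  #   significant, same sign, |kd| < |ctl| -> dampened (by control direction)
  #   significant, sign disagreement       -> lost
  #   significant, same sign, |kd| >= |ctl| (amplified) -> unchanged,
  #     reported with negative delta
  category <- rep("unchanged", length(universe))
  damp <- sig & sameSign & abs(lk) < abs(lc)
  category[damp & lc > 0] <- "dampened_induction"
  category[damp & lc < 0] <- "dampened_repression"
  category[sig & !sameSign] <- "lost"
  calls <- data.frame(
    gene = universe, category = category,
    lfc_control = lc, lfc_knockdown = lk, delta = lc - lk,
    p_interaction = pInt, padj_interaction = padjInt, row.names = NULL)

  gained <- setdiff(c(kdDegs$up, kdDegs$down), universe)
  if (length(gained)) {
    j <- match(gained, shared)
    zg <- (ctl$log2FC[j] - kd$log2FC[j]) / sqrt(ctl$SE[j]^2 + kd$SE[j]^2)
    pg <- 2 * pnorm(abs(zg), lower.tail = FALSE)
    calls <- rbind(calls, data.frame(
      gene = gained, category = "gained",
      lfc_control = ctl$log2FC[j], lfc_knockdown = kd$log2FC[j],
      delta = ctl$log2FC[j] - kd$log2FC[j],
      p_interaction = pg, padj_interaction = NA_real_, row.names = NULL))
  }

  nDamp <- sum(calls$category %in% c("dampened_induction",
                                     "dampened_repression"))
  # are the significant interactions one-directional (dampening, not
  # amplification)? sign test on |lfc_kd| < |lfc_ctl| among them
  sigIdx <- which(sig)
  nSig <- length(sigIdx)
  nTowardDamp <- sum(abs(lk[sigIdx]) < abs(lc[sigIdx]))
  signTest <- if (nSig > 0)
    binom.test(nTowardDamp, nSig, p = 0.5, alternative = "greater")$p.value
  else NA_real_

  list(calls = calls,
       summary = list(
         n_control_degs = length(universe),
         counts = table(factor(calls$category,
                               levels = c("dampened_induction",
                                          "dampened_repression", "lost",
                                          "gained", "unchanged"))),
         dampened_fraction = if (length(universe)) nDamp / length(universe)
                             else NA_real_,
         sign_test_p = signTest))
}

#' Partition two DEG sets into shared and exclusive counts
#'
#' The Venn-diagram counts used to compare a hormone response between two
#' backgrounds.
#'
#' @param ctlDegs,kdDegs character vectors of gene ids.
#' @return list with `shared`, `ctlOnly`, `kdOnly` counts and the gene sets.
#' @export
responseVenn <- function(ctlDegs, kdDegs) {
  shared <- intersect(ctlDegs, kdDegs)
  list(shared = length(shared),
       ctlOnly = length(setdiff(ctlDegs, kdDegs)),
       kdOnly = length(setdiff(kdDegs, ctlDegs)),
       sharedGenes = shared)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Classic RT-qPCR fold change: the target gene's Ct is normalised to a
#' reference gene within each condition, and the experimental condition is
#' expressed relative to control:
#' `FC = 2^-((Ct_tgt,exp - Ct_ref,exp) - (Ct_tgt,ctl - Ct_ref,ctl))`.
#'
#' @param ctTargetExp,ctRefExp Ct values of target and reference gene in
#'   the experimental condition.
#' @param ctTargetCtl,ctRefCtl the same in the control condition.
#' @return linear fold change (1 = no change; vectorised).
#' @examples
#' ddctFoldChange(25, 20, 24, 20)  # ddCt = 1 -> 0.5
#' @export
ddctFoldChange <- function(ctTargetExp, ctRefExp, ctTargetCtl, ctRefCtl) {
  stopifnot(all(is.finite(c(ctTargetExp, ctRefExp, ctTargetCtl, ctRefCtl))))
  ddct <- (ctTargetExp - ctRefExp) - (ctTargetCtl - ctRefCtl)
  2^(-ddct)
}
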