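#' Select enriched gene sets from an enrichment table
#'
#' Applies the conventional strict thresholds on normalized enrichment
#' score and FDR q-value (`NES > nesMin` and `fdr_q < qMax`, both strict).
#'
#' @param tbl data.frame with columns set_name, NES, fdr_q (and optionally
#'   direction), one row per set per comparison.
#' @param nesMin minimum NES, strict (default 1.8).
#' @param qMax maximum FDR q, strict (default 0.05).
#' @return character vector of enriched set names.
#' @examples
#' tbl <- data.frame(set_name = c("A_B", "C_D"), NES = c(2.7, 1.8),
#'                   fdr_q = c(0.001, 0.01))
#' selectEnriched(tbl)  # only "A_B": NES must exceed 1.8 strictly
#' @export
selectEnriched <- function(tbl, nesMin = 1.8, qMax = 0.05) {
  need <- c("set_name", "NES", "fdr_q")
  missing <- setdiff(need, colnames(tbl))
  if (length(missing))
    stop("enrichment table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nesMin <= 0) stop("'nesMin' must be > 0", call. = FALSE)
  tbl$set_name[tbl$NES > nesMin & tbl$fdr_q < qMax]
}

#' Default stop tokens for gene-set name mining
#'
#' Collection prefixes and bookkeeping tokens stripped before keyword
#' counting. Direction suffixes ("UP", "DN") are deliberately *not*
#' stopped, since direction-specific meta-groups are informative.
#' @return character vector of upper-case tokens.
#' @export
defaultStopTokens <- function() {
  c("HALLMARK", "GO", "GOBP", "GOMF", "GOCC", "KEGG", "REACTOME",
    "BIOCARTA", "PID", "WP", "GSE", "OF", "THE", "AND", "IN", "TO", "VS")
}

# unique upper-case tokens per set name, stop tokens removed
tokenizeSetNames <- function(names, stopTokens) {
  lapply(strsplit(toupper(names), "_", fixed = TRUE), function(t)
    setdiff(unique(t[nzchar(t)]), stopTokens))
}

#' Mine keyword meta-groups from enriched gene-set names
#'
#' Tokenizes gene-set identifiers on underscores and asks, for every
#' keyword, whether it occurs among the enriched set names more often than
#' its background frequency across all set names predicts: an upper-tail
#' hypergeometric test with `N = |all sets|`, `K` = background sets whose
#' name contains the keyword, `n = |enriched sets|` and `k` = enriched
#' sets containing it, BH-adjusted across keywords. Keywords seen in fewer
#' than `minCount` background names are dropped before adjustment.
#'
#' @param allNames character vector of all gene-set names (the universe).
#'   Duplicates are dropped with a warning.
#' @param enrichedNames subset of `allNames` flagged enriched.
#' @param minCount minimum background occurrence for a keyword to be
#'   tested (default 2).
#' @param stopTokens tokens excluded from mining
#'   (default [defaultStopTokens()]).
#' @return data.frame with columns keyword, n_background, n_enriched, p,
#'   padj, ordered by p.
#' @examples
#' all <- c("TNFA_SIGNALING_UP", "TNFA_TARGETS_DN", "MYC_TARGETS_UP",
#'          "DNA_REPAIR_UP")
#' mineKeywords(all, all[1:2], minCount = 2)
#' @export
mineKeywords <- function(allNames, enrichedNames, minCount = 2,
                         stopTokens = defaultStopTokens()) {
  if (anyDuplicated(allNames)) {
    warning("duplicate set names dropped")
    allNames <- unique(allNames)
  }
  enrichedNames <- unique(enrichedNames)
  if (!all(enrichedNames %in% allNames))
    stop("'enrichedNames' must be a subset of 'allNames'", call. = FALSE)
  empty <- data.frame(keyword = character(), n_background = integer(),
                      n_enriched = integer(), p = numeric(),
                      padj = numeric())
  if (!length(enrichedNames)) {
    warning("empty enriched set: no keywords to mine")
    return(empty)
  }
  tokAll <- tokenizeSetNames(allNames, stopTokens)
  tokEnr <- tokenizeSetNames(enrichedNames, stopTokens)
  bgCount <- table(unlist(tokAll))
  enrCount <- table(unlist(tokEnr))
  keywords <- names(bgCount)[bgCount >= minCount]
  if (!length(keywords)) return(empty)

  N <- length(allNames); n <- length(enrichedNames)
  K <- as.integer(bgCount[keywords])
  k <- as.integer(enrCount[keywords])
  k[is.na(k)] <- 0L
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(keyword = keywords, n_background = K, n_enriched = k,
                    p = p, padj = p.adjust(p, "BH"), row.names = NULL)
  out[order(out$p, out$keyword), ]
}

#' Hypergeometric significance of the overlap of two gene sets
#'
#' Upper-tail hypergeometric test on `|a` \eqn{\cap} `b|` against a stated
#' universe: the p-value is the probability of drawing at least the
#' observed overlap when `|a|` genes are drawn from a universe containing
#' `|b|` marked genes.
#'
#' @param setA,setB character vectors of gene ids.
#' @param universeSize size of the gene universe both sets live in; must
#'   be stated explicitly (at least `|a U b|`).
#' @return list with `kOverlap`, `p`, and the set sizes.
#' @examples
#' geneSetOverlapTest(letters[1:4], letters[3:8], universeSize = 26)
#' @export
geneSetOverlapTest <- function(setA, setB, universeSize) {
  setA <- unique(setA); setB <- unique(setB)
  union <- length(union(setA, setB))
  if (universeSize < union)
    stop("'universeSize' (", universeSize, ") is smaller than |a U b| (",
         union, ")", call. = FALSE)
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1L, length(setB), universeSize - length(setB),
              length(setA), lower.tail = FALSE)
  list(kOverlap = k, p = p, nA = length(setA), nB = length(setB),
       universe = universeSize)
}
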