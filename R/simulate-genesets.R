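#' Simulate a gene-set collection with an enrichment table and a planted
#' keyword meta-group
#'
#' Emulates the input to keyword meta-group mining: gene-set names are
#' underscore-delimited keyword tokens, and an accompanying enrichment
#' table marks a subset of sets as enriched (NES and FDR q generated on
#' either side of the conventional thresholds). The `plantedKeyword` is
#' inserted into enriched-set names at rate `enrichmentRate` and into the
#' remaining names at `backgroundRate`; mining should flag it whenever the
#' two rates differ materially.
#'
#' @param nSets number of gene sets.
#' @param keywordVocab character vector of candidate name tokens.
#' @param plantedKeyword token to over-represent among enriched sets.
#' @param enrichmentRate probability the planted keyword appears in an
#'   enriched set's name.
#' @param backgroundRate probability it appears in a non-enriched name.
#' @param enrichedFraction fraction of sets flagged enriched.
#' @param tokensPerName tokens per set name.
#' @param nGenesPerSet,geneUniverse membership draw for the GMT-style
#'   collection (sizes and the pool of gene ids).
#' @param seed integer RNG seed.
#' @return list with `sets` (named list of gene-id vectors), `enrichment`
#'   (data.frame: set_name, NES, fdr_q, direction) and `truth`
#'   (enriched set names, planted keyword).
#' @examples
#' gs <- simulateGeneSets(nSets = 40, plantedKeyword = "NFKB", seed = 5)
#' head(gs$enrichment)
#' @export
simulateGeneSets <- function(nSets = 300L,
                             keywordVocab = defaultKeywordVocab(),
                             plantedKeyword = "NFKB",
                             enrichmentRate = 0.8,
                             backgroundRate = 0.1,
                             enrichedFraction = 0.1,
                             tokensPerName = 3L,
                             nGenesPerSet = 25L,
                             geneUniverse = geneIds(2000L),
                             seed = 1L) {
  nSets <- checkCount(nSets, "nSets", 1L)
  if (!length(keywordVocab))
    failField("keywordVocab", "vocabulary must be non-empty")
  checkFraction(enrichmentRate, "enrichmentRate")
  checkFraction(backgroundRate, "backgroundRate")
  checkFraction(enrichedFraction, "enrichedFraction")
  set.seed(checkCount(seed, "seed"))

  vocab <- setdiff(toupper(keywordVocab), toupper(plantedKeyword))
  if (length(vocab) < tokensPerName)
    failField("keywordVocab", "too few distinct tokens for the name length")

  nEnr <- max(1L, round(enrichedFraction * nSets))
  enriched <- seq_len(nEnr)   # first nEnr sets enriched; names carry no order info
  hasKw <- logical(nSets)
  hasKw[enriched] <- runif(nEnr) < enrichmentRate
  hasKw[-enriched] <- runif(nSets - nEnr) < backgroundRate

  names <- vapply(seq_len(nSets), function(i) {
    toks <- sample(vocab, tokensPerName)
    if (hasKw[i]) toks[sample.int(tokensPerName, 1L)] <- toupper(plantedKeyword)
    paste(toks, collapse = "_")
  }, character(1))
  names <- make.unique(names, sep = "_V")

  nes <- numeric(nSets); q <- numeric(nSets)
  nes[enriched] <- runif(nEnr, 1.9, 3.0)
  q[enriched] <- runif(nEnr, 0, 0.04)
  nes[-enriched] <- runif(nSets - nEnr, 0.4, 1.7)
  q[-enriched] <- runif(nSets - nEnr, 0.06, 1)
  direction <- sample(c("up", "down"), nSets, replace = TRUE)

  sets <- lapply(seq_len(nSets), function(i)
    sample(geneUniverse, min(nGenesPerSet, length(geneUniverse))))
  names(sets) <- names

  list(sets = sets,
       enrichment = data.frame(set_name = names, NES = nes, fdr_q = q,
                               direction = direction),
       truth = list(enriched = names[enriched],
                    plantedKeyword = toupper(plantedKeyword),
                    hasKeyword = names[hasKw]))
}

#' Default token vocabulary for simulated gene-set names
#'
#' Biology-flavoured tokens of the kind found in curated gene-set
#' identifiers, used by [simulateGeneSets()].
#' @return character vector of upper-case tokens.
#' @export
defaultKeywordVocab <- function() {
  c("ANDROGEN", "RESPONSE", "TARGETS", "SIGNALING", "PATHWAY", "CELL",
    "CYCLE", "APOPTOSIS", "HYPOXIA", "MYC", "E2F", "P53", "ESTROGEN",
    "EPITHELIAL", "MESENCHYMAL", "TRANSITION", "INFLAMMATORY", "TNFA",
    "INTERFERON", "GAMMA", "ALPHA", "BETA", "METABOLISM", "GLYCOLYSIS",
    "OXIDATIVE", "PHOSPHORYLATION", "DNA", "REPAIR", "REPLICATION",
    "CHECKPOINT", "MITOTIC", "SPINDLE", "PROSTATE", "CANCER", "TUMOR",
    "SUPPRESSOR", "KINASE", "RECEPTOR", "NUCLEAR", "CHROMATIN",
    "REMODELING", "METHYLATION", "ACETYLATION", "STEM", "DIFFERENTIATION",
    "PROLIFERATION", "MIGRATION", "ADHESION", "JUNCTION", "SECRETION",
    "UP", "DN", "EARLY", "LATE", "INDUCED", "REPRESSED")
}
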