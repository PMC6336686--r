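grFrom <- function(chrom, start1, end1, name = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
  if (!is.null(name)) g$name <- name
  g
}

test_that("a TSS inside a peak annotates at distance zero", {
  pk <- grFrom("chr1", 1001, 1200, "pk1")   # BED [1000,1200)
  tss <- data.frame(gene = "g1", chrom = "chr1", strand = "+", tss = 1100)
  map <- annotatePeaksToTSS(pk, tss, window = 7500)
  expect_identical(nrow(map), 1L)
  expect_identical(map$distance, 0)
})

test_that("the window boundary follows the gap convention", {
  pk <- grFrom("chr1", 10001, 10100)        # BED [10000,10100)
  tssNear <- data.frame(gene = "g", chrom = "chr1", strand = "+", tss = 2500)
  tssFar <- data.frame(gene = "g", chrom = "chr1", strand = "+", tss = 2499)
  expect_identical(nrow(annotatePeaksToTSS(pk, tssNear, 7500)), 1L)  # gap 7500
  expect_identical(nrow(annotatePeaksToTSS(pk, tssFar, 7500)), 0L)   # gap 7501
})

test_that("signed distance is strand-aware", {
  pk <- grFrom("chr1", 2001, 2100)
  tss <- data.frame(gene = c("plus", "minus"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(1000, 1000))
  map <- annotatePeaksToTSS(pk, tss, 7500)
  # peak lies at larger coordinates: downstream of a + gene, upstream of a -
  expect_gt(map$distance[map$gene == "plus"], 0)
  expect_lt(map$distance[map$gene == "minus"], 0)
})

test_that("annotation equals the exhaustive all-pairs scan", {
  for (s in 1:5) {
    set.seed(s)
    n <- 20; m <- 10
    pk <- grFrom(sample(c("chr1", "chr2"), n, TRUE),
                 st <- sample.int(50000, n), st + sample(50:500, n, TRUE),
                 name = sprintf("p%02d", 1:n))
    tss <- data.frame(gene = sprintf("g%02d", 1:m),
                      chrom = sample(c("chr1", "chr2"), m, TRUE),
                      strand = sample(c("+", "-"), m, TRUE),
                      tss = sample.int(50000, m))
    map <- annotatePeaksToTSS(pk, tss, window = 7500)
    oracle <- bruteAnnotate(pk, tss, window = 7500)
    key <- function(p, g) paste(p, g)
    expect_setequal(key(map$peak, map$gene), key(oracle$peak, oracle$gene))
    i <- match(key(map$peak, map$gene), key(oracle$peak, oracle$gene))
    expect_equal(abs(map$distance), oracle$d[i])
  }
})

test_that("an empty TSS table yields an empty map with a warning", {
  pk <- grFrom("chr1", 1, 100)
  expect_warning(map <- annotatePeaksToTSS(
    pk, data.frame(gene = character(), chrom = character(),
                   strand = character(), tss = numeric())), "empty")
  expect_identical(nrow(map), 0L)
})

test_that("overlap significance: identity, disjointness and symmetry", {
  a <- grFrom("chr1", c(1, 1000, 5000), c(100, 1100, 5100))
  ident <- overlapSignificance(a, a, universe = 1000)
  expect_identical(ident$nOverlap, 3L)
  b <- grFrom("chr9", c(1, 1000), c(100, 1100))
  expect_identical(overlapSignificance(a, b, universe = 1000)$nOverlap, 0L)
  expect_identical(overlapSignificance(a, b, universe = 1000)$nOverlap,
                   overlapSignificance(b, a, universe = 1000)$nOverlap)
  expect_error(overlapSignificance(a, b, universe = 3), "universe")
})

test_that("maxGap controls which gaps count as overlap", {
  a <- grFrom("chr1", 1000, 1100)
  b <- grFrom("chr1", 1601, 1700)   # gap of 500 bases between them
  expect_identical(overlapSignificance(a, b, maxGap = 500,
                                       universe = 100)$nOverlap, 1L)
  expect_identical(overlapSignificance(a, b, maxGap = 499,
                                       universe = 100)$nOverlap, 0L)
})

test_that("hypergeometric overlap p equals exact subset enumeration", {
  # spec's worked case: universe 10, |a| = 4, |b| = 5, overlap 4
  expect_equal(phyper(3, 5, 5, 4, lower.tail = FALSE),
               choose(4, 4) * choose(6, 1) / choose(10, 5),
               tolerance = 1e-14)
  for (case in list(c(10, 4, 5, 2), c(12, 6, 4, 3), c(8, 3, 3, 1),
                    c(12, 5, 7, 5), c(9, 4, 4, 0))) {
    N <- case[1]; nA <- case[2]; nB <- case[3]; k <- case[4]
    expect_equal(phyper(k - 1, nB, N - nB, nA, lower.tail = FALSE),
                 enumHyperP(N, nA, nB, k), tolerance = 1e-12)
  }
})

test_that("bootstrap association: extreme sets approach the add-one floor", {
  set.seed(1)
  de <- makeDeTable(geneIds(50), rnorm(50, sd = 0.5))
  top <- de$gene[order(-abs(de$log2FC))][1:3]
  res <- bootstrapExpressionAssociation(top, de, nResamples = 1e5, seed = 2)
  # the exact floor 1/(B+1) is unattainable with a with-replacement null
  # (repeated draws of the top gene can tie or exceed the top-k mean), but
  # an extreme set must land within an order of magnitude of it
  expect_gte(pEmpirical(res), 1 / (1e5 + 1))
  expect_lt(pEmpirical(res), 1e-3)
  # and the add-one identity holds against the stored null
  expect_identical(pEmpirical(res),
                   (1 + sum(nullStats(res) >= observedStat(res))) / (1e5 + 1))
  expect_s4_class(res, "EmpiricalTestResult")
})

test_that("bootstrap empirical p matches full enumeration within 0.02", {
  set.seed(7)
  de <- makeDeTable(geneIds(10), rnorm(10))
  pick <- geneIds(10)[c(2, 5, 9)]
  res <- bootstrapExpressionAssociation(pick, de, nResamples = 1e5, seed = 3)
  exact <- enumBootP(abs(de$log2FC), 3, observedStat(res))
  expect_lt(abs(pEmpirical(res) - exact), 0.02)
})

test_that("bootstrap is reproducible and p is monotone in the statistic", {
  de <- makeDeTable(geneIds(30), rnorm(30, sd = 0.5), seed = 5)
  r1 <- bootstrapExpressionAssociation(de$gene[1:4], de,
                                       nResamples = 2000, seed = 9)
  r2 <- bootstrapExpressionAssociation(de$gene[1:4], de,
                                       nResamples = 2000, seed = 9)
  expect_identical(nullStats(r1), nullStats(r2))
  expect_identical(pEmpirical(r1), pEmpirical(r2))
  # larger observed statistic, same null -> p can only shrink
  weak <- de$gene[order(abs(de$log2FC))][1:4]
  strong <- de$gene[order(-abs(de$log2FC))][1:4]
  rw <- bootstrapExpressionAssociation(weak, de, nResamples = 2000, seed = 9)
  rs <- bootstrapExpressionAssociation(strong, de, nResamples = 2000, seed = 9)
  expect_gte(pEmpirical(rw), pEmpirical(rs))
  expect_gt(pEmpirical(rw), 0)
  expect_error(bootstrapExpressionAssociation("absent", de,
                                              nResamples = 2000, seed = 1),
               "universe")
  expect_error(bootstrapExpressionAssociation(de$gene[1], de,
                                              nResamples = 10, seed = 1),
               "1000")
})

test_that("correlation distribution test: identity, errors and planted shift", {
  set.seed(11)
  m <- matrix(rnorm(200 * 300), 200, 300, dimnames = list(geneIds(200), NULL))
  focal <- rnorm(300)
  allG <- correlationDistributionTest(focal, geneIds(200), m)
  expect_identical(allG$D, 0)
  expect_error(correlationDistributionTest(rep(1, 300), geneIds(200)[1:5], m),
               "zero-variance")
  # plant r = -0.5 into 50 targets
  m2 <- m
  m2[1:50, ] <- -0.5 * matrix(focal, 50, 300, byrow = TRUE) +
    sqrt(1 - 0.25) * m[1:50, ]
  res <- correlationDistributionTest(focal, geneIds(200)[1:50], m2)
  expect_lt(res$p, 1e-6)
  expect_lt(mean(res$rTargets), -0.3)
})

test_that("KS statistic agrees with the ecdf-difference oracle", {
  set.seed(3)
  m <- matrix(rnorm(40 * 60), 40, 60, dimnames = list(geneIds(40), NULL))
  res <- correlationDistributionTest(rnorm(60), geneIds(40)[1:12], m)
  expect_equal(res$D, bruteKsD(res$rTargets, res$rBackground),
               tolerance = 1e-12)
})
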