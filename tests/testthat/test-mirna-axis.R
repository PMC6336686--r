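test_that("consensus voting keeps interactions at the vote threshold", {
  v <- data.frame(mirna = "miR-96",
                  gene = c("RARG", "TACC1", "CDH1", "FOXO1"),
                  votes = c(9, 5, 4, 7))
  tg <- consensusTargets(v)
  expect_setequal(tg[["miR-96"]], c("RARG", "TACC1", "FOXO1"))  # 5 kept, 4 not
  expect_error(consensusTargets(data.frame(mirna = "m", gene = "g",
                                           votes = 10)), "votes")
  set.seed(3)
  rand <- data.frame(mirna = sample(c("m1", "m2"), 50, TRUE),
                     gene = sample(geneIds(30), 50, TRUE),
                     votes = sample(0:9, 50, TRUE))
  tg2 <- consensusTargets(rand)
  brute <- rand[rand$votes >= 5, ]
  for (m in names(tg2))
    expect_setequal(tg2[[m]], unique(brute$gene[brute$mirna == m]))
})

test_that("elevation bootstrap: extreme set, enumeration match, errors", {
  de <- data.frame(mirna = mirnaIds(8),
                   log2FC = c(3, 2.5, 2, 0.1, -0.2, 0, 0.3, -1),
                   p = rep(0.01, 8))
  top <- mirnaIds(8)[1:3]
  res <- mirnaSetElevationTest(de, top, nResamples = 1e5, seed = 4)
  exact <- enumBootP(de$log2FC, 3, observedStat(res))
  expect_lt(abs(pEmpirical(res) - exact), 0.02)
  expect_gt(pEmpirical(res), 0)
  expect_error(mirnaSetElevationTest(de, character()), "empty")
  expect_error(mirnaSetElevationTest(de, "miR-999"), "universe")
  alt <- mirnaSetElevationTest(de, top, nResamples = 1000, seed = 4,
                               statistic = "negLog10P")
  expect_s4_class(alt, "EmpiricalTestResult")
})

test_that("pulldown target calling subtracts the control mimic", {
  pd <- data.frame(gene = c("both", "mirOnly", "ctlOnly", "boundary", "weak"),
                   log2FC_mir = c(1, 1, 0, log2(1.2), 1),
                   padj_mir = c(0.01, 0.01, 0.9, 0.01, 0.5),
                   log2FC_ctl = c(1, 0, 1, 0, 0),
                   padj_ctl = c(0.01, 0.9, 0.01, 0.9, 0.9))
  expect_identical(callPulldownTargets(pd), "mirOnly")
  expect_error(callPulldownTargets(pd[, 1:3]), "control")
  set.seed(5)
  rand <- data.frame(gene = geneIds(20),
                     log2FC_mir = rnorm(20), padj_mir = runif(20, 0, 0.1),
                     log2FC_ctl = rnorm(20), padj_ctl = runif(20, 0, 0.1))
  brute <- with(rand, gene[(log2FC_mir > log2(1.2) & padj_mir < 0.05) &
                             !(log2FC_ctl > log2(1.2) & padj_ctl < 0.05)])
  expect_identical(callPulldownTargets(rand), brute)
})

test_that("quartile stratification takes floor(n/4) per arm with stable ties", {
  st <- quartileStratify(setNames(1:8, letters[1:8]))
  expect_identical(st$low, c("a", "b"))
  expect_identical(st$high, c("g", "h"))
  big <- quartileStratify(setNames(rnorm(498), sprintf("s%03d", 1:498)))
  expect_identical(st498 <- big$sizeLow, 124L)
  expect_identical(big$sizeHigh, 124L)
  tied <- quartileStratify(setNames(c(1, 1, 1, 1, 2, 2, 2, 2),
                                    letters[1:8]))
  expect_identical(tied$low, c("a", "b"))   # stable order breaks ties
  expect_identical(tied$high, c("g", "h"))
  expect_error(quartileStratify(setNames(rep(1, 8), letters[1:8])),
               "undefined")
  expect_error(quartileStratify(1:5), "at least 8")
})

test_that("identical strata give zero delta and unchanged classes", {
  set.seed(8)
  expr <- matrix(rnorm(20 * 30), 20, 30,
                 dimnames = list(geneIds(20), sprintf("s%02d", 1:30)))
  expr[1, ] <- expr[2, ] * 0.9 + rnorm(30, sd = 0.1)  # ensure a hit
  samples <- colnames(expr)
  # both strata are the same samples, so r_low == r_high exactly
  strata <- list(low = samples[1:15], high = samples[1:15])
  cs <- correlationShift("gene0001", geneIds(20)[-1], expr, strata)
  expect_true(all(cs$table$delta == 0))
  expect_true(all(cs$table$class == "unchanged"))
})

test_that("swapping strata negates delta and swaps the shift classes", {
  sc <- richCohort()
  tr <- cohortTruth(sc)$axis
  clin <- clinicalTable(sc)
  tum <- clin$sample[clin$role == "tumor"]
  strata <- quartileStratify(mirnaExpr(sc)[tr$mirna, tum])
  expr <- geneExpr(sc)[, tum]
  fwd <- correlationShift("gene0001", geneIds(120)[2:40], expr, strata)
  rev <- correlationShift("gene0001", geneIds(120)[2:40], expr,
                          list(low = strata$high, high = strata$low))
  shared <- intersect(fwd$table$gene, rev$table$gene)
  i <- match(shared, fwd$table$gene); j <- match(shared, rev$table$gene)
  expect_equal(fwd$table$delta[i], -rev$table$delta[j], tolerance = 1e-12)
  swap <- c(strengthened = "weakened", weakened = "strengthened",
            switched = "switched", unchanged = "unchanged")
  expect_identical(unname(swap[fwd$table$class[i]]), rev$table$class[j])
})

test_that("a planted correlation shift is recovered with a powered Welch test", {
  g <- geneIds(240)
  sc <- simulateCohort(cohortSpec(
    nTumors = 480, nNormals = 10, nGenes = 240, nMirnas = 2,
    plantedAxis = list(mirna = "miR-001", targets = g[1:100],
                       rLow = c(rep(0.7, 50), rep(-0.1, 50)),
                       rHigh = c(rep(0.1, 50), rep(-0.7, 50))),
    seed = 55))
  clin <- clinicalTable(sc)
  tum <- clin$sample[clin$role == "tumor"]
  strata <- quartileStratify(mirnaExpr(sc)["miR-001", tum])
  cs <- correlationShift("miR-001",
                         g[1:100],
                         rbind(geneExpr(sc), mirnaExpr(sc))[, tum],
                         strata)
  pos <- cs$table[match(g[1:50], cs$table$gene), ]
  pos <- pos[!is.na(pos$gene), ]
  expect_lt(abs(mean(pos$delta) - 0.6), 0.1)
  expect_gt(mean(pos$class == "strengthened"), 0.8)
  expect_false(cs$welch$inestimable)
  expect_lt(cs$welch$p, 0.05)
})

test_that("axis DE guards groups and recovers planted shifts", {
  set.seed(12)
  expr <- matrix(rnorm(100 * 60, mean = 8, sd = 0.5), 100, 60,
                 dimnames = list(geneIds(100), sprintf("s%02d", 1:60)))
  a <- colnames(expr)[1:30]; b <- colnames(expr)[31:60]
  expr[1:20, a] <- expr[1:20, a] + 1   # planted 2-fold shift
  de <- axisDifferentialExpression(expr, a, b)
  expect_error(axisDifferentialExpression(expr, a, a), "overlap")
  expect_error(axisDifferentialExpression(expr, a[1:2], b), "at least 3")
  degs <- callDEGs(de)   # composes with the DEG caller unchanged
  expect_gte(sum(geneIds(100)[1:20] %in% degs$up), 18)
  expect_identical(colnames(de)[1:5], c("gene", "log2FC", "SE", "p", "padj"))
})

test_that("axis DE is calibrated under the null", {
  set.seed(13)
  expr <- matrix(rnorm(200 * 40, mean = 8), 200, 40,
                 dimnames = list(geneIds(200), sprintf("s%02d", 1:40)))
  de <- axisDifferentialExpression(expr, colnames(expr)[1:20],
                                   colnames(expr)[21:40])
  expect_lt(mean(de$p < 0.05), 0.12)
  expect_identical(callDEGs(de)$up, character(0))
})

test_that("correlation matrix has unit diagonal, symmetry and planted sign", {
  g <- geneIds(40)
  sc <- simulateCohort(cohortSpec(
    nTumors = 300, nNormals = 10, nGenes = 40, nMirnas = 3,
    plantedAxis = list(mirna = "miR-001", targets = g[1:5],
                       rLow = -0.9, rHigh = -0.9), seed = 23))
  # planted correlations hold within a stratum (the generator standardizes
  # the latent miRNA signal per quartile stratum), so estimate there
  tum <- cohortTruth(sc)$axis$lowSamples
  cm <- correlationMatrix(c(g[1:5], "miR-001"), geneExpr(sc)[, tum],
                          mirnaExpr(sc)[, tum])
  expect_true(all(diag(cm$r) == 1))
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  expect_equal(cm$q, t(cm$q), tolerance = 1e-12)
  est <- cm$r["miR-001", g[1]]
  expect_true(est > -0.95 && est < -0.8)
  # permutation invariance of sample order
  cm2 <- correlationMatrix(c(g[1:5], "miR-001"),
                           geneExpr(sc)[, rev(tum)],
                           mirnaExpr(sc)[, rev(tum)])
  expect_equal(cm$r, cm2$r, tolerance = 1e-12)
  # zero-variance feature flagged
  expr0 <- geneExpr(sc)[, tum]; expr0[1, ] <- 5
  cm0 <- suppressWarnings(correlationMatrix(g[1:3], expr0))
  expect_identical(cm0$flagged, g[1])
})
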